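#' Default model configuration
#'
#' Returns the full parameter set for the arm, rod, muscle paths, muscle-tendon
#' units and controller as a nested list. Values represent a generic adult male
#' arm assembled from standard musculoskeletal literature ranges; every entry
#' can be overridden (see \code{\link{modify_config}}) and the whole set can be
#' serialized to YAML with \code{\link{write_config}} for reproducibility.
#'
#' Units: lengths m, masses kg, inertias kg m^2, forces N, torques N m,
#' angles rad, times s, stiffnesses N/m, damping N s/m.
#'
#' Coordinate convention (used consistently throughout): the generalized
#' coordinates are \code{q = (shoulder, elbow)} in rad, both measured so that
#' flexion increases the angle; 0 rad is the arm hanging straight down;
#' gravity acts along -y of the sagittal plane. Muscle moment arms follow a
#' flexor-positive sign convention, and muscle-tendon length satisfies
#' d l_MTU / d q_j = -r_j(q_j).
#'
#' @return Nested list with components \code{segments}, \code{rod},
#'   \code{muscles} (per-muscle named entries), \code{controller},
#'   \code{simulation} and \code{analysis}.
#' @export
default_config <- function() {
  muscle_names <- c("shoulder_flexor", "shoulder_extensor",
                    "elbow_flexor", "elbow_extensor",
                    "biarticular_flexor", "biarticular_extensor")

  # moment-arm magnitudes (m); rows = muscles, cols = (shoulder, elbow);
  # 0 means the muscle does not span that joint
  r0 <- rbind(
    shoulder_flexor      = c( 0.040, 0.000),
    shoulder_extensor    = c(-0.040, 0.000),
    elbow_flexor         = c( 0.000, 0.028),
    elbow_extensor       = c( 0.000,-0.028),
    biarticular_flexor   = c( 0.030, 0.025),
    biarticular_extensor = c(-0.030,-0.025)
  )
  colnames(r0) <- c("shoulder", "elbow")

  mus <- list()
  lopt   <- c(0.12, 0.12, 0.09, 0.09, 0.13, 0.13)
  lslack <- c(0.10, 0.10, 0.18, 0.18, 0.26, 0.26)
  fmax   <- c(1100, 1100, 1200, 1200, 900, 900)
  for (i in seq_along(muscle_names)) {
    mus[[muscle_names[i]]] <- list(
      f_max       = fmax[i],
      l_ce_opt    = lopt[i],
      fl_width    = 0.45,     # force-length bell width (dimensionless)
      v_max_rel   = 10,       # max concentric velocity in l_ce_opt / s
      hill_curv   = 0.25,     # Hill curvature K of the concentric hyperbola
      ecc_plateau = 1.5,      # eccentric force asymptote, multiples of isometric
      tendon_strain_fmax = 0.04,  # tendon strain at F_max (linear tendon)
      l_slack     = lslack[i],
      pee_strain_fmax = 0.5,  # parallel-elastic strain where F_PEE = F_max
      pee_comp_rel   = 0.7,   # fiber length (rel. l_ce_opt) where compression starts
      pee_comp_width = 0.3,   # compression strain scale (F_max at l_ce = 0.4 l_ce_opt)
      sde_d       = 0.3,      # serial damping, dimensionless (d = sde_d F_max / v_max)
      tau_act     = 0.020,    # activation time constant
      act_min     = 0.005,    # Hatze minimal activity q0
      act_rho     = 4.0,      # length-scaling constant of the Hatze nonlinearity
      act_nu      = 3.0,      # exponent of the Hatze nonlinearity
      r0          = r0[i, ],  # base moment arms at the reference posture
      wrap_gamma  = 0.5       # cosine-wrapping rate of the moment-arm model
    )
  }

  list(
    segments = list(
      upper_arm = list(mass = 2.1, length = 0.31, com = 0.135, inertia = 0.018),
      forearm   = list(mass = 1.9, length = 0.35, com = 0.170, inertia = 0.021),
      gravity   = 9.81
    ),
    rod = list(
      mass = 0.5,
      # free resonance sqrt(k/m)/2pi = 3.8 Hz, matching the pattern-generator
      # drive band; quality factor ~20 so the free oscillation persists well
      # beyond the excitation window
      stiffness = (2 * pi * 3.8)^2 * 0.5,
      damping   = sqrt((2 * pi * 3.8)^2 * 0.5 * 0.5) / 20
    ),
    muscles = mus,
    reference_posture = c(shoulder = 0.4, elbow = 1.0),
    joint_range = list(shoulder = c(-1.0, 2.0), elbow = c(0.0, 2.7)),
    controller = list(
      k_p       = 80,     # feedback gain (stimulation per m^2 of scaled length error)
      delay     = 0.010,  # proprioceptive delay, s
      u_open    = 0.25,   # default open-loop co-contraction level
      cpg_amplitude = 0.1,
      cpg_window    = c(0, 4),
      cpg_phase = c(shoulder_flexor = 0, shoulder_extensor = pi,
                    elbow_flexor = 0, elbow_extensor = pi,
                    biarticular_flexor = 0, biarticular_extensor = pi)
    ),
    simulation = list(
      sample_rate = 1000,  # output grid, Hz
      rtol = 1e-6,
      atol = 1e-8
    ),
    analysis = list(           # see mc_binning_policy() for the rules
      world_bins = 30,
      actuator_bins_selected = 12,
      actuator_bins_accumulated = 15,
      min_occupancy = 5
    )
  )
}

#' Modify a configuration
#'
#' Deep-merges \code{changes} into \code{config}: any named leaf present in
#' \code{changes} replaces the corresponding default.
#'
#' @param config A configuration list, e.g. from \code{\link{default_config}}.
#' @param changes Nested list of overrides.
#' @export
modify_config <- function(config, changes) {
  for (nm in names(changes)) {
    if (is.list(changes[[nm]]) && is.list(config[[nm]])) {
      config[[nm]] <- modify_config(config[[nm]], changes[[nm]])
    } else {
      config[[nm]] <- changes[[nm]]
    }
  }
  config
}

#' Write / read a configuration as YAML
#'
#' @param config Configuration list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::as.yaml
  cfg <- yaml::read_yaml(path)
  # yaml drops names on numeric vectors stored as maps; restore the ones we use
  for (m in names(cfg$muscles)) {
    cfg$muscles[[m]]$r0 <- unlist(cfg$muscles[[m]]$r0)
  }
  cfg$reference_posture <- unlist(cfg$reference_posture)
  cfg$controller$cpg_phase <- unlist(cfg$controller$cpg_phase)
  cfg
}

muscle_names <- function(config) names(config$muscles)

# stack a per-muscle scalar field into a named numeric vector
muscle_field <- function(config, field) {
  vapply(config$muscles, function(m) m[[field]], numeric(1))
}

# 6 x 2 matrix of base moment arms (rows muscles, cols shoulder/elbow)
moment_arm_matrix <- function(config) {
  t(vapply(config$muscles, function(m) m$r0, numeric(2)))
}

validate_config <- function(config) {
  seg <- config$segments
  stopifnot(
    seg$upper_arm$mass > 0, seg$forearm$mass > 0,
    seg$upper_arm$length > 0, seg$forearm$length > 0,
    seg$upper_arm$inertia > 0, seg$forearm$inertia > 0,
    config$rod$mass > 0, config$rod$stiffness > 0, config$rod$damping >= 0,
    all(muscle_field(config, "f_max") > 0),
    all(muscle_field(config, "l_ce_opt") > 0),
    all(muscle_field(config, "tau_act") > 0),
    config$controller$delay > 0
  )
  r0 <- moment_arm_matrix(config)
  lmax <- max(seg$upper_arm$length, seg$forearm$length)
  if (any(abs(r0) >= lmax)) stop("moment arm exceeds segment length")
  invisible(TRUE)
}
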