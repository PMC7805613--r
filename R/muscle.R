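#' Hill-type muscle-tendon unit
#'
#' Four-curve Hill model: contractile element (CE) with bell-shaped active
#' force-length and hyperbolic force-velocity characteristics, a parallel
#' elastic element (PEE), and a linear serial elastic tendon (SEE). The CE
#' velocity follows from force equilibrium between the tendon and the fiber,
#' solved in closed form because both force-velocity branches are invertible.
#' Activation is a first-order Hatze-type process with fiber-length-dependent
#' stationary activity.
#'
#' All curve helpers are vectorized over the six muscles.
#'
#' @name muscle_model
NULL

# active force-length factor, 1 at l_ce_opt
force_length <- function(l_ce, mp) {
  exp(-((l_ce / mp$l_ce_opt - 1) / mp$fl_width)^2)
}

# force-velocity factor; v_norm = (dl_ce/dt) / v_max, shortening negative.
# Concentric: (1 + v)/(1 - v/K); eccentric: N - (N-1)/(1 + v/Ke) with
# Ke = (N-1) K / (K+1) for slope continuity at v = 0.
force_velocity <- function(v_norm, mp) {
  K <- mp$hill_curv; N <- mp$ecc_plateau
  Ke <- (N - 1) * K / (K + 1)
  vc <- pmax(v_norm, -1)
  fv <- ifelse(v_norm < 0,
               (1 + vc) / (1 - vc / K),
               N - (N - 1) / (1 + v_norm / Ke))
  pmax(fv, 0)
}

# inverse of force_velocity: normalized fiber velocity for a demanded factor
force_velocity_inverse <- function(fv, mp) {
  K <- mp$hill_curv; N <- mp$ecc_plateau
  Ke <- (N - 1) * K / (K + 1)
  fv <- pmin(pmax(fv, 0), N - 0.01)
  ifelse(fv < 1,
         (fv - 1) / (1 + fv / K),
         pmin(Ke * (fv - 1) / (N - fv), 1))
}

force_pee <- function(l_ce, mp) {
  strain <- pmax(0, l_ce / mp$l_ce_opt - 1)
  mp$f_max * (strain / mp$pee_strain_fmax)^2
}

# net parallel-elastic force: tension above rest length, compression below the
# short-length stop (keeps an unloaded fiber from collapsing to zero length)
force_pee_net <- function(l_ce, mp) {
  comp <- pmax(0, mp$pee_comp_rel - l_ce / mp$l_ce_opt)
  force_pee(l_ce, mp) - mp$f_max * (comp / mp$pee_comp_width)^2
}

force_see <- function(l_see, mp) {
  k_t <- mp$f_max / (mp$tendon_strain_fmax * mp$l_slack)
  k_t * pmax(0, l_see - mp$l_slack)
}

#' Stationary muscle activity
#'
#' Closed-form fixed point of the activation dynamics for constant
#' stimulation and fiber length: a Hill-function ("Hatze-type") nonlinearity
#' whose gain grows with normalized fiber length,
#' \code{a_inf = (q0 + (rho u)^nu) / (1 + (rho u)^nu)},
#' \code{rho = act_rho l_ce / l_ce_opt}.
#'
#' @param u Stimulation in [0, 1] (vectorized).
#' @param l_ce Fiber length, m.
#' @param mp Muscle parameter list(s) stacked as vectors (see
#'   \code{muscle_param_vectors}).
#' @return Stationary activity in \code{[act_min, 1)}; nondecreasing in
#'   \code{u} and in \code{l_ce}.
#' @export
activation_stationary <- function(u, l_ce, mp) {
  rho_u <- (mp$act_rho * l_ce / mp$l_ce_opt) * u
  x <- rho_u^mp$act_nu
  (mp$act_min + x) / (1 + x)
}

#' Activation rate
#'
#' First-order relaxation of muscle activity toward the length-dependent
#' stationary value: \code{da/dt = (a_inf(u, l_ce) - a) / tau_act}.
#'
#' @param a Current activity in [0, 1].
#' @param u Stimulation in [0, 1]; values outside are a hard error (clamping
#'   is the controller's responsibility).
#' @param l_ce Fiber length, m.
#' @param mp Stacked muscle parameters.
#' @return da/dt, 1/s.
#' @export
activation_rate <- function(a, u, l_ce, mp) {
  if (any(u < 0 | u > 1)) stop("stimulation outside [0, 1]")
  (activation_stationary(u, l_ce, mp) - a) / mp$tau_act
}

#' Contraction dynamics of the muscle-tendon unit
#'
#' Given fiber length, activity, total MTU length and (optionally) MTU
#' lengthening velocity, enforces force equilibrium between the fiber side
#' (active CE force a f_l f_v F_max plus net parallel-elastic force) and the
#' serial side (linear tendon plus serial damping element):
#' \deqn{a f_l(l_{ce}) f_v(v) F_{max} + F_{PEE} =
#'       F_{SEE}(l_{MTU} - l_{ce}) + d_{se} (\dot l_{MTU} - v).}
#' Both force-velocity branches are hyperbolic, so the equilibrium velocity
#' solves a quadratic per branch in closed form. A slack tendon transmits no
#' force (the tendon cannot push); the reported F_MTU is floored at zero.
#'
#' @param l_ce Fiber length(s), m (> 0).
#' @param a Activity in [0, 1].
#' @param l_mtu MTU length(s), m.
#' @param mp Stacked muscle parameters.
#' @param l_mtu_dot MTU lengthening velocity, m/s (default 0: isometric MTU).
#' @return List \code{dl_ce} (m/s), \code{f_ce} (active fiber force, N),
#'   \code{f_mtu} (serial force, N, >= 0).
#' @export
contraction_dynamics <- function(l_ce, a, l_mtu, mp, l_mtu_dot = 0) {
  if (any(l_ce <= 0)) stop("fiber length must be positive")
  n <- length(l_ce)
  l_mtu_dot <- rep_len(l_mtu_dot, n)
  f_see <- force_see(l_mtu - l_ce, mp)
  taut <- (l_mtu - l_ce) > mp$l_slack
  d_se <- ifelse(taut, mp$sde_d * mp$f_max / (mp$v_max_rel * mp$l_ce_opt), 0)
  f_pee <- force_pee_net(l_ce, mp)
  fl <- force_length(l_ce, mp)
  f_iso <- pmax(a, mp$act_min) * pmax(fl, 1e-6) * mp$f_max
  v_max <- mp$v_max_rel * mp$l_ce_opt
  v_norm <- solve_fiber_velocity(f_iso, f_see + d_se * l_mtu_dot - f_pee,
                                 d_se * v_max, mp)
  f_mtu <- pmax(0, f_see + d_se * (l_mtu_dot - v_norm * v_max))
  f_ce <- pmax(a, mp$act_min) * fl * force_velocity(v_norm, mp) * mp$f_max
  list(dl_ce = v_norm * v_max, f_ce = f_ce, f_mtu = f_mtu)
}

# closed-form equilibrium fiber velocity (normalized): solves
# f_iso fv(v) = R - dv v per branch; dv = d_se v_max, R the serial load at
# v = 0 net of parallel force. Reduces to the plain f_v inverse when dv = 0.
solve_fiber_velocity <- function(f_iso, R, dv, mp) {
  K <- mp$hill_curv; N <- mp$ecc_plateau
  Ke <- (N - 1) * K / (K + 1)
  n <- length(f_iso)
  out <- numeric(n)
  conc <- R < f_iso
  for (i in seq_len(n)) {
    if (dv[i] <= 0) {
      out[i] <- force_velocity_inverse(max(R[i], 0) / f_iso[i],
                                       lapply(mp, `[`, i))
    } else if (conc[i]) {
      A <- dv[i] / K[i]
      B <- -(R[i] / K[i] + dv[i] + f_iso[i])
      C <- R[i] - f_iso[i]
      out[i] <- max((-B - sqrt(B^2 - 4 * A * C)) / (2 * A), -1)
    } else {
      A <- dv[i] / Ke[i]
      B <- (f_iso[i] * N[i] - R[i]) / Ke[i] + dv[i]
      C <- f_iso[i] - R[i]
      out[i] <- min((-B + sqrt(B^2 - 4 * A * C)) / (2 * A), 3)
    }
  }
  out
}

# Stack the per-muscle parameter lists into parallel vectors for vectorized
# evaluation across the six muscles.
muscle_param_vectors <- function(config) {
  fields <- c("f_max", "l_ce_opt", "fl_width", "v_max_rel", "hill_curv",
              "ecc_plateau", "tendon_strain_fmax", "l_slack",
              "pee_strain_fmax", "pee_comp_rel", "pee_comp_width", "sde_d",
              "tau_act", "act_min", "act_rho", "act_nu")
  mp <- lapply(fields, function(f) muscle_field(config, f))
  names(mp) <- fields
  mp
}

#' Isometric fiber-length equilibrium
#'
#' Fiber length at which the MTU is stationary (dl_ce/dt = 0) for a fixed
#' activity and MTU length, found by safeguarded bisection on the force
#' residual F_SEE - (a f_l F_max + F_PEE).
#'
#' @param a Activity (scalar or 6-vector).
#' @param l_mtu MTU length(s), m.
#' @param mp Stacked muscle parameters.
#' @param tol Force tolerance, N.
#' @return Fiber length(s), m.
#' @export
isometric_fiber_length <- function(a, l_mtu, mp, tol = 1e-10) {
  n <- length(l_mtu)
  a <- rep_len(a, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    mpi <- lapply(mp, `[`, i)
    resid <- function(l) {
      force_see(l_mtu[i] - l, mpi) -
        (pmax(a[i], mpi$act_min) * force_length(l, mpi) * mpi$f_max +
           force_pee_net(l, mpi))
    }
    lo <- 1e-4
    hi <- max(l_mtu[i] - 1e-4, 2 * mpi$l_ce_opt)
    # residual is decreasing in l (tendon force falls, fiber force rises)
    out[i] <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  }
  out
}
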