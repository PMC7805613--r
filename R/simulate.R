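#' Closed-loop simulation of the neuro-musculoskeletal arm
#'
#' Integrates the coupled system -- rigid-body arm, optional hand-held rod,
#' six activation states and six fiber lengths -- under the equilibrium-point
#' controller with delayed length feedback, as one global delay-differential
#' system (deSolve::dede, adaptive lsoda). All hierarchy signals are recorded
#' on a uniform output grid.
#'
#' @param schedule An \code{\link{ep_schedule}}.
#' @param config Full configuration (see \code{\link{default_config}}).
#' @param duration Simulated time, s.
#' @param cpg \code{NULL} (inactive) or list \code{f} (Hz); amplitude, phases
#'   and active window come from \code{config$controller}.
#' @param rod Attach the vibrating rod to the hand?
#' @param q0 Initial posture; defaults to the closed-loop static equilibrium
#'   of the first EP segment (the run starts at rest in the start posture).
#' @param protocol,seed Metadata recorded on the trace.
#' @return A \code{\link{hierarchy_trace}}.
#' @export
simulate_arm <- function(schedule, config = default_config(), duration,
                         cpg = NULL, rod = FALSE, q0 = NULL,
                         protocol = "custom", seed = NA_integer_) {
  validate_config(config)
  mp <- muscle_param_vectors(config)
  ctrl <- config$controller
  seg <- config$segments
  rodp <- config$rod
  kp <- ctrl$k_p
  delta <- ctrl$delay
  phi0 <- ctrl$cpg_phase
  u_hat <- ctrl$cpg_amplitude
  cpg_win <- ctrl$cpg_window
  f_cpg <- if (is.null(cpg)) NA_real_ else cpg$f

  if (is.null(q0)) {
    q0 <- closed_loop_equilibrium(schedule$u_open[1, ], schedule$lambda[1, ],
                                  config)$q
  }

  # consistent initial fiber lengths and activities at rest in q0
  kin0 <- muscle_kinematics(q0, config)
  l_ce <- isometric_fiber_length(0.5, kin0$l_mtu, mp)
  for (k in 1:60) {
    u0 <- motor_command(schedule$u_open[1, ], schedule$lambda[1, ], l_ce,
                        0, kp, mp$l_ce_opt)
    a0 <- activation_stationary(u0, l_ce, mp)
    l_new <- isometric_fiber_length(a0, kin0$l_mtu, mp)
    if (max(abs(l_new - l_ce)) < 1e-12) { l_ce <- l_new; break }
    l_ce <- l_new
  }
  lce0 <- l_ce

  y0 <- c(q0, c(0, 0), a0, lce0, if (rod) c(0, 0))
  lce_idx <- 11:16

  ## precomputed constants for the inner loop (the RHS is evaluated tens of
  ## thousands of times per run; avoid any list traversal there)
  r0m <- moment_arm_matrix(config)
  gam <- muscle_field(config, "wrap_gamma")
  qref <- config$reference_posture
  lref <- mp$l_ce_opt + mp$l_slack
  r0_gam <- r0m / gam
  lopt <- mp$l_ce_opt; tau <- mp$tau_act
  act_min <- mp$act_min; rho_c <- mp$act_rho; nu <- mp$act_nu
  fmax <- mp$f_max; flw <- mp$fl_width
  k_t <- fmax / (mp$tendon_strain_fmax * mp$l_slack)
  lslack <- mp$l_slack; pee_s <- mp$pee_strain_fmax
  comp_rel <- mp$pee_comp_rel; comp_w <- mp$pee_comp_width
  Kc <- mp$hill_curv; Ne <- mp$ecc_plateau
  Ke <- (Ne - 1) * Kc / (Kc + 1)
  v_max <- mp$v_max_rel * lopt
  d_base <- mp$sde_d * fmax / v_max
  s1m <- seg$upper_arm$mass; s1l <- seg$upper_arm$length
  s1c <- seg$upper_arm$com; s1i <- seg$upper_arm$inertia
  s2m <- seg$forearm$mass; s2l <- seg$forearm$length
  s2c <- seg$forearm$com; s2i <- seg$forearm$inertia
  grav <- seg$gravity
  m22 <- s2i + s2m * s2c^2
  g1c <- (s1m * s1c + s2m * s1l) * grav
  g2c <- s2m * s2c * grav
  hc <- s2m * s1l * s2c
  sched_t <- schedule$times
  sched_uo <- schedule$u_open
  sched_la <- schedule$lambda
  cpg_on <- !is.null(cpg)

  rhs <- function(t, y, p) {
    q1 <- y[1]; q2 <- y[2]; qd1 <- y[3]; qd2 <- y[4]
    a <- y[5:10]; lce <- y[11:16]
    seg_i <- if (t >= sched_t[length(sched_t)]) length(sched_t) else
      max(1L, findInterval(t, sched_t))
    lce_d <- if (t <= delta + 1e-12) lce0 else
      deSolve::lagvalue(t - delta, lce_idx)
    u_cpg <- if (cpg_on && t >= cpg_win[1] && t <= cpg_win[2])
      u_hat * sin(2 * pi * f_cpg * t + phi0) else 0
    u <- sched_uo[seg_i, ] + kp * lopt * (lce_d - sched_la[seg_i, ]) + u_cpg
    u <- u * (u > 0)
    u <- u + (1 - u) * (u > 1)
    rho_u <- (rho_c * lce / lopt) * u
    x <- rho_u^nu
    da <- ((act_min + x) / (1 + x) - a) / tau

    # muscle-path kinematics (cosine wrapping)
    ang1 <- gam * (q1 - qref[1]); ang2 <- gam * (q2 - qref[2])
    r1 <- r0m[, 1] * cos(ang1); r2 <- r0m[, 2] * cos(ang2)
    lmtu <- lref - r0_gam[, 1] * sin(ang1) - r0_gam[, 2] * sin(ang2)

    # contraction dynamics: serial force (tendon + serial damper) balanced
    # against CE + parallel forces, fiber velocity in closed form
    see_ext <- lmtu - lce - lslack
    taut <- see_ext > 0
    f_see <- k_t * see_ext * taut
    d_se <- d_base * taut
    mdot <- -(r1 * qd1 + r2 * qd2)
    lrel <- lce / lopt
    strp <- lrel - 1
    comp <- comp_rel - lrel
    f_pee_net <- fmax * (((strp * (strp > 0)) / pee_s)^2 -
                           ((comp * (comp > 0)) / comp_w)^2)
    fl <- exp(-(strp / flw)^2)
    ae <- a + (act_min - a) * (a < act_min)
    f_iso <- ae * (fl + (1e-6 - fl) * (fl < 1e-6)) * fmax
    Rr <- f_see + d_se * mdot - f_pee_net
    dv <- d_se * v_max
    conc <- Rr < f_iso
    # slack branch (dv = 0): plain force-velocity inverse of the demand
    fv0 <- Rr / f_iso
    fv0 <- fv0 * (fv0 > 0)
    fv0 <- fv0 + (Ne - 0.01 - fv0) * (fv0 > Ne - 0.01)
    v0c <- (fv0 - 1) / (1 + fv0 / Kc)
    v0e <- Ke * (fv0 - 1) / (Ne - fv0)
    v0 <- v0c * conc + (v0e + (1 - v0e) * (v0e > 1)) * (!conc)
    # damped branches: quadratic roots (dv guarded against 0 by mask below)
    dvg <- dv + (dv <= 0)
    disc <- Rr - f_iso
    Bc <- -(Rr / Kc + dvg + f_iso)
    sc <- Bc * Bc - 4 * (dvg / Kc) * disc
    vc <- (-Bc - sqrt(sc * (sc > 0))) / (2 * dvg / Kc)
    vc <- vc + (-1 - vc) * (vc < -1)
    Be <- (f_iso * Ne - Rr) / Ke + dvg
    se <- Be * Be + 4 * (dvg / Ke) * disc
    ve <- (-Be + sqrt(se * (se > 0))) / (2 * dvg / Ke)
    ve <- ve + (3 - ve) * (ve > 3)
    damped <- dv > 0
    v_norm <- v0 * (!damped) + (vc * conc + ve * (!conc)) * damped
    f_mtu <- f_see + d_se * (mdot - v_norm * v_max)
    f_mtu <- f_mtu * (f_mtu > 0)
    neg <- v_norm < 0
    fv_real <- ((1 + v_norm) / (1 - v_norm / Kc)) * neg +
      (Ne - (Ne - 1) / (1 + v_norm / Ke)) * (!neg)
    f_ce <- ae * fl * fv_real * fmax
    tq1 <- sum(r1 * f_mtu); tq2 <- sum(r2 * f_mtu)

    # arm dynamics
    c2 <- cos(q2); s2 <- sin(q2); s12 <- sin(q1 + q2)
    m11 <- s1i + s2i + s1m * s1c^2 +
      s2m * (s1l^2 + s2c^2 + 2 * s1l * s2c * c2)
    m12 <- s2i + s2m * (s2c^2 + s1l * s2c * c2)
    h <- hc * s2
    cor1 <- -h * qd2^2 - 2 * h * qd1 * qd2
    cor2 <- h * qd1^2
    g1 <- g1c * sin(q1) + g2c * s12
    g2 <- g2c * s12
    b1 <- tq1 - cor1 - g1
    b2 <- tq2 - cor2 - g2
    if (rod) {
      xr <- y[17]; vr <- y[18]
      f_rod <- rodp$stiffness * xr + rodp$damping * vr
      j1 <- s1l * sin(q1) + s2l * s12; j2 <- s2l * s12
      b1 <- b1 + j1 * f_rod; b2 <- b2 + j2 * f_rod
      det <- m11 * m22 - m12 * m12
      qdd1 <- (m22 * b1 - m12 * b2) / det
      qdd2 <- (m11 * b2 - m12 * b1) / det
      jdot_qd <- s1l * cos(q1) * qd1^2 + s2l * cos(q1 + q2) * (qd1 + qd2)^2
      xrdd <- -f_rod / rodp$mass - (j1 * qdd1 + j2 * qdd2 + jdot_qd)
      list(c(qd1, qd2, qdd1, qdd2, da, v_norm * v_max, vr, xrdd),
           c(u, f_ce, f_see, tq1, tq2))
    } else {
      det <- m11 * m22 - m12 * m12
      qdd1 <- (m22 * b1 - m12 * b2) / det
      qdd2 <- (m11 * b2 - m12 * b1) / det
      list(c(qd1, qd2, qdd1, qdd2, da, v_norm * v_max),
           c(u, f_ce, f_see, tq1, tq2))
    }
  }

  times <- seq(0, duration, by = 1 / config$simulation$sample_rate)
  out <- deSolve::dede(y0, times, rhs, NULL,
                       rtol = config$simulation$rtol,
                       atol = config$simulation$atol)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    stop("simulation diverged; last state: ",
         paste(signif(out[nrow(out), ], 4), collapse = " "))
  }

  tt <- out[, 1]
  si <- schedule_index(schedule, tt)
  n_state <- length(y0)
  aux0 <- 1 + n_state                     # aux outputs start after the states
  cols <- list(
    time = tt, u_central = si,
    uo  = schedule$u_open[si, , drop = FALSE],
    lam = schedule$lambda[si, , drop = FALSE],
    u    = out[, aux0 + 1:6, drop = FALSE],
    a    = out[, 1 + 5:10, drop = FALSE],
    fce  = out[, aux0 + 7:12, drop = FALSE],
    fmtu = out[, aux0 + 13:18, drop = FALSE],
    T    = out[, aux0 + 19:20, drop = FALSE],
    q    = out[, 1 + 1:2, drop = FALSE]
  )
  df <- data.frame(do.call(cbind, cols))
  names(df) <- c("time", "u_central", paste0("uo", 1:6), paste0("lam", 1:6),
                 paste0("u", 1:6), paste0("a", 1:6), paste0("fce", 1:6),
                 paste0("fmtu", 1:6), "T1", "T2", "q1", "q2")
  if (rod) df$rod_x <- out[, 1 + 17]

  trace <- new_hierarchy_trace(df, list(
    protocol = protocol, seed = seed, f_cpg = f_cpg, noise_level = 0,
    sample_rate = config$simulation$sample_rate, rod = rod,
    schedule = schedule
  ))
  check_trace_invariants(trace)
  trace
}

# Default EP postures of the point-to-point protocol: four target postures
# along a roughly vertical hand path, plus an intermediate peak-elbow posture
# used while passing between the extremes. c(shoulder, elbow), rad.
p2p_postures <- function() {
  list(p1 = c(0.10, 0.50), p2 = c(0.25, 0.90), p3 = c(0.45, 1.30),
       p4 = c(0.70, 1.70), peak = c(0.45, 2.00))
}

# Build the 3-segment EP schedule (start hold, peak, target) for a
# point-to-point movement between two postures.
p2p_schedule <- function(start_q, peak_q, target_q, config,
                         t_switch = c(0, 0.5, 1.0)) {
  u_open <- matrix(config$controller$u_open, 3, 6)
  lambda <- rbind(posture_lambda(start_q, config),
                  posture_lambda(peak_q, config),
                  posture_lambda(target_q, config))
  ep_schedule(t_switch, u_open, lambda)
}

#' Jittered EP schedules emulating natural movement variability
#'
#' Draws \code{n} point-to-point schedules whose start angles, peak elbow
#' angle and target angles are independently jittered (truncated normal,
#' sd \code{angle_jitter}, cut at +/- 2 sd), then converted to top-down
#' commands via the inverse muscle-length map. All controller parameters are
#' identical across schedules, so the schedules differ only in the top-down
#' signals.
#'
#' @param n Number of schedules.
#' @param angle_jitter Angular sd, rad (default 2 degrees).
#' @param seed Integer seed.
#' @param config Full configuration.
#' @param movement Character "1_4" style pair, or list(start, target) postures.
#' @return List of \code{ep_schedule}; jittered postures kept as attributes.
#' @export
sample_ep_variations <- function(n, angle_jitter = 2 * pi / 180, seed = 1L,
                                 config = default_config(),
                                 movement = "1_4") {
  stopifnot(n >= 1)
  pp <- p2p_postures()
  if (is.character(movement)) {
    ab <- strsplit(movement, "_")[[1]]
    start0 <- pp[[paste0("p", ab[1])]]; target0 <- pp[[paste0("p", ab[2])]]
  } else {
    start0 <- movement$start; target0 <- movement$target
  }
  peak0 <- pp$peak
  rng <- config$joint_range
  set.seed(seed)
  jit <- function(x) {
    repeat {
      d <- stats::rnorm(1, 0, angle_jitter)
      if (abs(d) <= 2 * angle_jitter) return(x + d)
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      start  <- c(jit(start0[1]), jit(start0[2]))
      peak   <- c(peak0[1], jit(peak0[2]))          # peak elbow angle only
      target <- c(jit(target0[1]), jit(target0[2]))
      ok <- all(c(start[1], peak[1], target[1]) >= rng$shoulder[1],
                c(start[1], peak[1], target[1]) <= rng$shoulder[2],
                c(start[2], peak[2], target[2]) >= rng$elbow[1],
                c(start[2], peak[2], target[2]) <= rng$elbow[2])
      if (ok) break
    }
    sch <- p2p_schedule(start, peak, target, config)
    attr(sch, "postures") <- list(start = start, peak = peak, target = target)
    out[[i]] <- sch
  }
  out
}

#' Run one point-to-point movement
#'
#' Simulates a goal-directed movement through start, peak and target EPs with
#' the pattern generator inactive (u_cpg identically zero) and no rod.
#'
#' @param schedule An \code{ep_schedule} (e.g. from
#'   \code{\link{sample_ep_variations}}).
#' @param config Full configuration.
#' @param duration Simulated time, s (default 3: holds settle well within it).
#' @param seed Metadata only (the run itself is deterministic).
#' @return A \code{hierarchy_trace}.
#' @export
run_point_to_point <- function(schedule, config = default_config(),
                               duration = 3, seed = NA_integer_) {
  simulate_arm(schedule, config, duration, cpg = NULL, rod = FALSE,
               protocol = "point_to_point", seed = seed)
}

#' Run one oscillation movement with the vibrating rod
#'
#' The arm holds a single EP while the pattern generator drives all muscles
#' sinusoidally (flexors/extensors in antiphase) during the excitation window
#' (default 0-4 s); afterwards the stimulation contribution is zero and the
#' movement continues on the stored energy of the rod.
#'
#' @param f_cpg Drive frequency, Hz.
#' @param config Full configuration.
#' @param duration Simulated time, s (>= 6 so the free phase is covered).
#' @param posture Held EP posture.
#' @param seed Metadata only.
#' @return A \code{hierarchy_trace} including the \code{rod_x} channel.
#' @export
run_oscillation <- function(f_cpg, config = default_config(), duration = 6,
                            posture = c(0.30, 1.60), seed = NA_integer_) {
  u_open <- matrix(config$controller$u_open, 1, 6)
  lambda <- rbind(posture_lambda(posture, config))
  sch <- ep_schedule(0, u_open, lambda)
  simulate_arm(sch, config, duration, cpg = list(f = f_cpg), rod = TRUE,
               protocol = "oscillation", seed = seed)
}

#' Sample pattern-generator frequencies
#'
#' Uniform draws from \code{center +/- spread}, emulating the observed
#' frequency variance of the human rod-swinging exercise.
#'
#' @param n Number of draws (the study uses 14).
#' @param center,spread Hz (defaults 3.8 and 0.2).
#' @param seed Integer seed.
#' @export
sample_cpg_frequencies <- function(n, center = 3.8, spread = 0.2, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  stats::runif(n, center - spread, center + spread)
}
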