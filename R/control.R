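#' Hierarchical equilibrium-point controller
#'
#' The motor command for muscle i is the clamped sum of an open-loop
#' stimulation, a delayed proprioceptive length-feedback term, and an optional
#' central-pattern-generator contribution:
#' \code{u_i = clamp01(u_open_i + k_p l_ce_opt_i (lambda_i - l_ce_i(t - delta))
#' + u_cpg_i)}. The top-down command (u_open, lambda) is piecewise constant in
#' time -- each constant segment is an equilibrium posture (EP) -- and the
#' highest control level is the integer index of the active segment.
#'
#' @name controller
NULL

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Central pattern generator signal
#'
#' \code{u_cpg(t) = u_hat sin(2 pi f t + phi0)}; flexors use phase 0,
#' extensors pi, so antagonist pairs are driven in exact antiphase. The
#' excitation window (default 0-4 s) is applied by the caller.
#'
#' @param t Time(s), s.
#' @param u_hat Amplitude (default 0.1).
#' @param f_cpg Frequency, Hz.
#' @param phi0 Phase offset, rad (scalar or per-muscle).
#' @return Stimulation contribution (dimensionless), |value| <= u_hat.
#' @export
cpg_signal <- function(t, u_hat, f_cpg, phi0) {
  u_hat * sin(2 * pi * f_cpg * t + phi0)
}

#' Motor command (low-level controller output)
#'
#' The feedback term is a monosynaptic stretch reflex: stimulation increases
#' in proportion to how far the delayed fiber length exceeds its desired
#' value lambda (scaled by the optimal fiber length), which is what makes a
#' held EP a stable equilibrium of the loop.
#'
#' @param u_open Open-loop stimulation, 6-vector in [0, 1].
#' @param lambda Desired fiber lengths, m (absolute).
#' @param l_ce_delayed Fiber lengths at t - delta, m.
#' @param u_cpg CPG contributions (0 when inactive).
#' @param k_p Feedback gain (> 0).
#' @param l_ce_opt Optimal fiber lengths, m (scales the feedback term).
#' @return Stimulations in [0, 1]; the clamp is applied once, to the full sum.
#' @export
motor_command <- function(u_open, lambda, l_ce_delayed, u_cpg, k_p, l_ce_opt) {
  clamp01(u_open + k_p * l_ce_opt * (l_ce_delayed - lambda) + u_cpg)
}

#' Delayed fiber length by interpolation in a stored history
#'
#' Linear interpolation of l_ce(t - delta) in a sampled history; for
#' t < delta the initial fiber lengths are returned (no history yet).
#'
#' @param history Data frame / matrix: first column time, then one column per
#'   muscle fiber length.
#' @param t Query time, s.
#' @param delta Delay, s (default 0.010).
#' @return Fiber lengths at t - delta.
#' @export
delayed_length <- function(history, t, delta = 0.010) {
  history <- as.matrix(history)
  if (nrow(history) == 0) stop("empty fiber-length history")
  tq <- t - delta
  if (tq <= history[1, 1]) return(history[1, -1])
  apply(history[, -1, drop = FALSE], 2, function(col) {
    stats::approx(history[, 1], col, xout = tq, rule = 2)$y
  })
}

#' Equilibrium-point schedule
#'
#' Ordered piecewise-constant top-down command: at each switch time all 12
#' top-down channels (6 open-loop stimulations + 6 desired fiber lengths)
#' change simultaneously. \code{u_central} is the integer index of the active
#' segment.
#'
#' @param times Strictly increasing segment start times, s (first must be 0).
#' @param u_open Matrix segments x 6 of open-loop stimulations in [0, 1].
#' @param lambda Matrix segments x 6 of desired fiber lengths, m.
#' @return Object of class \code{ep_schedule}.
#' @export
ep_schedule <- function(times, u_open, lambda) {
  u_open <- rbind(u_open); lambda <- rbind(lambda)
  stopifnot(length(times) == nrow(u_open), nrow(u_open) == nrow(lambda),
            ncol(u_open) == 6, ncol(lambda) == 6,
            all(diff(times) > 0), times[1] == 0,
            all(u_open >= 0 & u_open <= 1))
  structure(list(times = times, u_open = u_open, lambda = lambda),
            class = "ep_schedule")
}

# active segment index at time t (vectorized)
schedule_index <- function(schedule, t) {
  pmax(1L, findInterval(t, schedule$times))
}

schedule_at <- function(schedule, t) {
  i <- schedule_index(schedule, t)
  list(u_open = schedule$u_open[i, ], lambda = schedule$lambda[i, ], index = i)
}

#' Desired fiber lengths for a target posture
#'
#' Inverse muscle-length map used to build EP schedules: for a posture q the
#' desired fiber length of each muscle is its MTU length minus tendon slack,
#' i.e. the fiber length with the tendon just taut. Postures at larger
#' muscle lengths than lambda then produce positive (stretch-reflex-like)
#' feedback, yielding a stable equilibrium near q.
#'
#' @param q Target posture \code{c(shoulder, elbow)}, rad.
#' @param config Full configuration.
#' @return Named 6-vector of desired fiber lengths, m.
#' @export
posture_lambda <- function(q, config) {
  l_mtu <- muscle_kinematics(q, config)$l_mtu
  lam <- l_mtu - muscle_field(config, "l_slack")
  names(lam) <- muscle_names(config)
  lam
}

#' Closed-loop static equilibrium of a held equilibrium point
#'
#' Solves the statics of the full loop (activation fixed point, isometric
#' fiber equilibrium, muscle paths, gravity) for the posture at which joint
#' torques balance gravity under a held (u_open, lambda) command with the CPG
#' off. Used as an independent prediction of where a held EP settles.
#'
#' @param u_open,lambda Held command (6-vectors).
#' @param config Full configuration.
#' @param q_init Starting guess posture.
#' @param tol Torque residual tolerance, N m.
#' @return List \code{q} (posture), \code{residual} (torque imbalance).
#' @export
closed_loop_equilibrium <- function(u_open, lambda, config,
                                    q_init = config$reference_posture,
                                    tol = 1e-8) {
  mp <- muscle_param_vectors(config)
  resid <- function(q) {
    kin <- muscle_kinematics(q, config)
    # static fiber length: solve jointly with activation fixed point
    l_ce <- isometric_fiber_length(0.5, kin$l_mtu, mp)
    for (k in 1:60) {
      u <- motor_command(u_open, lambda, l_ce, 0, config$controller$k_p,
                         mp$l_ce_opt)
      a <- activation_stationary(u, l_ce, mp)
      l_new <- isometric_fiber_length(a, kin$l_mtu, mp)
      if (max(abs(l_new - l_ce)) < 1e-12) { l_ce <- l_new; break }
      l_ce <- l_new
    }
    f <- force_see(kin$l_mtu - l_ce, mp)
    drop(crossprod(kin$r, f)) - gravity_vec(q, config$segments)
  }
  # damped Newton with numerical Jacobian
  q <- q_init
  for (it in 1:80) {
    r0 <- resid(q)
    if (max(abs(r0)) < tol) break
    J <- matrix(0, 2, 2)
    h <- 1e-6
    for (j in 1:2) {
      qh <- q; qh[j] <- qh[j] + h
      J[, j] <- (resid(qh) - r0) / h
    }
    step <- tryCatch(solve(J, r0), error = function(e) r0 * 0.01)
    step <- pmin(pmax(-step, -0.2), 0.2)
    q <- q + step
  }
  list(q = q, residual = resid(q))
}

#' Add uniform stimulation noise to a recorded trace
#'
#' Adds per-sample i.i.d. zero-mean uniform noise to the stimulation channels
#' of a hierarchy trace and re-clamps to [0, 1]. The noise width per muscle is
#' \code{level * (u_max - u_min)} over the clean trace, following the medium
#' (40/300) and high (80/300) levels of the noise experiment.
#'
#' @param trace A \code{hierarchy_trace} (see \code{\link{run_point_to_point}}).
#' @param level Noise level: \code{"none"}, \code{"medium"}, \code{"high"}, or
#'   a numeric fraction of the per-muscle stimulation range.
#' @param seed Integer seed (reproducible).
#' @return The trace with noisy \code{u_*} channels; metadata records the level.
#' @export
add_stimulation_noise <- function(trace, level, seed = 1L) {
  if (is.character(level)) {
    level <- switch(level, none = 0, medium = 40 / 300, high = 80 / 300,
                    stop("unknown noise level"))
  }
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(trace)
  ucols <- grep("^u[1-6]$", names(trace), value = TRUE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (cl in ucols) {
    width <- level * diff(range(trace[[cl]]))
    trace[[cl]] <- clamp01(trace[[cl]] +
                             stats::runif(nrow(trace), -width / 2, width / 2))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  attr(trace, "meta")$noise_level <- level
  trace
}
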