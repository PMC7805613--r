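#' Two-link arm rigid-body dynamics
#'
#' Planar double-pendulum dynamics of the upper arm / forearm chain in the
#' sagittal plane, in the manipulator form M(q) qdd + C(q, qd) + G(q) = T.
#' Angles are measured from the downward vertical, flexion positive;
#' \code{q = c(shoulder, elbow)} with the elbow angle relative to the upper arm.
#'
#' @name arm_dynamics
NULL

# Mass matrix M(q) (2x2, symmetric positive definite).
mass_matrix <- function(q, segments) {
  s1 <- segments$upper_arm; s2 <- segments$forearm
  c2 <- cos(q[2])
  m11 <- s1$inertia + s2$inertia + s1$mass * s1$com^2 +
    s2$mass * (s1$length^2 + s2$com^2 + 2 * s1$length * s2$com * c2)
  m12 <- s2$inertia + s2$mass * (s2$com^2 + s1$length * s2$com * c2)
  m22 <- s2$inertia + s2$mass * s2$com^2
  matrix(c(m11, m12, m12, m22), 2, 2)
}

# Coriolis/centrifugal generalized forces C(q, qd) qd (length-2 vector).
coriolis_vec <- function(q, qd, segments) {
  s1 <- segments$upper_arm; s2 <- segments$forearm
  h <- s2$mass * s1$length * s2$com * sin(q[2])
  c(-h * qd[2]^2 - 2 * h * qd[1] * qd[2], h * qd[1]^2)
}

# Gravity generalized forces G(q).
gravity_vec <- function(q, segments) {
  s1 <- segments$upper_arm; s2 <- segments$forearm; g <- segments$gravity
  s12 <- sin(q[1] + q[2])
  c((s1$mass * s1$com + s2$mass * s1$length) * g * sin(q[1]) +
      s2$mass * s2$com * g * s12,
    s2$mass * s2$com * g * s12)
}

# Hand (forearm distal end) vertical position, Jacobian row and its drift term.
hand_vertical <- function(q, qd, segments) {
  l1 <- segments$upper_arm$length; l2 <- segments$forearm$length
  s1 <- sin(q[1]); s12 <- sin(q[1] + q[2])
  y  <- -(l1 * cos(q[1]) + l2 * cos(q[1] + q[2]))
  jy <- c(l1 * s1 + l2 * s12, l2 * s12)
  jdot_qd <- l1 * cos(q[1]) * qd[1]^2 + l2 * cos(q[1] + q[2]) * (qd[1] + qd[2])^2
  list(y = y, jac = jy, jdot_qd = jdot_qd)
}

#' Joint angular accelerations of the arm
#'
#' Solves the manipulator equation for \code{qdd} given joint torques and,
#' optionally, the reaction force of an attached vibrating rod. The rod slides
#' along a vertical axis through the hand; its spring-damper reaction
#' \code{k x + c v} acts on the hand in +y.
#'
#' @param q,qd Joint angles (rad) and velocities (rad/s), \code{(shoulder, elbow)}.
#' @param torque Joint torques (N m), same order.
#' @param segments \code{config$segments}.
#' @param rod_state Optional \code{c(x, v)} rod displacement/velocity.
#' @param rod Optional \code{config$rod} (required with \code{rod_state}).
#' @return \code{qdd}, length-2 (rad/s^2).
#' @export
arm_accelerations <- function(q, qd, torque, segments,
                              rod_state = NULL, rod = NULL) {
  if (any(!is.finite(c(q, qd, torque)))) stop("non-finite arm state or torque")
  M <- mass_matrix(q, segments)
  rhs <- torque - coriolis_vec(q, qd, segments) - gravity_vec(q, segments)
  if (!is.null(rod_state)) {
    f_rod <- rod$stiffness * rod_state[1] + rod$damping * rod_state[2]
    rhs <- rhs + hand_vertical(q, qd, segments)$jac * f_rod
  }
  solve(M, rhs)
}

#' Rod point-mass acceleration
#'
#' One-dimensional spring-mass-damper attached to the hand, expressed in
#' hand-relative coordinates (static gravity sag absorbed into the origin):
#' \code{xdd = -(k x + c v)/m - a_hand}. The free resonance is
#' \code{sqrt(k/m)/2/pi} Hz.
#'
#' @param rod_state \code{c(x, v)}, m and m/s.
#' @param hand_accel Vertical hand acceleration, m/s^2.
#' @param rod List with \code{mass}, \code{stiffness}, \code{damping}.
#' @return Scalar rod-mass acceleration relative to the hand, m/s^2.
#' @export
rod_accel <- function(rod_state, hand_accel, rod) {
  if (rod$mass <= 0 || rod$stiffness <= 0) {
    stop("rod mass and stiffness must be positive")
  }
  -(rod$stiffness * rod_state[1] + rod$damping * rod_state[2]) / rod$mass -
    hand_accel
}

#' Muscle-tendon path kinematics
#'
#' Moment arms and muscle-tendon-unit lengths at a posture, under the
#' cosine-wrapping model: \code{r_j(q_j) = r0_j cos(gamma (q_j - qref_j))},
#' with MTU length the matching integral so that
#' \code{d l_MTU / d q_j = -r_j(q_j)} exactly (flexor-positive moment arms,
#' so flexor MTUs shorten as their joint flexes). At the reference posture
#' every MTU length equals \code{l_ce_opt + l_slack}.
#'
#' @param q Posture \code{c(shoulder, elbow)}, rad.
#' @param config Full configuration.
#' @return List: \code{l_mtu} (named 6-vector, m), \code{r} (6 x 2 matrix of
#'   signed moment arms, m; zero where a muscle does not span a joint).
#' @export
muscle_kinematics <- function(q, config) {
  r0 <- moment_arm_matrix(config)
  gam <- muscle_field(config, "wrap_gamma")
  qref <- config$reference_posture
  dq <- rbind(q[1] - qref[1], q[2] - qref[2])  # 2 x 1
  # per muscle i, joint j: r_ij = r0_ij * cos(gam_i * dq_j)
  ang <- gam * t(matrix(dq, 2, nrow(r0)))     # 6 x 2
  r <- r0 * cos(ang)
  lref <- muscle_field(config, "l_ce_opt") + muscle_field(config, "l_slack")
  l_mtu <- lref - rowSums(ifelse(r0 == 0, 0, (r0 / gam) * sin(ang)))
  list(l_mtu = unname(l_mtu), r = r)
}

#' Joint torques from muscle-tendon forces
#'
#' \code{T_j = sum_i r_ij(q) F_i}; linear in the forces.
#'
#' @param f_mtu Nonnegative 6-vector of MTU forces, N.
#' @param q Posture, rad.
#' @param config Full configuration.
#' @return Named torque pair \code{c(shoulder, elbow)}, N m.
#' @export
joint_torques <- function(f_mtu, q, config) {
  if (any(f_mtu < 0)) stop("muscle forces must be nonnegative (muscles pull)")
  r <- muscle_kinematics(q, config)$r
  tq <- drop(crossprod(r, f_mtu))
  names(tq) <- c("shoulder", "elbow")
  tq
}

# Total mechanical energy of the passive arm (kinetic + gravitational,
# potential zero with the arm hanging straight down).
arm_energy <- function(q, qd, segments) {
  s1 <- segments$upper_arm; s2 <- segments$forearm; g <- segments$gravity
  kin <- 0.5 * drop(t(qd) %*% mass_matrix(q, segments) %*% qd)
  y1 <- -s1$com * cos(q[1])
  y2 <- -(s1$length * cos(q[1]) + s2$com * cos(q[1] + q[2]))
  pot <- s1$mass * g * (y1 + s1$com) + s2$mass * g * (y2 + s1$length + s2$com)
  kin + pot
}

#' Simulate the passive (muscle-free) arm
#'
#' Integrates the unforced double pendulum, optionally with zero gravity.
#' Used for conservation checks and as a plain rigid-body testbed.
#'
#' @param q0,qd0 Initial posture and velocity.
#' @param duration Seconds.
#' @param config Full configuration.
#' @param gravity If \code{FALSE}, gravity is switched off.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame \code{time, q1, q2, qd1, qd2}.
#' @export
simulate_passive_arm <- function(q0, qd0, duration, config = default_config(),
                                 gravity = TRUE, rtol = 1e-8, atol = 1e-10) {
  seg <- config$segments
  if (!gravity) seg$gravity <- 0
  rhs <- function(t, y, p) {
    qdd <- arm_accelerations(y[1:2], y[3:4], c(0, 0), seg)
    list(c(y[3:4], qdd))
  }
  times <- seq(0, duration, by = 1 / config$simulation$sample_rate)
  out <- deSolve::ode(c(q0, qd0), times, rhs, NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out) <- c("time", "q1", "q2", "qd1", "qd2")
  out
}
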