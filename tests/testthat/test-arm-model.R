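test_that("gravity-aligned and zero-gravity postures are equilibria", {
  cfg <- test_config()
  qdd <- arm_accelerations(c(0, 0), c(0, 0), c(0, 0), cfg$segments)
  expect_equal(qdd, c(0, 0), tolerance = 1e-12)

  seg0 <- cfg$segments
  seg0$gravity <- 0
  for (q in list(c(0.3, 1.2), c(-0.5, 0.1), c(1.4, 2.5))) {
    expect_equal(arm_accelerations(q, c(0, 0), c(0, 0), seg0), c(0, 0),
                 tolerance = 1e-12)
  }
  expect_error(arm_accelerations(c(NaN, 0), c(0, 0), c(0, 0), cfg$segments),
               "finite")
})

test_that("mass matrix is symmetric positive definite across postures", {
  cfg <- test_config()
  set.seed(4)
  for (i in 1:25) {
    q <- c(runif(1, -1, 2), runif(1, 0, 2.7))
    M <- neuromc:::mass_matrix(q, cfg$segments)
    expect_equal(M[1, 2], M[2, 1])
    expect_true(all(eigen(M, symmetric = TRUE)$values > 0))
  }
})

test_that("unforced frictionless swing conserves mechanical energy", {
  cfg <- test_config()
  out <- simulate_passive_arm(c(0.8, 1.0), c(0, 0), 2, cfg)
  E <- apply(out, 1, function(r) {
    neuromc:::arm_energy(c(r["q1"], r["q2"]), c(r["qd1"], r["qd2"]),
                         cfg$segments)
  })
  expect_lt(max(abs(E - E[1])), 1e-4 * max(1, abs(E[1])))
})

test_that("torque map is linear in muscle forces", {
  cfg <- test_config()
  q <- c(0.5, 1.1)
  set.seed(11)
  for (i in 1:10) {
    f1 <- runif(6, 0, 500); f2 <- runif(6, 0, 500)
    al <- runif(1, 0, 2); be <- runif(1, 0, 2)
    expect_equal(joint_torques(al * f1 + be * f2, q, cfg),
                 al * joint_torques(f1, q, cfg) +
                   be * joint_torques(f2, q, cfg),
                 tolerance = 1e-10)
  }
  expect_equal(unname(joint_torques(rep(0, 6), q, cfg)), c(0, 0))
  expect_error(joint_torques(c(-1, rep(0, 5)), q, cfg), "nonnegative")
})

test_that("single muscles produce the expected torque pattern", {
  cfg <- test_config()
  q <- c(0.4, 1.0)
  kin <- muscle_kinematics(q, cfg)
  # monoarticular elbow flexor (index 3), 1 N
  f <- rep(0, 6); f[3] <- 1
  tq <- joint_torques(f, q, cfg)
  expect_equal(unname(tq["elbow"]), kin$r[3, 2])
  expect_equal(unname(tq["shoulder"]), 0)
  # biarticular flexor (index 5) acts at both joints
  f <- rep(0, 6); f[5] <- 100
  tq <- joint_torques(f, q, cfg)
  expect_true(all(abs(tq) > 0))
  # moment-arm structure: monoarticular muscles span one joint only
  expect_equal(sum(kin$r[3, ] != 0), 1)
  expect_equal(sum(kin$r[5, ] != 0), 2)
})

test_that("MTU length derivative equals minus the moment arm", {
  cfg <- test_config()
  h <- 1e-6
  for (q in list(c(0.2, 0.6), c(0.7, 1.8), c(-0.3, 2.3))) {
    kin <- muscle_kinematics(q, cfg)
    for (j in 1:2) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      dl <- (muscle_kinematics(qp, cfg)$l_mtu -
               muscle_kinematics(qm, cfg)$l_mtu) / (2 * h)
      expect_equal(dl, -kin$r[, j], tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("elbow flexor MTU shortens monotonically with elbow flexion", {
  cfg <- test_config()
  angles <- seq(0.1, 2.6, length.out = 40)
  l <- vapply(angles, function(a) muscle_kinematics(c(0.4, a), cfg)$l_mtu[3],
              numeric(1))
  expect_true(all(diff(l) < 0))
})

test_that("rod behaves as a damped oscillator at the design resonance", {
  cfg <- test_config()
  rod <- cfg$rod
  expect_equal(rod_accel(c(0, 0), 0, rod), 0)
  expect_error(rod_accel(c(0, 0), 0, list(mass = 0, stiffness = 1,
                                          damping = 0)), "positive")
  # free response frequency vs closed form, via FFT of a simulated release
  f0 <- sqrt(rod$stiffness / rod$mass) / (2 * pi)
  expect_equal(f0, 3.8, tolerance = 1e-12)
  dt <- 1e-3; tt <- seq(0, 4, dt)
  rhs <- function(t, y, p) list(c(y[2], rod_accel(y, 0, rod)))
  out <- deSolve::ode(c(0.05, 0), tt, rhs, NULL)
  sp <- Mod(stats::fft(out[, 2]))[1:(length(tt) %/% 2)]
  fgrid <- (seq_along(sp) - 1) / (length(tt) * dt)
  expect_lt(abs(fgrid[which.max(sp[-1]) + 1] - f0), 1 / (length(tt) * dt))
})

test_that("clamped-hand rod response peaks at the resonance frequency", {
  cfg <- test_config()
  rod <- cfg$rod
  amp <- vapply(c(3.0, 3.8, 4.6), function(f) {
    rhs <- function(t, y, p) {
      a_hand <- -0.01 * (2 * pi * f)^2 * sin(2 * pi * f * t)
      list(c(y[2], rod_accel(y, a_hand, rod)))
    }
    out <- deSolve::ode(c(0, 0), seq(0, 4, 1e-3), rhs, NULL)
    x <- out[out[, 1] >= 2, 2]
    diff(range(x))
  }, numeric(1))
  expect_gt(amp[2], amp[1])
  expect_gt(amp[2], amp[3])
})
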