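test_that("identical schedule and seed reproduce a bit-identical run", {
  cfg <- test_config()
  sch <- neuromc:::p2p_schedule(c(0.15, 0.6), c(0.4, 1.6), c(0.5, 1.3), cfg,
                                t_switch = c(0, 0.3, 0.6))
  a <- simulate_arm(sch, cfg, duration = 1.2, protocol = "det", seed = 1)
  b <- simulate_arm(sch, cfg, duration = 1.2, protocol = "det", seed = 1)
  expect_identical(as.matrix(as.data.frame(a)), as.matrix(as.data.frame(b)))
})

test_that("EP variation sampling has the documented structure", {
  # the study repetition count
  schs <- sample_ep_variations(7, seed = 5)
  expect_length(schs, 7)
  # zero jitter: all schedules identical
  same <- sample_ep_variations(3, angle_jitter = 0, seed = 5)
  expect_identical(same[[1]]$lambda, same[[2]]$lambda)
  expect_identical(same[[1]]$u_open, same[[3]]$u_open)
  # jittered schedules differ only in top-down signals
  expect_identical(schs[[1]]$u_open, schs[[2]]$u_open)
  expect_identical(schs[[1]]$times, schs[[2]]$times)
  expect_false(identical(schs[[1]]$lambda, schs[[2]]$lambda))
  # truncation at +/- 2 sd around the base postures
  base <- neuromc:::p2p_postures()
  sj <- 2 * pi / 180
  for (s in schs) {
    po <- attr(s, "postures")
    expect_lte(max(abs(po$start - base$p1)), 2 * sj + 1e-12)
    expect_lte(abs(po$peak[2] - base$peak[2]), 2 * sj + 1e-12)
    expect_identical(po$peak[1], base$peak[1])
    expect_lte(max(abs(po$target - base$p4)), 2 * sj + 1e-12)
  }
})

test_that("pattern-generator frequencies are drawn uniformly in the band", {
  fs <- sample_cpg_frequencies(14, seed = 3)
  expect_length(fs, 14)
  expect_true(all(fs >= 3.6 & fs <= 4.0))
  expect_identical(fs, sample_cpg_frequencies(14, seed = 3))
})

test_that("point-to-point runs keep the pattern generator silent", {
  tr <- p2p_runs()[[1]]
  expect_true(is.na(attr(tr, "meta")$f_cpg))
  # u carries no component at oscillation frequencies during the final hold:
  # it converges to a constant
  tail_u <- tr$u1[tr$time > 2.5]
  expect_lt(diff(range(tail_u)), 5e-3)
})

test_that("point-to-point runs settle onto the closed-loop statics equilibrium", {
  cfg <- test_config()
  for (tr in p2p_runs()) {
    sch <- attr(tr, "meta")$schedule
    eq <- closed_loop_equilibrium(sch$u_open[3, ], sch$lambda[3, ], cfg,
                                  q_init = c(0.6, 1.5))
    n <- nrow(tr)
    expect_lt(max(abs(c(tr$q1[n], tr$q2[n]) - eq$q)) * 180 / pi, 2)
  }
})

test_that("oscillation runs stop the drive at 4 s yet keep oscillating", {
  tr <- osc_resonance()
  expect_true(trace_has_rod(tr))
  expect_gte(max(tr$time), 6)
  # after the excitation window the stimulation has no 3.8 Hz drive component:
  # project u1 onto the drive quadratures in 4.5-6 s vs 2-4 s
  proj <- function(t0, t1) {
    i <- tr$time >= t0 & tr$time <= t1
    tt <- tr$time[i]; u <- tr$u1[i] - mean(tr$u1[i])
    sqrt(mean(u * sin(2 * pi * 3.8 * tt))^2 + mean(u * cos(2 * pi * 3.8 * tt))^2)
  }
  expect_lt(proj(4.5, 6), 0.2 * proj(2, 4))
  # the rod keeps a substantial share of its driven amplitude
  amp24 <- diff(range(tr$rod_x[tr$time >= 2 & tr$time < 4]))
  amp46 <- diff(range(tr$rod_x[tr$time >= 4 & tr$time < 6]))
  expect_gt(amp46, 0.25 * amp24)
})

test_that("rod amplitude at resonance exceeds the off-resonance response", {
  cfg <- test_config()
  off <- cached("osc30", run_oscillation(3.0, cfg, duration = 4, seed = 8))
  res <- osc_resonance()
  amp <- function(tr) diff(range(tr$rod_x[tr$time >= 2 & tr$time < 4]))
  expect_gt(amp(res), amp(off))
})

test_that("benchmark kinds carry their analytic information values", {
  ind <- generate_discrete_benchmark("independent", 4, 4, T = 2000, seed = 1)
  expect_equal(ind$analytic_mc, 0, tolerance = 1e-10)
  cw <- generate_discrete_benchmark("copy_world", 4, 4, T = 2000, seed = 1)
  expect_equal(cw$analytic_mc, 2)
  gen <- generate_discrete_benchmark("general", 3, 5, T = 2000, seed = 2)
  # independent exhaustive-summation oracle over the kernel
  K <- gen$kernel; pw <- gen$p_w; pa <- gen$p_a
  tot <- 0
  for (ai in 1:5) for (wi in 1:3) for (wpi in 1:3) {
    al <- K[wpi, wi, ai]
    at <- sum(K[wpi, , ai] * pw)
    if (al > 0) tot <- tot + pa[ai] * pw[wi] * al * log2(al / at)
  }
  expect_equal(gen$analytic_mc, tot, tolerance = 1e-12)
})

test_that("the estimator is consistent on long benchmark sequences", {
  for (spec in list(list(k = "independent", nw = 4, na = 4),
                    list(k = "copy_world", nw = 4, na = 4),
                    list(k = "general", nw = 8, na = 8))) {
    b <- generate_discrete_benchmark(spec$k, spec$nw, spec$na, T = 1e5,
                                     seed = 42)
    est <- mc_w(estimate_joint(b))
    expect_lt(abs(est - b$analytic_mc), 0.02)
  }
})

test_that("simulated traces satisfy the producing-module invariants", {
  for (tr in c(p2p_runs(), osc_runs())) {
    expect_true(neuromc:::check_trace_invariants(tr))
    a <- as.matrix(tr[paste0("a", 1:6)])
    expect_true(all(a >= 0 & a <= 1))
    f <- as.matrix(tr[paste0("fmtu", 1:6)])
    expect_true(all(f >= 0))
  }
})

test_that("traces round-trip through the CSV exporter", {
  tr <- p2p_runs()[[1]]
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(as.data.frame(back)$q2, tr$q2, tolerance = 1e-10)
  expect_equal(attr(back, "meta")$protocol, "point_to_point")
  unlink(path)
})
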