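test_that("discretization handles constant, binary and crafted channels", {
  # constant channel collapses to one symbol
  d <- discretize(matrix(1.5, 10, 1), 4)
  expect_equal(d$alphabet, 1)
  expect_true(all(d$codes == 1))
  # a binary channel at 2 bins reproduces the sequence structure
  x <- c(0, 1, 1, 0, 1, 0)
  d <- discretize(matrix(x, ncol = 1), 2)
  expect_equal(d$alphabet, 2)
  expect_equal(d$codes[x == 0], rep(d$codes[1], 3))
  expect_length(unique(d$codes[x == 1]), 1)
  # two channels: occupied alphabet bounded by the per-channel product,
  # with equality iff every combination occurs
  m <- rbind(c(0, 0), c(0, 1), c(1, 0))
  d <- discretize(m, 2)
  expect_equal(d$alphabet, 3)          # 3 of the 4 combinations occur
  m2 <- rbind(m, c(1, 1))
  expect_equal(discretize(m2, 2)$alphabet, 4)
  expect_error(discretize(matrix(numeric(0), 0, 1), 2), "empty")
})

test_that("level splits assign channels per mode", {
  tr <- p2p_runs()[[1]]
  s <- build_level_split(tr, "selected", "u")
  expect_length(s$a_channels, 6)
  expect_equal(s$w_channels, c("q1", "q2"))
  # accumulated cut at the torque level: A holds the whole control side
  s <- build_level_split(tr, "accumulated", "T")
  expect_length(s$a_channels, 1 + 12 + 6 + 6 + 6 + 6 + 2)
  expect_equal(s$w_channels, c("q1", "q2"))
  # accumulated top cut
  s <- build_level_split(tr, "accumulated", "u_central")
  expect_equal(s$a_channels, "u_central")
  expect_length(s$w_channels, 12 + 6 + 6 + 6 + 6 + 2 + 2)
  # q (and rod) never appear on the actuator side
  tro <- osc_resonance()
  for (mode in c("selected", "accumulated")) for (lev in hierarchy_levels()) {
    s <- build_level_split(tro, mode, lev)
    expect_false(any(c("q1", "q2", "rod_x") %in% s$a_channels))
    if (mode == "selected") expect_equal(s$w_channels, c("q1", "q2", "rod_x"))
  }
  expect_error(build_level_split(tr, "selected", "q"), "level")
})

test_that("joint estimation reproduces hand-counted frequencies", {
  s <- structure(list(w = c(0, 0, 0), a = c(0, 0, 0), time = 0:2),
                 class = "discrete_series")
  j <- estimate_joint(s)
  expect_equal(nrow(j$table), 1)
  expect_equal(j$table$p, 1)
  # 5-step toy sequence: four distinct triples, each with probability 1/4
  s <- structure(list(w = c(0, 1, 0, 1, 0), a = c(0, 0, 1, 1, 0),
                      time = 0:4), class = "discrete_series")
  j <- estimate_joint(s)
  jt <- as.data.frame(j$table)
  expect_equal(j$N, 4)
  lookup <- function(wp, w, a) {
    r <- jt[jt$wp == wp & jt$w == w & jt$a == a, "p"]
    if (length(r)) r else 0
  }
  expect_equal(lookup(1, 0, 0), 1 / 4)
  expect_equal(lookup(0, 1, 0), 1 / 4)
  expect_equal(lookup(1, 0, 1), 1 / 4)
  expect_equal(lookup(0, 1, 1), 1 / 4)
  expect_equal(sum(jt$p), 1, tolerance = 1e-12)
})

test_that("marginalizing the joint over w matches the direct pair estimate", {
  set.seed(21)
  s <- structure(list(w = sample(1:3, 500, TRUE), a = sample(1:2, 500, TRUE),
                      time = seq_len(500)), class = "discrete_series")
  j <- estimate_joint(s)
  jt <- as.data.frame(j$table)
  marg <- stats::aggregate(p ~ wp + a, jt, sum)
  direct <- table(wp = s$w[2:500], a = s$a[1:499]) / 499
  for (i in seq_len(nrow(marg))) {
    expect_equal(marg$p[i],
                 direct[as.character(marg$wp[i]), as.character(marg$a[i])],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the divergence vanishes when W adds nothing beyond A", {
  # w' depends only on a: generate i.i.d. pairs with w' = f(a)
  set.seed(8)
  a <- sample(1:3, 4000, TRUE)
  b <- structure(list(w_prime = a, w = sample(1:4, 4000, TRUE), a = a),
                 class = "discrete_benchmark")
  expect_equal(mc_w(estimate_joint(b)), 0, tolerance = 1e-12)
})

test_that("the estimator equals brute-force conditional mutual information", {
  set.seed(13)
  for (i in 1:5) {
    s <- structure(list(w = sample(1:4, 800, TRUE), a = sample(1:3, 800, TRUE),
                        time = seq_len(800)), class = "discrete_series")
    j <- estimate_joint(s)
    expect_equal(mc_w(j), brute_cmi(j), tolerance = 1e-10)
  }
  # and on an actual simulated-arm joint
  tr <- p2p_runs()[[1]]
  j <- estimate_joint(discretize_split(tr, build_level_split(tr, "selected",
                                                             "u")))
  expect_equal(mc_w(j), brute_cmi(j), tolerance = 1e-10)
})

test_that("the divergence is nonnegative on arbitrary series", {
  set.seed(17)
  for (i in 1:20) {
    T <- sample(50:400, 1)
    s <- structure(list(w = sample(1:sample(2:6, 1), T, TRUE),
                        a = sample(1:sample(2:5, 1), T, TRUE),
                        time = seq_len(T)), class = "discrete_series")
    expect_gte(mc_w(estimate_joint(s)), 0)
  }
})

test_that("state-dependent values average back to the scalar measure", {
  # constant series: every entry zero
  s <- structure(list(w = rep(1, 50), a = rep(1, 50), time = 1:50),
                 class = "discrete_series")
  j <- estimate_joint(s)
  expect_equal(mc_w_state_dependent(j, s), rep(0, 49))
  # random series: frequency-weighted mean equals the scalar
  set.seed(30)
  for (i in 1:4) {
    s <- structure(list(w = sample(1:4, 600, TRUE), a = sample(1:3, 600, TRUE),
                        time = seq_len(600)), class = "discrete_series")
    j <- estimate_joint(s)
    expect_equal(mean(mc_w_state_dependent(j, s)), mc_w(j), tolerance = 1e-10)
  }
  # deterministic copy series: entries equal log2(1 / p(w'|a)) >= 0
  set.seed(31)
  w <- rep(1:4, length.out = 400)          # cycles deterministically
  a <- sample(1:2, 400, TRUE)
  s <- structure(list(w = w, a = a, time = seq_len(400)),
                 class = "discrete_series")
  j <- estimate_joint(s)
  sd_t <- mc_w_state_dependent(j, s)
  jt <- as.data.frame(j$table)
  for (t in sample(1:399, 25)) {
    p_wa <- jt$p_wa[jt$wp == w[t + 1] & jt$w == w[t] & jt$a == a[t]]
    expect_equal(sd_t[t], log2(1 / p_wa), tolerance = 1e-12)
  }
  expect_true(all(sd_t >= 0))
})

test_that("per-level tables have the right shape and information bound", {
  tr <- p2p_runs()[[1]]
  tab <- mc_by_level(list(tr), "selected")
  expect_equal(nrow(tab), 7)
  expect_equal(as.character(tab$level), hierarchy_levels())
  for (lev in hierarchy_levels()) {
    s <- discretize_split(tr, build_level_split(tr, "selected", lev))
    expect_lte(tab$mc_bits[tab$level == lev], log2(s$n_w) + 1e-9)
  }
  # a full-trace window reproduces the unwindowed value
  m1 <- mc_trace(tr, "accumulated", "u")$mc_w
  m2 <- mc_trace(tr, "accumulated", "u", window = c(-1, 1e9))$mc_w
  expect_equal(m1, m2)
})
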