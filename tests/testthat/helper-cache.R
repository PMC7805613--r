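# Expensive simulations are shared across test files through a lazy cache.
# All study seeds are fixed here, once, for the whole suite.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

test_config <- function() default_config()

# the 3-run point-to-point study (jittered EPs, movement 1 -> 4)
p2p_runs <- function() cached("p2p", {
  schs <- sample_ep_variations(3, seed = 1)
  lapply(seq_along(schs), function(i) {
    run_point_to_point(schs[[i]], test_config(), seed = i)
  })
})

# the 3-run oscillation study (random drive frequencies, 3.8 +/- 0.2 Hz)
osc_runs <- function() cached("osc", {
  fs <- sample_cpg_frequencies(3, seed = 2)
  lapply(seq_along(fs), function(i) {
    run_oscillation(fs[[i]], test_config(), seed = i)
  })
})

# the resonance run used for the segment analysis
osc_resonance <- function() cached("osc38", {
  run_oscillation(3.8, test_config(), seed = 9)
})

# a single-EP hold used for settling/stability checks
hold_run <- function() cached("hold", {
  cfg <- test_config()
  sch <- ep_schedule(0, matrix(cfg$controller$u_open, 1, 6),
                     rbind(posture_lambda(c(0.45, 1.3), cfg)))
  simulate_arm(sch, cfg, duration = 4, protocol = "hold")
})

# independent brute-force conditional mutual information I(W'; W | A) of an
# estimated joint, via entropies of the empirical distribution
brute_cmi <- function(joint) {
  jt <- as.data.frame(joint$table)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_wpa <- H(stats::aggregate(p ~ wp + a, jt, sum)$p)
  h_a <- H(stats::aggregate(p ~ a, jt, sum)$p)
  h_wpwa <- H(jt$p)
  h_wa <- H(stats::aggregate(p ~ w + a, jt, sum)$p)
  (h_wpa - h_a) - (h_wpwa - h_wa)
}
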