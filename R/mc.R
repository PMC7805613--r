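#' Quantifying morphological computation on discretized traces
#'
#' The measure is the Kullback-Leibler divergence between the empirical
#' world-dynamics kernel and its action-only reduction,
#' \deqn{MC_W = \sum_{w',w,a} p(w',w,a) \log_2
#'       \frac{p(w'|w,a)}{p(w'|a)},}
#' i.e. the conditional mutual information I(W'; W | A) of the empirical
#' joint, in bits. The joint p(w', w, a) is estimated by frequency counts of
#' the N = T - 1 consecutive-sample triples (w_{t+1}, w_t, a_t).
#'
#' @name mc_quantification
NULL

#' Binning policy for hierarchy-level splits
#'
#' Per-channel bin counts are set by a state group's role and mode, not
#' tuned per level, so that every comparison (across levels, and between
#' windows of one trace) is made under one identical policy.
#' \itemize{
#'   \item Selected-mode world state (q, plus rod position): \code{world_bins}
#'     per channel -- the observable state is 2-3 channels and affords the
#'     default fine resolution.
#'   \item Selected-mode actuator level: \code{actuator_bins_selected} per
#'     channel, identical for every level. With equal per-channel resolution,
#'     total resolution grows with channel count, which is what makes the
#'     2-channel torque state a coarser conditioning variable than the
#'     6-channel force states.
#'   \item Accumulated-mode world group: the frequency estimator counts
#'     (w', w, a) triples, so the occupied table scales like |W|^2 |A|; the
#'     world resolution is therefore held at the occupancy bound evaluated at
#'     the full channel-set dimension,
#'     \code{max(2, floor((N / min_occupancy)^(1 / n_total)))} (2 for these
#'     trace sizes), and -- deliberately -- at the same value for every cut,
#'     so that moving the cut, not changing resolution, is the only
#'     difference between accumulated splits.
#'   \item Accumulated-mode actuator group: \code{actuator_bins_accumulated}
#'     per channel; the conditioning side enters the triple table only once,
#'     so it affords an intermediate resolution.
#' }
#'
#' @param world_bins Bins/channel for the low-dimensional observable world
#'   state (default 30).
#' @param actuator_bins_selected Bins/channel for a selected actuation level
#'   (default 12).
#' @param actuator_bins_accumulated Bins/channel for the accumulated
#'   actuator group (default 15).
#' @param min_occupancy Target samples per occupied cell driving the
#'   accumulated world resolution (default 5).
#' @return A policy list consumed by \code{\link{discretize_split}}.
#' @export
mc_binning_policy <- function(world_bins = 30, actuator_bins_selected = 12,
                              actuator_bins_accumulated = 15,
                              min_occupancy = 5) {
  list(world_bins = world_bins,
       actuator_bins_selected = actuator_bins_selected,
       actuator_bins_accumulated = actuator_bins_accumulated,
       min_occupancy = min_occupancy)
}

#' Bins per channel for a state group
#'
#' Applies the rules of \code{\link{mc_binning_policy}} for one state group.
#'
#' @param n_channels Channels in the state group.
#' @param n_samples Samples in the trace.
#' @param mode \code{"selected"} or \code{"accumulated"}.
#' @param role \code{"world"} or \code{"actuator"}.
#' @param n_total Total channels across the hierarchy (sets the accumulated
#'   world resolution; defaults to \code{n_channels}).
#' @param policy A \code{\link{mc_binning_policy}}.
#' @return Integer bins per channel.
#' @export
bins_for_group <- function(n_channels, n_samples, mode,
                           role = c("world", "actuator"),
                           n_total = n_channels,
                           policy = mc_binning_policy()) {
  role <- match.arg(role)
  if (role == "actuator") {
    b <- if (mode == "selected") policy$actuator_bins_selected else
      policy$actuator_bins_accumulated
    return(as.integer(b))
  }
  if (mode == "selected") return(as.integer(policy$world_bins))
  max(2L, as.integer(floor((n_samples / policy$min_occupancy)^(1 / n_total))))
}

#' Discretize channels into a symbol sequence
#'
#' Each channel is cut into \code{n_bins} uniform-width bins over its observed
#' range (left-closed, right-open; the maximum falls in the last bin); a
#' channel with zero variance collapses to a single bin. The multi-channel
#' symbol is the combination of per-channel bin indices, coded densely as
#' integers 1..K over the occupied combinations (K is bounded by the product
#' of occupied per-channel bin counts, with equality iff every combination
#' occurs).
#'
#' @param x Numeric matrix / data frame (rows = samples, cols = channels).
#' @param n_bins Bins per channel.
#' @return List: \code{codes} (integer symbols, 1..K), \code{alphabet} (K),
#'   \code{bin_index} (matrix of per-channel bins), \code{edges} (per-channel
#'   bin edges).
#' @export
discretize <- function(x, n_bins) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty trace")
  if (n_bins < 2) stop("need at least 2 bins")
  if (any(!is.finite(x))) stop("non-finite channel values")
  bins <- matrix(1L, nrow(x), ncol(x))
  edges <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi - lo <= 0) { edges[[j]] <- c(lo, lo); next }  # constant channel
    e <- seq(lo, hi, length.out = n_bins + 1)
    b <- findInterval(x[, j], e, rightmost.closed = TRUE)
    bins[, j] <- pmin(b, n_bins)
    edges[[j]] <- e
  }
  key <- do.call(paste, c(as.data.frame(bins), sep = "\r"))
  uk <- unique(key)
  codes <- match(key, uk)
  list(codes = codes, alphabet = length(uk), bin_index = bins, edges = edges)
}

#' Assign trace channels to world and actuator states
#'
#' \code{selected}: A is exactly the named level's channels and W is the
#' observable mechanical state q (plus the rod position when present).
#' \code{accumulated}: a clean cut -- A collects the named level and every
#' level above it, W everything strictly below the cut (down to and including
#' q). The mechanical state is never part of A.
#'
#' @param trace A \code{hierarchy_trace}.
#' @param mode \code{"selected"} or \code{"accumulated"}.
#' @param level One of \code{hierarchy_levels()}.
#' @return Object of class \code{level_split}: \code{w_channels},
#'   \code{a_channels}, \code{mode}, \code{level}.
#' @export
build_level_split <- function(trace, mode = c("selected", "accumulated"),
                              level) {
  mode <- match.arg(mode)
  lev <- hierarchy_levels()
  if (!level %in% lev) stop("no such hierarchy level: ", level)
  rod <- trace_has_rod(trace)
  if (mode == "selected") {
    a_ch <- level_channels(level)
    w_ch <- level_channels("q", rod)
  } else {
    above <- lev[seq_len(match(level, lev))]
    below <- setdiff(lev, above)
    a_ch <- unlist(lapply(above, level_channels), use.names = FALSE)
    w_ch <- c(unlist(lapply(below, level_channels), use.names = FALSE),
              level_channels("q", rod))
  }
  miss <- setdiff(c(a_ch, w_ch), names(trace))
  if (length(miss)) stop("channels missing from trace: ",
                         paste(miss, collapse = ", "))
  if (!length(a_ch) || !length(w_ch)) stop("empty W or A side of the split")
  structure(list(mode = mode, level = level,
                 w_channels = w_ch, a_channels = a_ch),
            class = "level_split")
}

#' Discretize a trace under a level split
#'
#' Bins the W-group and A-group channels (policy: \code{\link{bins_for_group}})
#' and returns the paired symbol sequences.
#'
#' @param trace A \code{hierarchy_trace}.
#' @param split A \code{level_split}.
#' @param policy A \code{\link{mc_binning_policy}}.
#' @return Object of class \code{discrete_series}: integer sequences \code{w},
#'   \code{a} of equal length, alphabet sizes, bins used, and the trace times.
#' @export
discretize_split <- function(trace, split, policy = mc_binning_policy()) {
  N <- nrow(trace)
  n_total <- length(unlist(lapply(c(hierarchy_levels(), "q"), level_channels,
                                  rod = trace_has_rod(trace))))
  bw <- bins_for_group(length(split$w_channels), N, split$mode, "world",
                       n_total, policy)
  ba <- bins_for_group(length(split$a_channels), N, split$mode, "actuator",
                       n_total, policy)
  dw <- discretize(trace[split$w_channels], bw)
  da <- discretize(trace[split$a_channels], ba)
  structure(list(w = dw$codes, a = da$codes,
                 n_w = dw$alphabet, n_a = da$alphabet,
                 bins_w = bw, bins_a = ba,
                 time = trace$time, split = split),
            class = "discrete_series")
}

#' Estimate the joint distribution p(w', w, a)
#'
#' Frequency estimate over transition triples. For a \code{discrete_series}
#' the triples are the N = T - 1 consecutive pairs (w_{t+1}, w_t, a_t);
#' for a \code{discrete_benchmark} they are its stored independent transition
#' draws. Conditionals are computed on the occupied support only.
#'
#' @param x A \code{discrete_series} or \code{discrete_benchmark}, or a list
#'   with integer vectors \code{w_prime, w, a}.
#' @param window Optional \code{c(t0, t1)}: use only transitions whose source
#'   sample time lies in [t0, t1) (series input only).
#' @return Object of class \code{joint_distribution}: a data.table with one
#'   row per occupied triple (\code{wp, w, a, n, p, p_wwa, p_wa}) plus the
#'   sample count \code{N}.
#' @export
estimate_joint <- function(x, window = NULL) {
  if (inherits(x, "discrete_series")) {
    T <- length(x$w)
    if (T < 2) stop("need at least two samples")
    src <- seq_len(T - 1)
    if (!is.null(window)) {
      src <- src[x$time[src] >= window[1] & x$time[src] < window[2]]
      if (length(src) < 1) stop("empty analysis window")
    }
    tri <- data.table::data.table(wp = x$w[src + 1L], w = x$w[src],
                                  a = x$a[src])
  } else {
    tri <- data.table::data.table(wp = x$w_prime, w = x$w, a = x$a)
  }
  N <- nrow(tri)
  n <- NULL; p <- NULL; wp <- NULL; w <- NULL; a <- NULL  # NSE bindings
  jt <- tri[, list(n = .N), by = list(wp, w, a)]
  jt[, p := n / N]
  jt[, p_wwa := n / sum(n), by = list(w, a)]
  jt[, p_wa := as.numeric(sum(n)), by = list(wp, a)]
  jt[, p_wa := p_wa / sum(n), by = list(a)]
  structure(list(table = jt[], N = N), class = "joint_distribution")
}

#' Morphological computation of an estimated joint
#'
#' Probability-weighted sum of per-triple log-ratios over the occupied
#' support; a KL divergence, hence nonnegative (tiny negative rounding is
#' floored at zero).
#'
#' @param joint A \code{joint_distribution}.
#' @return MC_W in bits.
#' @export
mc_w <- function(joint) {
  jt <- joint$table
  val <- sum(jt$p * log2(jt$p_wwa / jt$p_wa))
  if (val < -1e-9) stop("negative divergence: inconsistent joint")
  max(val, 0)
}

#' State-dependent morphological computation MC_W(t)
#'
#' Per-transition log-ratio log2 p(w_{t+1}|w_t,a_t) / p(w_{t+1}|a_t) along the
#' trajectory; entries may be negative, and their frequency-weighted mean over
#' triples equals the scalar \code{\link{mc_w}}.
#'
#' @param joint A \code{joint_distribution} estimated from \code{series}.
#' @param series The same \code{discrete_series}.
#' @return Numeric vector of length T - 1.
#' @export
mc_w_state_dependent <- function(joint, series) {
  T <- length(series$w)
  tri <- data.table::data.table(wp = series$w[2:T], w = series$w[1:(T - 1)],
                                a = series$a[1:(T - 1)],
                                ord = seq_len(T - 1))
  jt <- joint$table
  m <- merge(tri, jt, by = c("wp", "w", "a"), all.x = TRUE, sort = FALSE)
  if (anyNA(m$p_wwa)) stop("triple absent from the estimated joint support")
  data.table::setorder(m, ord)
  log2(m$p_wwa / m$p_wa)
}

#' MC of one trace at one hierarchy level
#'
#' Convenience pipeline: split, discretize (bin edges over the full trace),
#' estimate the joint (optionally on a time window) and reduce to bits.
#'
#' @param trace A \code{hierarchy_trace}.
#' @param mode,level Split specification.
#' @param window Optional time window \code{c(t0, t1)} for the joint.
#' @param policy A \code{\link{mc_binning_policy}}.
#' @return List of class \code{mc_result}: \code{mc_w} (bits), \code{split},
#'   \code{bins_w}, \code{bins_a}, \code{N}.
#' @export
mc_trace <- function(trace, mode, level, window = NULL,
                     policy = mc_binning_policy()) {
  split <- build_level_split(trace, mode, level)
  series <- discretize_split(trace, split, policy)
  joint <- estimate_joint(series, window = window)
  structure(list(mc_w = mc_w(joint), split = split, N = joint$N,
                 bins_w = series$bins_w, bins_a = series$bins_a),
            class = "mc_result")
}

#' MC of several traces at every hierarchy level
#'
#' @param traces List of \code{hierarchy_trace}.
#' @param mode \code{"selected"} or \code{"accumulated"}.
#' @param window,policy Passed to \code{\link{mc_trace}}.
#' @return Data frame \code{run, level, mc_bits} (levels ordered highest
#'   first), suitable for \code{\link{rm_anova}}.
#' @export
mc_by_level <- function(traces, mode, window = NULL,
                        policy = mc_binning_policy()) {
  lev <- hierarchy_levels()
  out <- expand.grid(run = seq_along(traces), level = lev,
                     stringsAsFactors = FALSE)
  out$mc_bits <- mapply(function(r, l) {
    mc_trace(traces[[r]], mode, l, window, policy)$mc_w
  }, out$run, out$level)
  out$level <- factor(out$level, levels = lev)
  out[order(out$run, out$level), c("run", "level", "mc_bits")]
}
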