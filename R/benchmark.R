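#' Discrete Markov benchmarks with analytically known morphological computation
#'
#' Validation fixtures for the discrete estimator: a world-dynamics kernel
#' alpha(w' | w, a) with known conditional mutual information
#' I(W'; W | A) -- the analytic value the empirical estimator must recover.
#' Samples are drawn i.i.d.-in-transition: each of the \code{T} samples is an
#' independent draw w ~ stationary, a ~ p(a), w' ~ alpha(. | w, a), stored as
#' explicit (w', w, a) triples (a kernel such as w' = w is non-ergodic as a
#' chain, so independent transition draws are the only sampling scheme under
#' which every kind converges to its analytic value).
#'
#' Kinds:
#' \itemize{
#'   \item \code{independent}: alpha(w'|w,a) = alpha(w'|a); analytic value 0.
#'   \item \code{copy_world}: w' = w, uniform stationary W, A independent;
#'     analytic value H(W) = log2 |W| bits.
#'   \item \code{general}: random stochastic kernel (Dirichlet rows) with the
#'     analytic value computed by exhaustive summation over the kernel.
#' }
#'
#' @param kind \code{"independent"}, \code{"copy_world"} or \code{"general"}.
#' @param n_w,n_a Alphabet sizes (>= 2).
#' @param T Number of transition samples (>= 1000).
#' @param seed Integer seed.
#' @return Object of class \code{discrete_benchmark}: integer vectors
#'   \code{w_prime, w, a} (1-based symbols), the generating \code{kernel}
#'   (n_w x n_w x n_a array), \code{p_w} (stationary), \code{p_a}, and
#'   \code{analytic_mc} in bits.
#' @export
generate_discrete_benchmark <- function(kind = c("independent", "copy_world",
                                                 "general"),
                                        n_w = 4, n_a = 4, T = 10000,
                                        seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_w >= 2, n_a >= 2, T >= 1000)
  set.seed(seed)
  kernel <- array(0, c(n_w, n_w, n_a))  # [w', w, a]
  p_a <- rep(1 / n_a, n_a)
  if (kind == "independent") {
    # w' depends on a only: one random column distribution per a
    for (ai in seq_len(n_a)) {
      col <- stats::rgamma(n_w, 1)
      col <- col / sum(col)
      for (wi in seq_len(n_w)) kernel[, wi, ai] <- col
    }
    p_w <- rep(1 / n_w, n_w)
  } else if (kind == "copy_world") {
    for (ai in seq_len(n_a)) kernel[, , ai] <- diag(n_w)
    p_w <- rep(1 / n_w, n_w)
  } else {
    for (ai in seq_len(n_a)) for (wi in seq_len(n_w)) {
      col <- stats::rgamma(n_w, 1)
      kernel[, wi, ai] <- col / sum(col)
    }
    # stationary distribution of the a-averaged chain
    abar <- matrix(0, n_w, n_w)
    for (ai in seq_len(n_a)) abar <- abar + p_a[ai] * kernel[, , ai]
    ev <- eigen(abar)   # columns of abar are alpha(. | w): abar[w', w]
    v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    p_w <- v / sum(v)
  }
  analytic <- kernel_mc(kernel, p_w, p_a)

  w <- sample.int(n_w, T, replace = TRUE, prob = p_w)
  a <- sample.int(n_a, T, replace = TRUE, prob = p_a)
  wp <- integer(T)
  u <- stats::runif(T)
  for (ai in seq_len(n_a)) for (wi in seq_len(n_w)) {
    idx <- which(w == wi & a == ai)
    if (length(idx)) {
      cum <- cumsum(kernel[, wi, ai])
      wp[idx] <- findInterval(u[idx], cum) + 1L
    }
  }
  structure(list(w_prime = wp, w = w, a = a, kernel = kernel,
                 p_w = p_w, p_a = p_a, analytic_mc = analytic,
                 kind = kind, seed = seed),
            class = "discrete_benchmark")
}

#' Analytic morphological computation of a kernel
#'
#' Exhaustive summation of
#' sum p(w) p(a) alpha(w'|w,a) log2[ alpha(w'|w,a) / alpha_tilde(w'|a) ]
#' with alpha_tilde(w'|a) = sum_w p(w) alpha(w'|w,a); i.e. I(W'; W | A) of the
#' joint p(w) p(a) alpha.
#'
#' @param kernel n_w x n_w x n_a array \code{[w', w, a]}.
#' @param p_w,p_a Marginals of W and A (assumed independent).
#' @return Bits, >= 0.
#' @export
kernel_mc <- function(kernel, p_w, p_a) {
  n_w <- dim(kernel)[1]; n_a <- dim(kernel)[3]
  total <- 0
  for (ai in seq_len(n_a)) {
    atilde <- drop(kernel[, , ai] %*% p_w)  # alpha_tilde(w' | a)
    for (wi in seq_len(n_w)) {
      al <- kernel[, wi, ai]
      pos <- al > 0
      total <- total + p_a[ai] * p_w[wi] *
        sum(al[pos] * log2(al[pos] / atilde[pos]))
    }
  }
  max(total, 0)
}
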