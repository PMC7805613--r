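#' Statistical comparison of MC across hierarchy levels
#'
#' The per-run, per-level MC values form a fully repeated design: every
#' simulation run contributes one value to every hierarchy level. Levels are
#' compared with a one-way repeated-measures ANOVA (run as subject, level as
#' within factor), after a Shapiro-Wilk normality screen per level, and
#' followed by pairwise paired t-tests with Bonferroni correction.
#'
#' @name mc_statistics
NULL

# coerce run/level/mc_bits long table; validate the complete repeated design
as_mc_table <- function(table) {
  stopifnot(all(c("run", "level", "mc_bits") %in% names(table)))
  table$run <- factor(table$run)
  table$level <- factor(table$level,
                        levels = intersect(hierarchy_levels(),
                                           unique(as.character(table$level))))
  counts <- table(table$run, table$level)
  if (any(counts != 1)) stop("incomplete repeated design (missing cells)")
  if (nlevels(table$run) < 2) stop("need at least 2 runs")
  table
}

#' Shapiro-Wilk normality screen per hierarchy level
#'
#' @param table Long data frame \code{run, level, mc_bits}.
#' @param alpha Screening level (default 0.1, deliberately liberal to keep
#'   the type-II error of the screen in check).
#' @return Data frame \code{level, n, statistic, p_value, pass}; degenerate
#'   (constant or n < 3) groups have \code{NA} statistics and
#'   \code{pass = NA}. Attribute \code{n_pass} counts passing groups.
#' @export
normality_screen <- function(table, alpha = 0.1) {
  table <- as_mc_table(table)
  res <- lapply(split(table$mc_bits, table$level), function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) {
      return(data.frame(n = length(x), statistic = NA_real_,
                        p_value = NA_real_, pass = NA))
    }
    sw <- stats::shapiro.test(x)
    data.frame(n = length(x), statistic = unname(sw$statistic),
               p_value = sw$p.value, pass = sw$p.value >= alpha)
  })
  out <- do.call(rbind, res)
  out <- cbind(level = names(res), out)
  rownames(out) <- NULL
  attr(out, "n_pass") <- sum(out$pass, na.rm = TRUE)
  out
}

#' One-way repeated-measures ANOVA over hierarchy levels
#'
#' Fits \code{mc_bits ~ level + Error(run/level)} via \code{stats::aov}:
#' F = MS_level / MS_(level x run residual). The Greenhouse-Geisser corrected
#' p-value is reported alongside the uncorrected one (sphericity is not
#' assumed to hold for MC tables).
#'
#' @param table Long data frame \code{run, level, mc_bits}.
#' @return List \code{F, df1, df2, p_value, p_value_gg, ms_level, ms_error};
#'   \code{degenerate = TRUE} with \code{p_value} at the machine minimum when
#'   the residual variance is zero.
#' @export
rm_anova <- function(table) {
  table <- as_mc_table(table)
  fit <- stats::aov(mc_bits ~ level + Error(run / level), data = table)
  sm <- summary(fit)
  tab <- sm[["Error: run:level"]][[1]]
  ms_level <- tab["level", "Mean Sq"]
  ms_error <- tab["Residuals", "Mean Sq"]
  df1 <- tab["level", "Df"]; df2 <- tab["Residuals", "Df"]
  # zero residual variance up to floating-point cancellation
  scale <- max(stats::var(table$mc_bits), .Machine$double.xmin)
  if (!is.finite(ms_error) || ms_error <= 1e-12 * scale) {
    if (ms_level <= 1e-12 * scale) {
      return(list(F = 0, df1 = df1, df2 = df2, p_value = 1, p_value_gg = 1,
                  ms_level = ms_level, ms_error = ms_error,
                  degenerate = TRUE))
    }
    return(list(F = Inf, df1 = df1, df2 = df2,
                p_value = .Machine$double.xmin,
                p_value_gg = .Machine$double.xmin,
                ms_level = ms_level, ms_error = ms_error, degenerate = TRUE))
  }
  Fv <- ms_level / ms_error
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  eps <- gg_epsilon(table)
  p_gg <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  list(F = Fv, df1 = df1, df2 = df2, p_value = p, p_value_gg = p_gg,
       epsilon_gg = eps, ms_level = ms_level, ms_error = ms_error,
       degenerate = FALSE)
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix
gg_epsilon <- function(table) {
  wide <- stats::reshape(table[c("run", "level", "mc_bits")],
                         idvar = "run", timevar = "level",
                         direction = "wide")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  S <- stats::cov(Y)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  eps <- num / den
  min(max(eps, 1 / (k - 1)), 1)
}

#' Pairwise post-hoc comparison with Bonferroni correction
#'
#' Paired two-sided t-tests for every pair of hierarchy levels; raw p-values
#' are multiplied by the number of pairs m (capped at 1). Levels are grouped
#' by non-significant links: two levels share a group label if they are
#' connected by comparisons with adjusted p >= alpha.
#'
#' @param table Long data frame \code{run, level, mc_bits}.
#' @param alpha Significance level for the grouping (default 0.05).
#' @return List: \code{p_adjusted} and \code{p_raw} (symmetric level x level
#'   matrices), \code{m} (number of comparisons), \code{groups} (integer group
#'   id per level).
#' @export
posthoc_bonferroni <- function(table, alpha = 0.05) {
  table <- as_mc_table(table)
  lev <- levels(table$level)
  k <- length(lev)
  wide <- sapply(lev, function(l) table$mc_bits[table$level == l][
    order(table$run[table$level == l])])
  m <- k * (k - 1) / 2
  p_raw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- wide[, i] - wide[, j]
    p <- if (stats::sd(d) == 0) {
      if (all(d == 0)) 1 else 0
    } else {
      stats::t.test(d)$p.value
    }
    p_raw[i, j] <- p_raw[j, i] <- p
  }
  p_adj <- pmin(m * p_raw, 1)
  # connected components of the non-significant-link graph
  adj <- (p_adj >= alpha)
  adj[is.na(adj)] <- FALSE
  diag(adj) <- TRUE
  groups <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (adj[i, j] && groups[j] > groups[i]) {
        groups[j] <- groups[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- as.integer(factor(groups))
  names(groups) <- lev
  list(p_adjusted = p_adj, p_raw = p_raw, m = m, groups = groups,
       alpha = alpha)
}
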