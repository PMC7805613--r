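#' Hierarchy traces
#'
#' A hierarchy trace is a data frame with one row per sample on a uniform time
#' grid and one named column per hierarchy channel, plus metadata in
#' \code{attr(trace, "meta")}. Channels, from the highest control level down:
#' \itemize{
#'   \item \code{u_central}: active EP segment index (1 channel)
#'   \item \code{uo1..uo6, lam1..lam6}: top-down open-loop stimulations and
#'     desired fiber lengths (12 channels)
#'   \item \code{u1..u6}: muscle stimulations (6)
#'   \item \code{a1..a6}: muscle activities (6)
#'   \item \code{fce1..fce6}: fiber forces, N (6)
#'   \item \code{fmtu1..fmtu6}: muscle-tendon forces, N (6)
#'   \item \code{T1, T2}: shoulder/elbow torques, N m (2)
#'   \item \code{q1, q2}: shoulder/elbow angles, rad (2); \code{rod_x}: rod
#'     displacement, m (oscillation runs only)
#' }
#' @name hierarchy_trace
NULL

#' Hierarchy level names, highest first
#' @export
hierarchy_levels <- function() {
  c("u_central", "u_topdown", "u", "a", "F_CE", "F_MTU", "T")
}

#' Channel names of one hierarchy level
#'
#' @param level One of \code{hierarchy_levels()}, or \code{"q"} for the
#'   observable mechanical state.
#' @param rod Include the rod channel in \code{"q"}?
#' @export
level_channels <- function(level, rod = FALSE) {
  switch(level,
    u_central = "u_central",
    u_topdown = c(paste0("uo", 1:6), paste0("lam", 1:6)),
    u     = paste0("u", 1:6),
    a     = paste0("a", 1:6),
    F_CE  = paste0("fce", 1:6),
    F_MTU = paste0("fmtu", 1:6),
    T     = c("T1", "T2"),
    q     = if (rod) c("q1", "q2", "rod_x") else c("q1", "q2"),
    stop("unknown hierarchy level: ", level)
  )
}

new_hierarchy_trace <- function(df, meta) {
  attr(df, "meta") <- meta
  class(df) <- c("hierarchy_trace", "data.frame")
  df
}

#' @export
print.hierarchy_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<hierarchy_trace> %s | %d samples @ %g Hz | rod: %s\n",
              meta$protocol, nrow(x), meta$sample_rate,
              if (isTRUE(meta$rod)) "yes" else "no"))
  utils::str(unclass(x)[1:4], give.attr = FALSE)
  invisible(x)
}

trace_has_rod <- function(trace) isTRUE(attr(trace, "meta")$rod)

#' Write / read a hierarchy trace as CSV
#'
#' Metadata is stored in commented header lines so a written trace round-trips.
#' @param trace A hierarchy trace.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  meta <- attr(trace, "meta")
  keep <- c("protocol", "seed", "f_cpg", "noise_level", "sample_rate", "rod")
  hdr <- vapply(keep, function(k) {
    sprintf("# %s: %s", k, paste(meta[[k]], collapse = " "))
  }, character(1))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(trace, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else if (val %in% c("TRUE", "FALSE"))
      as.logical(val) else val
  }
  df <- utils::read.csv(path, comment.char = "#")
  new_hierarchy_trace(df, meta)
}

# check every producing-module invariant on a finished trace
check_trace_invariants <- function(trace) {
  stopifnot(
    !anyNA(trace),
    all(vapply(trace, function(x) all(is.finite(x)), logical(1)))
  )
  u <- as.matrix(trace[paste0("u", 1:6)])
  a <- as.matrix(trace[paste0("a", 1:6)])
  fmtu <- as.matrix(trace[paste0("fmtu", 1:6)])
  stopifnot(all(u >= 0 & u <= 1), all(a >= 0 & a <= 1), all(fmtu >= -1e-9))
  invisible(TRUE)
}
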