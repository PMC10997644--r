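#' Sufficient statistics of a type-I censored labeled sample
#'
#' The censored likelihood of the 3-component power mixture depends on the
#' data only through the counts of observed failures per component
#' (`u1`, `u2`, `u3`), the per-component sums \eqn{S_m = \sum_w
#' \ln(1/y_{mw})} over observed values, the total number of test units `n`,
#' and the censor time through \eqn{\ln(1/t)}.  This constructor validates
#' and stores exactly those statistics.
#'
#' @param n Total number of units on test.
#' @param log_inv_t \eqn{\ln(1/t) \ge 0}; on the negative-log scale this is
#'   the censor time itself.
#' @param u1,u2,u3 Observed failure counts per component.
#' @param S1,S2,S3 Per-component sums of \eqn{\ln(1/y)} over observed values.
#' @return An object of class `censored_summary`.
#' @seealso [summarize_censored()] to compute the statistics from raw data,
#'   [read_censored_summary()] / [write_censored_summary()] for file I/O,
#'   [kevlar_summary()] for the packaged benchmark summary.
#' @export
censored_summary <- function(n, log_inv_t, u1, u2, u3, S1, S2, S3) {
  u <- c(u1, u2, u3)
  S <- c(S1, S2, S3)
  stopifnot(length(n) == 1, length(log_inv_t) == 1,
            is.numeric(u), is.numeric(S), length(u) == 3, length(S) == 3)
  if (n < 0 || n != round(n)) stop("n must be a nonnegative integer count")
  if (any(u < 0) || any(u != round(u))) stop("u1..u3 must be nonnegative counts")
  if (sum(u) > n) stop("u1 + u2 + u3 must not exceed n")
  if (!is.finite(log_inv_t) || log_inv_t < 0)
    stop("log_inv_t must be a nonnegative real (ln(1/t) for t in (0,1])")
  if (any(!is.finite(S)) || any(S < 0)) stop("S1..S3 must be nonnegative reals")
  if (any((S == 0) != (u == 0)))
    stop("S_m must be zero exactly when u_m is zero")
  structure(list(n = as.integer(n), log_inv_t = as.numeric(log_inv_t),
                 u = as.integer(u), S = as.numeric(S)),
            class = "censored_summary")
}

#' @export
print.censored_summary <- function(x, ...) {
  cat("Type-I censored sample summary\n")
  cat(sprintf("  n = %d, observed u = %d, censored n - u = %d\n",
              x$n, sum(x$u), x$n - sum(x$u)))
  cat(sprintf("  ln(1/t) = %g\n", x$log_inv_t))
  for (m in 1:3)
    cat(sprintf("  component %d: u%d = %d, S%d = %g\n", m, m, x$u[m], m, x$S[m]))
  invisible(x)
}

#' Summarize labeled lifetime data under type-I censoring
#'
#' Reduces labeled lifetimes to the sufficient statistics used by
#' [build_posterior()].  Data may be given on the unit scale (values
#' \eqn{y \in (0,1)}, censor time \eqn{t \in (0,1)}) or on the negative-log
#' scale (\eqn{x = \ln(1/y) > 0}, censor time \eqn{t_x > 0}); internally the
#' censor time is stored as \eqn{\ln(1/t)}.  Censoring removes the largest
#' values on the observation scale: on the unit scale a unit is observed iff
#' \eqn{y \le t}, on the negative-log scale iff \eqn{x \le t_x} (exact ties
#' count as observed on either scale; note the two rules censor opposite
#' tails of \eqn{y}, because \eqn{x = \ln(1/y)} reverses order).  Censored
#' units only increment the censored count; their component labels are
#' ignored (with a message), matching the pooled survival factor of the
#' likelihood.
#'
#' @param data A data frame with columns `component` (1, 2 or 3) and
#'   `value`.
#' @param censor_time Test termination time on the scale of `value`.
#' @param scale `"unit"` or `"neglog"`.
#' @param quiet Suppress the notice about ignored censored-unit labels.
#' @return A [censored_summary()].
#' @examples
#' d <- data.frame(component = c(1, 2), value = c(0.5, 0.95))
#' summarize_censored(d, censor_time = 0.9)
#' @export
summarize_censored <- function(data, censor_time,
                               scale = c("unit", "neglog"), quiet = FALSE) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(data), all(c("component", "value") %in% names(data)))
  comp <- data$component
  val <- data$value
  if (any(!comp %in% 1:3)) stop("component labels must be 1, 2 or 3")
  if (length(censor_time) != 1 || !is.finite(censor_time) || censor_time <= 0)
    stop("censor_time must be a single positive number")
  if (scale == "unit") {
    if (any(val <= 0 | val >= 1))
      stop("unit-scale values must lie strictly inside (0, 1)")
    if (censor_time >= 1)
      stop("unit-scale censor_time >= 1 leaves nothing censored; ",
           "use a value just below 1 instead")
    x <- log(1 / val)
    log_inv_t <- log(1 / censor_time)
    observed <- val <= censor_time # greatest y censored; ties observed
  } else {
    if (any(val <= 0)) stop("negative-log-scale values must be positive")
    x <- val
    log_inv_t <- censor_time
    observed <- x <= censor_time # greatest x censored; ties observed
  }
  if (!quiet && any(!observed))
    message(sum(!observed), " censored unit(s): component labels ignored")
  u <- S <- numeric(3)
  for (m in 1:3) {
    keep <- observed & comp == m
    u[m] <- sum(keep)
    S[m] <- sum(x[keep])
  }
  censored_summary(n = length(x), log_inv_t = log_inv_t,
                   u1 = u[1], u2 = u[2], u3 = u[3],
                   S1 = S[1], S2 = S[2], S3 = S[3])
}

#' Read or write a censored-sample summary file
#'
#' Plain-text key-value format, one `key: value` pair per line, with keys
#' `n`, `log_inv_t`, `u1`..`u3`, `S1`..`S3`.  This is the format of the
#' packaged Kevlar benchmark fixture.
#'
#' @param path File path.
#' @return `read_censored_summary()` returns a [censored_summary()];
#'   `write_censored_summary()` returns `path` invisibly.
#' @export
read_censored_summary <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed summary file at line(s): ",
         paste(which(bad), collapse = ", "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  need <- c("n", "log_inv_t", "u1", "u2", "u3", "S1", "S2", "S3")
  if (!all(need %in% keys))
    stop("summary file missing key(s): ",
         paste(setdiff(need, keys), collapse = ", "))
  v <- setNames(vals, keys)[need]
  censored_summary(v[["n"]], v[["log_inv_t"]], v[["u1"]], v[["u2"]], v[["u3"]],
                   v[["S1"]], v[["S2"]], v[["S3"]])
}

#' @rdname read_censored_summary
#' @param x A [censored_summary()].
#' @export
write_censored_summary <- function(x, path) {
  stopifnot(inherits(x, "censored_summary"))
  lines <- c(sprintf("n: %d", x$n),
             sprintf("log_inv_t: %.17g", x$log_inv_t),
             sprintf("u%d: %d", 1:3, x$u),
             sprintf("S%d: %.17g", 1:3, x$S))
  writeLines(lines, path)
  invisible(path)
}

#' Read labeled lifetime data
#'
#' Comma- or tab-delimited text with a header row naming at least
#' `component` and `value`.
#'
#' @param path File path.
#' @return A data frame with columns `component` and `value`.
#' @export
read_labeled_data <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- read.table(path, header = TRUE, sep = sep, strip.white = TRUE)
  if (!all(c("component", "value") %in% names(d)))
    stop("data file must have header columns 'component' and 'value'")
  if (anyNA(d$component) || anyNA(d$value)) {
    bad <- which(is.na(d$component) | is.na(d$value))
    stop("unparseable data at line(s): ", paste(bad + 1L, collapse = ", "))
  }
  d[c("component", "value")]
}

#' The Kevlar fatigue-fracture benchmark summary
#'
#' Sufficient statistics of the classic Kevlar 373/epoxy fatigue-fracture
#' lifetimes (76 units, grouped into three subpopulations), censored at 3.4
#' on the negative-log scale: n = 76, u = (22, 22, 21),
#' S = (31.2771, 32.3513, 30.1508), ln(1/t) = 3.4.  Shipped as a plain-text
#' fixture in `inst/extdata/kevlar_summary.txt`.
#'
#' @return A [censored_summary()].
#' @export
kevlar_summary <- function() {
  read_censored_summary(system.file("extdata", "kevlar_summary.txt",
                                    package = "cmpd3", mustWork = TRUE))
}
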