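#' Confidence interval of a per-condition feature mean
#'
#' Two-sided normal-theory interval for the mean with known population
#' variance: `mean +/- z * sqrt(variance / n)` with
#' `z = qnorm(1 - (1 - confidence) / 2)`. The exact quantile is used (e.g.
#' 2.5758... at the 0.99 level), not its two-decimal rounding.
#'
#' @param n sample size (>= 1).
#' @param mean sample mean, feature units.
#' @param variance population variance, feature units squared (>= 0).
#' @param confidence confidence level in (0, 1); default 0.99.
#' @param label optional condition name carried through.
#' @return list of class `interval_estimate` with `lo`, `hi`, `mean`, `n`,
#'   `confidence`, `label`.
#' @examples
#' confidence_interval(n = 5, mean = 3536.71, variance = 1611045.74)
#' @export
confidence_interval <- function(n, mean, variance, confidence = 0.99,
                                label = NULL) {
  if (is.list(n) && is.null(dim(n))) {   # allow a summary-style list
    s <- n
    return(confidence_interval(s$n, s$mean, s$variance,
                               s$confidence %||% 0.99, s$label))
  }
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop_input("confidence_interval: n must be a single integer >= 1")
  if (!is.finite(variance) || variance < 0)
    stop_input("confidence_interval: variance must be >= 0")
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1)
    stop_input("confidence_interval: confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  half <- z * sqrt(variance / n)
  structure(list(lo = mean - half, hi = mean + half, mean = mean,
                 n = as.integer(n), confidence = confidence, label = label),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("<interval_estimate>%s %.2f < mu < %.2f  (mean %.2f, n %d, %g%%)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$lo, x$hi, x$mean, x$n, 100 * x$confidence))
  invisible(x)
}

#' Convert calibration intervals into membership functions
#'
#' Implements the calibration rule that the confidence interval of a
#' condition's feature mean represents full (degree-1) membership of that
#' condition's set: each interval becomes the plateau `[b, c]` of a
#' trapezoid. Shoulders fall linearly to the adjacent interval's near edge,
#' so neighboring sets cross between their plateaus; the outermost shoulders
#' fall to the universe bounds. If two plateaus overlap, both are truncated
#' at the midpoint of the overlap and a warning is raised.
#'
#' @param intervals list of `interval_estimate` objects (or lists with `lo`,
#'   `hi`, `label`), ordered by mean.
#' @param universe numeric `[lo, hi]` covering all intervals.
#' @param name variable name for the result.
#' @return a [fuzzy_variable] whose sets give membership 1 on every
#'   calibration interval.
#' @export
intervals_to_membership <- function(intervals, universe, name = "calibrated") {
  stopifnot(length(intervals) >= 1)
  lo <- vapply(intervals, function(iv) iv$lo, numeric(1))
  hi <- vapply(intervals, function(iv) iv$hi, numeric(1))
  labels <- vapply(seq_along(intervals), function(i)
    intervals[[i]]$label %||% paste0("set", i), "")
  if (is.unsorted(lo) || is.unsorted(hi))
    stop_input("intervals must be ordered by location")
  if (universe[1] > min(lo) || universe[2] < max(hi))
    stop_input("universe does not cover the calibration intervals")
  k <- length(intervals)
  # Truncate overlapping plateaus at the midpoint of their overlap.
  for (i in seq_len(k - 1)) {
    if (hi[i] > lo[i + 1]) {
      mid <- (hi[i] + lo[i + 1]) / 2
      warning(sprintf("plateaus of '%s' and '%s' overlap; truncated at %g",
                      labels[i], labels[i + 1], mid), call. = FALSE)
      hi[i] <- mid; lo[i + 1] <- mid
    }
  }
  sets <- vector("list", k)
  for (i in seq_len(k)) {
    b <- lo[i]
    c2 <- hi[i]
    a <- if (i == 1) universe[1] else hi[i - 1]   # foot on previous near edge
    d <- if (i == k) universe[2] else lo[i + 1]
    sets[[i]] <- fuzzy_set(labels[i], "trapezoid",
                           c(min(a, b), b, c2, max(d, c2)))
  }
  fuzzy_variable(name, universe, sets)
}

#' Calibrate a fuzzy variable from a summary table
#'
#' Reads per-condition sample summaries (columns `label`, `n`, `mean`,
#' `variance`, optional `confidence`, default 0.99), computes
#' [confidence_interval()]s, and converts them into a [fuzzy_variable] via
#' [intervals_to_membership()]. Optionally writes the result as a config
#' fragment with [write_variable_config()].
#'
#' @param summaries data frame, or path to a CSV with those columns.
#' @param universe numeric `[lo, hi]`.
#' @param name variable name.
#' @param out optional output path for the config fragment.
#' @return the calibrated [fuzzy_variable] (invisibly if `out` is given).
#' @export
calibrate_variable <- function(summaries, universe, name = "calibrated",
                               out = NULL) {
  if (is.character(summaries)) {
    if (!file.exists(summaries)) stop_input(paste("file not found:", summaries))
    summaries <- utils::read.csv(summaries, stringsAsFactors = FALSE)
  }
  need <- c("label", "n", "mean", "variance")
  if (!all(need %in% names(summaries)))
    stop_input(paste("calibration table needs columns:", paste(need, collapse = ", ")))
  if ("confidence" %in% names(summaries)) conf <- summaries$confidence
  else conf <- rep(0.99, nrow(summaries))
  ord <- order(summaries$mean)
  summaries <- summaries[ord, ]; conf <- conf[ord]
  ivs <- lapply(seq_len(nrow(summaries)), function(i)
    confidence_interval(summaries$n[i], summaries$mean[i],
                        summaries$variance[i], conf[i], summaries$label[i]))
  v <- intervals_to_membership(ivs, universe, name = name)
  if (!is.null(out)) {
    write_variable_config(v, out)
    return(invisible(v))
  }
  v
}
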