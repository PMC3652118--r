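#' Piecewise-linear fuzzy set
#'
#' Constructs a triangular or trapezoidal membership function over a
#' one-dimensional universe. Breakpoints are given in universe units:
#' `(a, b, c)` for a triangle (membership 1 at `b`) or `(a, b, c, d)` for a
#' trapezoid (membership 1 on the plateau `[b, c]`). Membership is 0 outside
#' the support and piecewise-linear in between. Degenerate edges (`a == b` or
#' `c == d`) give vertical shoulders, e.g. a set that is fully on at the
#' universe boundary.
#'
#' @param label character, linguistic label of the set (e.g. `"young"`).
#' @param shape `"triangle"` or `"trapezoid"`.
#' @param params numeric breakpoints, length 3 (triangle) or 4 (trapezoid),
#'   non-decreasing.
#' @return an object of class `fuzzy_set`.
#' @examples
#' young <- fuzzy_set("young", "trapezoid", c(10, 15, 18, 22))
#' membership(young, c(9, 16, 20))
#' @export
fuzzy_set <- function(label, shape = c("triangle", "trapezoid"), params) {
  shape <- match.arg(shape)
  params <- as.numeric(params)
  n_expect <- if (shape == "triangle") 3L else 4L
  if (length(params) != n_expect)
    stop_config(sprintf("set '%s': %s needs %d breakpoints, got %d",
                        label, shape, n_expect, length(params)))
  if (any(!is.finite(params)))
    stop_config(sprintf("set '%s': non-finite breakpoints", label))
  if (is.unsorted(params))
    stop_config(sprintf("set '%s': breakpoints must be non-decreasing: %s",
                        label, paste(params, collapse = " ")))
  structure(list(label = as.character(label), shape = shape, params = params),
            class = "fuzzy_set")
}

#' Membership degree of crisp values in a fuzzy set
#'
#' Evaluates the piecewise-linear membership function of a [fuzzy_set] at the
#' given crisp values.
#'
#' @param set a `fuzzy_set`.
#' @param x numeric vector of crisp values (finite).
#' @return numeric vector of degrees in `[0, 1]`, same length as `x`.
#' @export
membership <- function(set, x) {
  stopifnot(inherits(set, "fuzzy_set"))
  if (any(!is.finite(x))) stop_input("membership: x must be finite")
  p <- set$params
  if (set$shape == "triangle") {
    a <- p[1]; b <- p[2]; c2 <- p[2]; d <- p[3]
  } else {
    a <- p[1]; b <- p[2]; c2 <- p[3]; d <- p[4]
  }
  mu <- numeric(length(x))
  mu[x >= b & x <= c2] <- 1
  rise <- x > a & x < b
  if (any(rise)) mu[rise] <- (x[rise] - a) / (b - a)
  fall <- x > c2 & x < d
  if (any(fall)) mu[fall] <- (d - x[fall]) / (d - c2)
  mu
}

# Support [lo, hi] of a set: where membership can be > 0 (closed hull).
set_support <- function(set) {
  p <- set$params
  c(p[1], p[length(p)])
}

# Core of a set: where membership is 1.
set_core <- function(set) {
  p <- set$params
  if (set$shape == "triangle") c(p[2], p[2]) else c(p[2], p[3])
}

#' @export
print.fuzzy_set <- function(x, ...) {
  cat(sprintf("<fuzzy_set> %s: %s (%s)\n", x$label, x$shape,
              paste(x$params, collapse = " ")))
  invisible(x)
}

#' Linguistic fuzzy variable
#'
#' A named variable over a closed universe, partitioned into an ordered list
#' of fuzzy sets. Set order is meaningful: later sets are treated as more
#' severe when classification ties must be broken.
#'
#' @param name character variable name (e.g. `"DN"`).
#' @param universe numeric length-2, closed interval `[lo, hi]` in the
#'   variable's units.
#' @param sets list of [fuzzy_set] objects whose supports lie within the
#'   universe.
#' @return an object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, universe, sets) {
  universe <- as.numeric(universe)
  if (length(universe) != 2 || universe[1] >= universe[2])
    stop_config(sprintf("variable '%s': universe must be [lo, hi], lo < hi", name))
  if (length(sets) < 1) stop_config(sprintf("variable '%s': needs at least one set", name))
  for (s in sets) {
    if (!inherits(s, "fuzzy_set")) stop_config("sets must be fuzzy_set objects")
    sup <- set_support(s)
    if (sup[1] < universe[1] - 1e-9 || sup[2] > universe[2] + 1e-9)
      stop_config(sprintf("variable '%s': set '%s' support [%g, %g] outside universe [%g, %g]",
                          name, s$label, sup[1], sup[2], universe[1], universe[2]))
  }
  labels <- vapply(sets, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop_config(sprintf("variable '%s': duplicate set labels", name))
  names(sets) <- labels
  structure(list(name = as.character(name), universe = universe, sets = sets),
            class = "fuzzy_variable")
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("<fuzzy_variable> %s on [%g, %g], %d sets: %s\n",
              x$name, x$universe[1], x$universe[2], length(x$sets),
              paste(names(x$sets), collapse = ", ")))
  invisible(x)
}

var_labels <- function(variable) names(variable$sets)

#' Fuzzify a crisp value
#'
#' Evaluates every set of a variable at a crisp value, returning one degree
#' per linguistic label. Values outside the universe are clamped to it with a
#' warning. If the value falls in a hairline gap where every set evaluates to
#' zero (the shipped configurations contain such gaps between printed
#' intervals, e.g. between 0.5 and 0.51), the value is snapped just inside
#' the nearest set support and a warning is raised.
#'
#' @param variable a [fuzzy_variable].
#' @param x single crisp value.
#' @return named numeric vector of degrees in `[0, 1]`, one per set label.
#' @export
fuzzify <- function(variable, x) {
  stopifnot(inherits(variable, "fuzzy_variable"), length(x) == 1, is.finite(x))
  lo <- variable$universe[1]; hi <- variable$universe[2]
  if (x < lo || x > hi) {
    warning(sprintf("%s = %g outside universe [%g, %g]; clamped",
                    variable$name, x, lo, hi), call. = FALSE)
    x <- min(max(x, lo), hi)
  }
  deg <- vapply(variable$sets, membership, numeric(1), x = x)
  if (all(deg == 0)) {
    # Hairline coverage gap: snap just inside the nearest support boundary.
    snapped <- snap_into_support(variable, x)
    warning(sprintf("%s = %g lies in a coverage gap; snapped to %g",
                    variable$name, x, snapped), call. = FALSE)
    deg <- vapply(variable$sets, membership, numeric(1), x = snapped)
  }
  deg
}

# Nearest point with positive membership in some set: the closest support
# edge nudged inward by a hair (1e-9 of the universe span).
snap_into_support <- function(variable, x) {
  eps <- 1e-9 * diff(variable$universe)
  best <- x; best_d <- Inf
  for (s in variable$sets) {
    sup <- set_support(s)
    cand <- c(sup[1] + eps, sup[2] - eps)
    for (p in cand) {
      if (membership(s, p) > 0 && abs(p - x) < best_d) {
        best <- p; best_d <- abs(p - x)
      }
    }
    # If x is already inside the closed support but scored 0 (degenerate),
    # the core midpoint is a safe target.
    core <- set_core(s)
    if (x >= sup[1] && x <= sup[2] && abs(mean(core) - x) < best_d) {
      best <- mean(core); best_d <- abs(mean(core) - x)
    }
  }
  best
}
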