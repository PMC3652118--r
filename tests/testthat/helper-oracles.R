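# Independent oracles, deliberately implemented through different code
# paths than the package internals.

# Membership via linear interpolation of the breakpoint polygon.
oracle_set_fun <- function(set) {
  p <- set$params
  if (set$shape == "triangle") {
    xs <- p; ys <- c(0, 1, 0)
  } else {
    xs <- p; ys <- c(0, 1, 1, 0)
  }
  stats::approxfun(xs, ys, yleft = 0, yright = 0, ties = max)
}

# Centroid of the aggregated output surface by pracma::trapz integration.
oracle_centroid <- function(output, activations, n = 100001L,
                            implication = "min") {
  x <- seq(output$universe[1], output$universe[2], length.out = n)
  mu <- numeric(n)
  for (lab in names(activations)) {
    a <- activations[[lab]]
    if (a <= 0) next
    m <- oracle_set_fun(output$sets[[lab]])(x)
    m <- if (implication == "prod") m * a else pmin(m, a)
    mu <- pmax(mu, m)
  }
  pracma::trapz(x, mu * x) / pracma::trapz(x, mu)
}

# Random output variable with non-overlapping ordered trapezoid/triangle
# sets, plus random activations; for defuzzification cross-checks.
random_defuzz_case <- function() {
  u <- sort(stats::runif(2, 0, 100))
  while (diff(u) < 5) u <- sort(stats::runif(2, 0, 100))
  k <- sample(1:4, 1)
  sets <- vector("list", k)
  for (i in seq_len(k)) {
    bp <- sort(stats::runif(4, u[1], u[2]))
    if (stats::runif(1) < 0.5) {
      sets[[i]] <- fuzzy_set(paste0("s", i), "triangle", bp[1:3])
    } else {
      sets[[i]] <- fuzzy_set(paste0("s", i), "trapezoid", bp)
    }
  }
  v <- fuzzy_variable("out", u, sets)
  act <- stats::runif(k)
  act[sample(k, sample(0:(k - 1), 1))] <- 0    # some sets silent
  if (all(act <= 0.05)) act[sample(k, 1)] <- stats::runif(1, 0.2, 1)
  list(variable = v, activations = stats::setNames(as.list(act),
                                                   paste0("s", seq_len(k))))
}

# Brute-force per-pixel accumulation of mean area / mean staining over
# ground-truth masks (explicit pixel loop; no vectorized shortcuts).
oracle_features <- function(stain, labels) {
  n <- max(labels)
  area <- numeric(n); ssum <- numeric(n)
  for (r in seq_len(nrow(labels))) {
    for (c2 in seq_len(ncol(labels))) {
      id <- labels[r, c2]
      if (id > 0) {
        area[id] <- area[id] + 1
        ssum[id] <- ssum[id] + stain[r, c2]
      }
    }
  }
  list(DN = mean(area), TN = mean(ssum / area), areas = area)
}

# Rule-space size by explicit nested looping over per-input label lists.
oracle_rule_space_size <- function(model) {
  count <- 0L
  recurse <- function(depth) {
    if (depth > length(model$inputs)) {
      count <<- count + 1L
      return(invisible())
    }
    for (lab in names(model$inputs[[depth]]$sets)) recurse(depth + 1L)
  }
  recurse(1L)
  count
}
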