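# Synthetic cytology-field generator. Renders dark elliptical nuclei (with
# optional darker interior nucleolus spots) on a lighter cytoplasm
# background, with pixel-level ground truth, so the whole pipeline is
# testable without patient material. Nuclei are darkest in the green
# channel; per-nucleus gray levels are chosen so the inverted-grayscale
# staining convention lands drawn staining values on the 50-150 TN scale.

#' Specification of a synthetic cytology image
#'
#' @param width,height frame size in pixels.
#' @param n_nuclei number of nuclei to place (non-overlapping).
#' @param area_mean,area_sd normal distribution of nucleus areas, pixels.
#' @param ecc_mean,ecc_sd normal distribution of eccentricities, clamped to
#'   `[0, 0.97]`.
#' @param staining_mean,staining_sd normal distribution of nucleus staining
#'   on the 50-150 TN scale (higher = darker), clamped to it.
#' @param nucleoli per-nucleus nucleolus count: a single count or `c(lo,
#'   hi)` for a uniform integer draw.
#' @param background_level background gray level on `[0, 255]`.
#' @param noise_sd Gaussian pixel noise standard deviation (gray levels).
#' @param seed integer RNG seed; the render is fully reproducible from it.
#' @return list of class `image_spec`.
#' @export
image_spec <- function(width = 512, height = 512, n_nuclei = 5,
                       area_mean = 3500, area_sd = 600,
                       ecc_mean = 0.6, ecc_sd = 0.03,
                       staining_mean = 65, staining_sd = 3,
                       nucleoli = 2, background_level = 200,
                       noise_sd = 3, seed = 1L) {
  stopifnot(width >= 1, height >= 1, n_nuclei >= 0, area_mean > 0,
            area_sd >= 0, noise_sd >= 0)
  if (n_nuclei * (area_mean + 3 * area_sd) > 0.3 * width * height)
    stop_input("image_spec: total nucleus area exceeds 30% of the frame")
  structure(as.list(environment()), class = "image_spec")
}

# Gray level realizing a staining value under the inverted-grayscale
# convention, and an RGB triple with that luminance, green channel darkest.
staining_to_gray <- function(s) 255 - s * 255 / 150

rgb_for_gray <- function(g) {
  r <- clamp(g + 12, 0, 255)
  b <- clamp(g + 20, 0, 255)
  green <- clamp((g - 0.299 * r - 0.114 * b) / 0.587, 0, 255)
  c(r, green, b)
}

# Pixel coverage of a rotated ellipse over a bounding box, by 3x3
# supersampling of pixel centers.
ellipse_coverage <- function(rows, cols, cy, cx, a, b, theta) {
  off <- c(-1, 0, 1) / 3
  cov <- matrix(0, length(rows), length(cols))
  ct <- cos(theta); st <- sin(theta)
  for (oy in off) for (ox in off) {
    dy <- outer(rows + oy - cy, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols + ox - cx)
    u <- (dx * ct + dy * st) / a
    v <- (-dx * st + dy * ct) / b
    cov <- cov + (u * u + v * v <= 1)
  }
  cov / 9
}

#' Generate a synthetic cytology image with ground truth
#'
#' Places non-overlapping rotated ellipses by rejection sampling, renders
#' them with anti-aliased (supersampled-coverage) edges over a lighter
#' background, plants darker interior nucleolus spots, and adds Gaussian
#' pixel noise. The returned ground truth stores, per nucleus, the
#' rasterized mask label, the pixel area of the mask, the drawn analytic
#' area and eccentricity, the rendered mean staining over the mask, and the
#' planted nucleolus count.
#'
#' @param spec an [image_spec()].
#' @return list with `image` (`[row, col, 3]` array on `[0, 255]`, 8-bit
#'   values) and `truth` (list: `labels` matrix, `table` data frame).
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  n <- spec$n_nuclei

  params <- vector("list", n)
  placed <- matrix(numeric(0), ncol = 3)   # cy, cx, clearance radius
  for (i in seq_len(n)) {
    A <- clamp(stats::rnorm(1, spec$area_mean, spec$area_sd),
               max(150, spec$area_mean - 3 * spec$area_sd),
               spec$area_mean + 3 * spec$area_sd)
    e <- clamp(stats::rnorm(1, spec$ecc_mean, spec$ecc_sd), 0, 0.97)
    s <- clamp(stats::rnorm(1, spec$staining_mean, spec$staining_sd), 50, 150)
    ratio <- sqrt(1 - e^2)
    a <- sqrt(A / (pi * ratio)); b <- A / (pi * a)
    theta <- stats::runif(1, 0, pi)
    k <- if (length(spec$nucleoli) == 2)
      sample(spec$nucleoli[1]:spec$nucleoli[2], 1) else spec$nucleoli
    ok <- FALSE
    for (try in 1:1000) {
      cy <- stats::runif(1, a + 2, H - a - 2)
      cx <- stats::runif(1, a + 2, W - a - 2)
      clear <- a + 4                       # half of an 8-px inter-nucleus gap
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                placed[, 3] + clear)) {
        placed <- rbind(placed, c(cy, cx, clear))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_compute(sprintf("could not place nucleus %d without overlap", i))
    params[[i]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta,
                        area_drawn = A, ecc_drawn = e, staining_drawn = s,
                        n_nucleoli = k)
  }

  bg <- rgb_for_gray(spec$background_level)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  labels <- matrix(0L, H, W)

  for (i in seq_len(n)) {
    p <- params[[i]]
    r0 <- max(1, floor(p$cy - p$a - 2)); r1 <- min(H, ceiling(p$cy + p$a + 2))
    c0 <- max(1, floor(p$cx - p$a - 2)); c1 <- min(W, ceiling(p$cx + p$a + 2))
    rows <- r0:r1; cols <- c0:c1
    cov <- ellipse_coverage(rows, cols, p$cy, p$cx, p$a, p$b, p$theta)
    nuc <- rgb_for_gray(staining_to_gray(p$staining_drawn))
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      img[rows, cols, ch] <- cov * nuc[ch] + (1 - cov) * sub
    }
    labels[rows, cols][cov >= 0.5] <- i

    # nucleolus spots: darker discs well inside the ellipse
    if (p$n_nucleoli > 0) {
      spot_gray <- max(10, staining_to_gray(p$staining_drawn) - 60)
      spot_rgb <- rgb_for_gray(spot_gray)
      centers <- matrix(numeric(0), ncol = 3)
      for (sp in seq_len(p$n_nucleoli)) {
        for (try in 1:100) {
          ang <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1)) * 0.55
          ux <- rad * cos(ang) * p$a; uy <- rad * sin(ang) * p$b
          scy <- p$cy + ux * sin(p$theta) + uy * cos(p$theta)
          scx <- p$cx + ux * cos(p$theta) - uy * sin(p$theta)
          srad <- stats::runif(1, 2.2, 3.2)
          if (nrow(centers) == 0 ||
              all(sqrt((centers[, 1] - scy)^2 + (centers[, 2] - scx)^2) >
                    centers[, 3] + srad + 2)) {
            centers <- rbind(centers, c(scy, scx, srad))
            break
          }
        }
      }
      for (sp in seq_len(nrow(centers))) {
        scy <- centers[sp, 1]; scx <- centers[sp, 2]; srad <- centers[sp, 3]
        sr <- max(1, floor(scy - srad - 1)):min(H, ceiling(scy + srad + 1))
        sc <- max(1, floor(scx - srad - 1)):min(W, ceiling(scx + srad + 1))
        scov <- ellipse_coverage(sr, sc, scy, scx, srad, srad, 0)
        for (ch in 1:3) {
          sub <- img[sr, sc, ch]
          img[sr, sc, ch] <- scov * spot_rgb[ch] + (1 - scov) * sub
        }
      }
      params[[i]]$n_nucleoli <- nrow(centers)
    }
  }

  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- round(clamp(img, 0, 255))

  stain <- staining_raster(to_grayscale(img))
  areas <- tabulate(labels[labels > 0], n)
  ms <- if (n > 0) region_means(stain, labels) else numeric(0)
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- params[[i]]
    data.frame(id = i, area = areas[i], area_drawn = p$area_drawn,
               eccentricity_drawn = p$ecc_drawn,
               staining_drawn = p$staining_drawn,
               mean_staining = ms[i],
               nucleolus_count = p$n_nucleoli,
               centroid_row = p$cy - 1, centroid_col = p$cx - 1)
  }))
  if (is.null(tab))
    tab <- data.frame(id = integer(0), area = numeric(0), area_drawn = numeric(0),
                      eccentricity_drawn = numeric(0), staining_drawn = numeric(0),
                      mean_staining = numeric(0), nucleolus_count = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  list(image = img, truth = list(labels = labels, table = tab))
}

# Frame side (multiple of 16) at which n nuclei of the given maximum area
# and eccentricity pack comfortably: rejection sampling separates nuclei by
# their bounding circles (radius = major semi-axis), so the packing budget
# uses the bounding-circle area A / sqrt(1 - e^2), kept under 25% fill.
frame_side <- function(n, area_max, ecc = 0) {
  eff <- area_max / sqrt(1 - ecc^2)
  16 * ceiling(sqrt(n * eff / 0.25) / 16)
}

#' Printed calibration summaries for mean nucleus area
#'
#' The per-condition (Small / Medium / Large) sample summaries used to
#' calibrate the DN membership plateaus: sample size, sample mean,
#' population variance, and confidence level.
#'
#' @return data frame with columns `label`, `n`, `mean`, `variance`,
#'   `confidence`.
#' @export
table_dn_calibration <- function() {
  data.frame(label = c("small", "medium", "large"),
             n = c(5L, 5L, 8L),
             mean = c(3536.71, 7658.24, 13747.13),
             variance = c(1611045.74, 2283910.70, 17225203.65),
             confidence = 0.99)
}

#' Image specs for the calibrated area regimes
#'
#' Builds an [image_spec()] whose nucleus areas are drawn from the
#' published per-condition distribution (mean and population variance of
#' [table_dn_calibration()]), with the per-condition sample size as the
#' nucleus count. The frame is sized so total nucleus area stays under 30%.
#'
#' @param regime `"small"`, `"medium"` or `"large"`.
#' @param seed RNG seed.
#' @return an [image_spec()].
#' @export
regime_image_spec <- function(regime = c("small", "medium", "large"), seed = 1L) {
  regime <- match.arg(regime)
  cal <- table_dn_calibration()
  row <- cal[cal$label == regime, ]
  sdv <- sqrt(row$variance)
  side <- frame_side(row$n, row$mean + 3 * sdv, ecc = 0.6)
  image_spec(width = side, height = side, n_nuclei = row$n,
             area_mean = row$mean, area_sd = sdv,
             ecc_mean = 0.6, ecc_sd = 0.02,
             staining_mean = 65, staining_sd = 2,
             nucleoli = 2, noise_sd = 3, seed = seed)
}

#' Image specs for the three diagnostic fixture regimes
#'
#' Feature regimes whose measured morphometry lands crisply in the Normal,
#' AGC, and Positive-to-malignity operating regions of the injury-resolution
#' model: Normal = small pale round nuclei with a few visible nucleoli; AGC
#' = medium-sized, moderately stained, elongated nuclei with nucleoli;
#' Positive = large dark elongated nuclei whose nucleoli are masked by the
#' hyperchromatic staining.
#'
#' @param case `"normal"`, `"agc"` or `"positive"`.
#' @param seed RNG seed.
#' @return an [image_spec()].
#' @export
diagnosis_image_spec <- function(case = c("normal", "agc", "positive"), seed = 1L) {
  case <- match.arg(case)
  cfg <- switch(case,
    normal   = list(area_mean = 3500,  area_sd = 400,  ecc = 0.62, tn = 66,
                    nucleoli = 2, n = 5),
    agc      = list(area_mean = 7658,  area_sd = 400,  ecc = 0.85, tn = 85.5,
                    nucleoli = 2, n = 5),
    positive = list(area_mean = 13747, area_sd = 800,  ecc = 0.85, tn = 105,
                    nucleoli = 0, n = 6))
  side <- frame_side(cfg$n, cfg$area_mean + 3 * cfg$area_sd, ecc = cfg$ecc)
  image_spec(width = side, height = side, n_nuclei = cfg$n,
             area_mean = cfg$area_mean, area_sd = cfg$area_sd,
             ecc_mean = cfg$ecc, ecc_sd = 0.015,
             staining_mean = cfg$tn, staining_sd = 1,
             nucleoli = cfg$nucleoli, noise_sd = 3, seed = seed)
}

#' Generate a synthetic clinical cohort
#'
#' Samples clinical records from a risk-stratum profile naming one fuzzy set
#' per risk-model field. Numeric fields are drawn uniformly from the named
#' set's plateau (its core; counts are drawn on the integer lattice of the
#' plateau); `ETS`/`LE` map "no"/"yes" to FALSE/TRUE. Temporal invariants
#' (age >= ivsa, pg >= ivsa) are enforced by rejection; a profile whose
#' plateaus make them unsatisfiable is an error. Profiles naming the NG
#' "null" set produce nulliparous records (`ng = 0`, `pg = NA`).
#'
#' @param n number of records.
#' @param profile named list with entries `E`, `IVSA`, `PS`, `NG`, `PG`,
#'   `ETS`, `LE` giving set labels (see the shipped risk configuration).
#' @param seed RNG seed.
#' @param model risk model supplying the variable definitions.
#' @return list of [clinical_record()] objects (length `n`).
#' @export
generate_cohort <- function(n, profile, seed = 1L,
                            model = build_risk_model(rules = NA)) {
  stopifnot(n >= 0)
  profile <- lapply(profile, normalize_label)
  need <- c("E", "IVSA", "PS", "NG", "PG", "ETS", "LE")
  if (!all(need %in% names(profile)))
    stop_input(paste("profile needs entries:", paste(need, collapse = ", ")))
  core_of <- function(var, lab) {
    v <- model$inputs[[var]]
    if (!lab %in% var_labels(v))
      stop_input(sprintf("profile: unknown %s label '%s'", var, lab))
    set_core(v$sets[[lab]])
  }
  e_core <- core_of("E", profile$E)
  i_core <- core_of("IVSA", profile$IVSA)
  p_core <- core_of("PG", profile$PG)
  if (i_core[1] > e_core[2])
    stop_input("contradictory profile: sexual onset after every age in the age set")
  nulliparous <- profile$NG == "null"
  if (!nulliparous && p_core[2] < i_core[1])
    stop_input("contradictory profile: first pregnancy before every onset age")
  set.seed(seed)
  draw_int <- function(core) {
    v <- seq(ceiling(core[1]), floor(core[2]))
    if (length(v) == 0) round(mean(core)) else if (length(v) == 1) v else sample(v, 1)
  }
  out <- vector("list", n)
  for (j in seq_len(n)) {
    for (try in 1:200) {
      ivsa <- stats::runif(1, i_core[1], i_core[2])
      age <- stats::runif(1, max(e_core[1], ivsa), e_core[2])
      if (age < ivsa) next
      ng <- if (nulliparous) 0 else draw_int(core_of("NG", profile$NG))
      pg <- if (ng == 0) NA else stats::runif(1, max(p_core[1], ivsa), p_core[2])
      if (!is.na(pg) && pg < ivsa) next
      rec <- try(clinical_record(age = round(age), ivsa = round(ivsa),
                                 ps = draw_int(core_of("PS", profile$PS)),
                                 ng = ng, pg = if (is.na(pg)) NA else round(pg),
                                 ets = profile$ETS == "yes",
                                 le = profile$LE == "yes"), silent = TRUE)
      if (!inherits(rec, "try-error")) break
      if (try == 200) stop_input("could not sample a record satisfying the profile")
    }
    out[[j]] <- rec
  }
  out
}
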