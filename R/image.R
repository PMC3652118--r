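# Cytology image pipeline. Images are numeric arrays [row, col, channel]
# with 8-bit values in [0, 255]; single-channel rasters are [row, col]
# matrices on the same scale. Pixel coordinates are 0-based (row, col).

#' Read / write cytology images
#'
#' Reads an 8-bit RGB PNG or TIFF micrograph into a `[row, col, 3]` array on
#' `[0, 255]`; grayscale files are expanded to three identical channels.
#'
#' @param path image path (PNG or TIFF).
#' @return numeric array `[height, width, 3]`, values in `[0, 255]`, with a
#'   `source` attribute.
#' @export
read_cytology_image <- function(path) {
  if (!file.exists(path)) stop_input(paste("image not found:", path))
  img <- try(suppressWarnings(EBImage::readImage(path)), silent = TRUE)
  if (inherits(img, "try-error")) stop_input(paste("unreadable image:", path))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) dat <- array(rep(dat, 3), c(dim(dat), 3))
  if (dim(dat)[3] > 3) dat <- dat[, , 1:3]          # drop alpha
  out <- aperm(dat, c(2, 1, 3)) * 255
  attr(out, "source") <- path
  out
}

#' @rdname read_cytology_image
#' @param image `[row, col, 3]` array on `[0, 255]` (or a single-channel
#'   matrix).
#' @export
write_cytology_image <- function(image, path) {
  if (length(dim(image)) == 2) image <- array(rep(image, 3), c(dim(image), 3))
  dat <- aperm(image, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(clamp(dat, 0, 1), colormode = "Color"), path)
  invisible(path)
}

#' Brightness/contrast level enhancement
#'
#' Linear level adjustment `gain * x + offset`, or a percentile stretch that
#' maps the (`p_lo`, `p_hi`) percentiles of each channel to 0 and 255.
#' Output is clipped to `[0, 255]`.
#'
#' @param image `[row, col, 3]` array (or matrix) on `[0, 255]`.
#' @param gain,offset linear parameters (defaults 1, 0: identity).
#' @param stretch `NULL`, or `c(p_lo, p_hi)` percentile bounds in `[0, 1]`.
#' @return adjusted image, same dimensions.
#' @export
enhance_levels <- function(image, gain = 1, offset = 0, stretch = NULL) {
  if (!is.null(stretch)) {
    stopifnot(length(stretch) == 2)
    q <- stats::quantile(image, probs = sort(stretch), names = FALSE)
    if (diff(q) <= 0)
      stop_input("degenerate percentile stretch: equal percentile values")
    out <- (image - q[1]) / diff(q) * 255
  } else {
    out <- gain * image + offset
  }
  out[] <- clamp(out, 0, 255)
  out
}

#' Emboss filter
#'
#' Directional 3x3 emboss convolution, offered for visual QC of nuclear
#' edges. It is not part of the feature-extraction path and has no effect on
#' measured morphometry.
#'
#' @param raster single-channel matrix on `[0, 255]`.
#' @return embossed matrix on `[0, 255]`.
#' @export
emboss_filter <- function(raster) {
  k <- matrix(c(-2, -1, 0, -1, 1, 1, 0, 1, 2), 3, 3)
  out <- EBImage::filter2(EBImage::Image(t(raster) / 255), k) * 255
  clamp(t(EBImage::imageData(out)), 0, 255)
}

#' Split an RGB image into channels
#'
#' @param image `[row, col, 3]` array.
#' @return named list of matrices `red`, `green`, `blue` (lossless).
#' @export
split_channels <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop_input("split_channels: expected an RGB image")
  list(red = image[, , 1], green = image[, , 2], blue = image[, , 3])
}

#' Convert an RGB image to grayscale luminance
#'
#' Convex channel weighting (default ITU-R BT.601 luma: 0.299 R + 0.587 G +
#' 0.114 B), values on `[0, 255]`.
#'
#' @param image `[row, col, 3]` array.
#' @param weights length-3 non-negative weights, normalized to sum 1.
#' @return luminance matrix.
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (length(dim(image)) != 3) stop_input("to_grayscale: expected an RGB image")
  w <- weights / sum(weights)
  image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3]
}

#' Staining scale
#'
#' Nuclear staining increases with darkness (hyperchromasia), while raw
#' intensity decreases; the staining raster is therefore the inverted
#' grayscale rescaled to the 0-150 staining universe:
#' `(255 - luminance) * 150 / 255`. Set `invert = FALSE` to keep raw
#' intensity instead.
#'
#' @param gray luminance matrix on `[0, 255]`.
#' @param invert logical; `FALSE` returns `gray` unchanged.
#' @return staining matrix.
#' @export
staining_raster <- function(gray, invert = TRUE) {
  if (!invert) return(gray)
  (255 - gray) * 150 / 255
}

#' Threshold nucleus candidates on the green channel
#'
#' Binarizes the green channel; foreground is the darker class (nuclei take
#' up stain, so they are darkest in green). The threshold is Otsu's (the
#' default) or a manual value.
#'
#' @param green green-channel matrix on `[0, 255]`.
#' @param method `"otsu"` or `"manual"`.
#' @param manual_value threshold on `[0, 255]`, required for `"manual"`.
#' @return logical mask, `TRUE` on nucleus-candidate pixels.
#' @export
threshold_nuclei <- function(green, method = c("otsu", "manual"),
                             manual_value = NULL) {
  method <- match.arg(method)
  if (diff(range(green)) == 0) {
    warning("uniform raster: no contrast, empty mask", call. = FALSE)
    return(matrix(FALSE, nrow(green), ncol(green)))
  }
  thr <- if (method == "manual") {
    if (is.null(manual_value)) stop_input("manual threshold requires manual_value")
    manual_value
  } else {
    EBImage::otsu(EBImage::Image(t(green) / 255), range = c(0, 1)) * 255
  }
  green < thr
}

#' Morphological cleanup of a binary mask
#'
#' Opening then closing with a disk structuring element, hole filling, and
#' removal of connected components below a minimum area. `radius = 0` skips
#' the morphology; `min_area = 0` keeps every component.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels (default 2).
#' @param min_area minimum component area in pixels (default 50).
#' @return cleaned logical mask.
#' @export
morph_cleanup <- function(mask, radius = 2, min_area = 50) {
  stopifnot(radius >= 0, min_area >= 0)
  m <- mask
  if (radius > 0) {
    img <- EBImage::Image(t(m) * 1)
    brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
    img <- EBImage::closing(EBImage::opening(img, brush), brush)
    img <- EBImage::fillHull(img)
    m <- t(EBImage::imageData(img)) > 0.5
  }
  if (min_area > 0 && any(m)) {
    lab <- label_components(m)
    keep <- which(tabulate(lab[lab > 0]) >= min_area)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

# 8-connected component labeling. Components are numbered 1..n in order of
# their first pixel in column-major scan.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- seq_along(idx)                 # vertex id per foreground pixel
  lut <- integer(nr * nc); lut[idx] <- pos
  r <- ((idx - 1L) %% nr) + 1L
  c2 <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + d[1]; cc <- c2 + d[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    hit <- lut[nb] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(pos[ok][hit], lut[nb][hit]))
  }
  if (is.null(edges)) {
    comp <- pos                          # all isolated pixels
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[pos]
  }
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  lab[idx] <- relab[comp]
  lab
}

#' Label nuclei and measure their geometry
#'
#' Labels 8-connected components of a binary mask and measures each region:
#' pixel area, perimeter (count of region pixels with a 4-neighbor outside
#' the region), centroid in 0-based (row, col) coordinates, and eccentricity
#' of the best-fit ellipse from second-order central moments (0 = circle,
#' towards 1 = elongated).
#'
#' @param mask logical matrix.
#' @return object of class `nucleus_regions`: a list with `table` (data
#'   frame: `id`, `area`, `perimeter`, `centroid_row`, `centroid_col`,
#'   `eccentricity`) and `labels` (integer label matrix). Empty mask gives a
#'   zero-row table.
#' @export
label_nuclei <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) {
    tab <- data.frame(id = integer(0), area = numeric(0), perimeter = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      eccentricity = numeric(0))
    return(structure(list(table = tab, labels = lab), class = "nucleus_regions"))
  }
  idx <- which(lab > 0)
  ids <- lab[idx]
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr)                # 0-based row
  c2 <- ((idx - 1L) %/% nr)              # 0-based col
  area <- tabulate(ids, n)
  cr <- as.numeric(rowsum(r, ids)) / area
  cc <- as.numeric(rowsum(c2, ids)) / area
  dr <- r - cr[ids]; dc <- c2 - cc[ids]
  mu20 <- as.numeric(rowsum(dc * dc, ids)) / area
  mu02 <- as.numeric(rowsum(dr * dr, ids)) / area
  mu11 <- as.numeric(rowsum(dr * dc, ids)) / area
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  # perimeter: region pixels with any 4-neighbor outside the same region
  on_border <- rep(FALSE, length(idx))
  lutlab <- matrix(0L, nr, ncol(mask)); lutlab[idx] <- ids
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    rr <- r + 1L + d[1]; cc2 <- c2 + 1L + d[2]
    outside <- rr < 1L | rr > nr | cc2 < 1L | cc2 > ncol(mask)
    nb <- ifelse(outside, 0L, (pmax(cc2, 1L) - 1L) * nr + pmax(rr, 1L))
    nb_lab <- ifelse(outside, 0L, lutlab[pmax(nb, 1L)])
    on_border <- on_border | nb_lab != ids
  }
  perim <- as.numeric(rowsum(as.numeric(on_border), ids))
  tab <- data.frame(id = seq_len(n), area = as.numeric(area), perimeter = perim,
                    centroid_row = cr, centroid_col = cc, eccentricity = ecc)
  structure(list(table = tab, labels = lab), class = "nucleus_regions")
}

#' @export
print.nucleus_regions <- function(x, ...) {
  cat(sprintf("<nucleus_regions> %d regions\n", nrow(x$table)))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Detect nucleoli inside labeled nuclei
#'
#' Within each nucleus, a secondary threshold at `region mean - k * region
#' sd` of the raw intensity selects darker interior spots. The spot mask is
#' opened with a 3x3 structuring element so an accepted spot must contain a
#' solid 3x3 core — pixel noise alone cannot produce one — and the surviving
#' 8-connected spots with area in `[min_spot, max_frac * nucleus_area]` are
#' counted as nucleoli. A nucleus of uniform intensity yields zero.
#'
#' @param intensity raw intensity raster (darker = lower), e.g. the
#'   grayscale luminance.
#' @param regions `nucleus_regions` from [label_nuclei()].
#' @param k multiplier on the region standard deviation (default 1).
#' @param min_spot minimum spot area in pixels (default 3).
#' @param max_frac maximum spot area as a fraction of the nucleus area
#'   (default 0.25).
#' @return `regions` with a `nucleolus_count` column added to its table.
#' @export
detect_nucleoli <- function(intensity, regions, k = 1, min_spot = 3,
                            max_frac = 0.25) {
  stopifnot(inherits(regions, "nucleus_regions"))
  lab <- regions$labels
  counts <- integer(nrow(regions$table))
  pix <- region_pixels(lab)
  nr <- nrow(lab)
  for (i in seq_len(nrow(regions$table))) {
    idx <- pix[[i]]
    vals <- intensity[idx]
    s <- stats::sd(vals)
    if (!is.finite(s) || s == 0) next
    thr <- mean(vals) - k * s
    dark <- idx[vals < thr]
    if (length(dark) == 0) next
    # local bounding box keeps spot labeling cheap on large frames
    r <- ((dark - 1L) %% nr) + 1L
    c2 <- ((dark - 1L) %/% nr) + 1L
    local <- matrix(FALSE, diff(range(r)) + 3L, diff(range(c2)) + 3L)
    local[cbind(r - min(r) + 2L, c2 - min(c2) + 2L)] <- TRUE
    local <- t(EBImage::imageData(EBImage::opening(
      EBImage::Image(t(local) * 1), EBImage::makeBrush(3, "box")))) > 0.5
    spots <- label_components(local)
    sizes <- tabulate(spots[spots > 0])
    counts[i] <- sum(sizes >= min_spot &
                       sizes <= max_frac * regions$table$area[i])
  }
  regions$table$nucleolus_count <- counts
  regions
}

#' Image-level morphometry feature vector
#'
#' Aggregates per-nucleus measurements into the four image-level features
#' used by the injury-resolution model: DN, the mean nucleus area in pixels;
#' TN, the mean of per-nucleus mean staining; HN, the mean eccentricity (or,
#' optionally, the fraction of irregular nuclei); and PN, the total
#' nucleolus count.
#'
#' @param staining staining raster (see [staining_raster()]).
#' @param regions `nucleus_regions`; nucleolus counts must have been added
#'   by [detect_nucleoli()] (regions without the column count as zero).
#' @param hn_stat `"mean"` (default) for mean eccentricity, or `"fraction"`
#'   for the share of nuclei with eccentricity above `hn_cutoff`.
#' @param hn_cutoff eccentricity cutoff for `hn_stat = "fraction"`
#'   (default 0.77, the upper edge of the regular plateau).
#' @return object of class `feature_vector`: list with `DN`, `TN`, `HN`,
#'   `PN`, `n_nuclei`.
#' @export
compute_features <- function(staining, regions, hn_stat = c("mean", "fraction"),
                             hn_cutoff = 0.77) {
  hn_stat <- match.arg(hn_stat)
  stopifnot(inherits(regions, "nucleus_regions"))
  tab <- regions$table
  if (nrow(tab) == 0) stop_compute("no nuclei detected")
  mean_staining <- region_means(staining, regions$labels)
  hn <- if (hn_stat == "mean") mean(tab$eccentricity)
        else mean(tab$eccentricity > hn_cutoff)
  structure(list(DN = mean(tab$area),
                 TN = mean(mean_staining),
                 HN = hn,
                 PN = sum(tab$nucleolus_count %||% rep(0L, nrow(tab))),
                 n_nuclei = nrow(tab)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> n=%d  DN=%.1f px  TN=%.1f  HN=%.3f  PN=%d\n",
              x$n_nuclei, x$DN, x$TN, x$HN, x$PN))
  invisible(x)
}

#' Default image-pipeline parameters
#'
#' @param stretch optional percentile-stretch bounds for [enhance_levels()]
#'   (`NULL`: no enhancement).
#' @param threshold `"otsu"` or `"manual"`.
#' @param manual_value manual threshold on the green channel.
#' @param radius,min_area morphology parameters (see [morph_cleanup()]).
#' @param nucleolus_k,min_spot,max_spot_frac nucleolus detection parameters
#'   (see [detect_nucleoli()]).
#' @param invert_staining compute TN on inverted grayscale (default TRUE).
#' @param hn_stat,hn_cutoff see [compute_features()].
#' @return named list of parameters.
#' @export
pipeline_params <- function(stretch = NULL, threshold = "otsu",
                            manual_value = NULL, radius = 2, min_area = 50,
                            nucleolus_k = 1, min_spot = 3, max_spot_frac = 0.25,
                            invert_staining = TRUE, hn_stat = "mean",
                            hn_cutoff = 0.77) {
  as.list(environment())
}

#' Run the full image-feature pipeline
#'
#' Level enhancement (optional), channel separation, green-channel
#' thresholding, morphological cleanup, nucleus labeling and measurement,
#' nucleolus detection on the grayscale, and feature aggregation.
#'
#' @param image `[row, col, 3]` array on `[0, 255]`, or a path readable by
#'   [read_cytology_image()].
#' @param params list from [pipeline_params()].
#' @return list with `features` ([compute_features()] result), `regions`
#'   (table with `mean_staining` appended), `mask`, and `labels`.
#' @export
extract_features <- function(image, params = pipeline_params()) {
  if (is.character(image)) image <- read_cytology_image(image)
  if (!is.null(params$stretch)) image <- enhance_levels(image, stretch = params$stretch)
  ch <- split_channels(image)
  gray <- to_grayscale(image)
  stain <- staining_raster(gray, invert = isTRUE(params$invert_staining))
  mask <- threshold_nuclei(ch$green, method = params$threshold,
                           manual_value = params$manual_value)
  mask <- morph_cleanup(mask, radius = params$radius, min_area = params$min_area)
  regions <- label_nuclei(mask)
  if (nrow(regions$table) == 0) stop_compute("no nuclei detected")
  regions <- detect_nucleoli(gray, regions, k = params$nucleolus_k,
                             min_spot = params$min_spot,
                             max_frac = params$max_spot_frac)
  feats <- compute_features(stain, regions, hn_stat = params$hn_stat,
                            hn_cutoff = params$hn_cutoff)
  regions$table$mean_staining <- region_means(stain, regions$labels)
  list(features = feats, regions = regions, mask = mask, labels = regions$labels)
}

# Pixel (linear) indices per region label.
region_pixels <- function(labels) {
  idx <- which(labels > 0)
  split(idx, labels[idx])
}

# Mean of a raster over each labeled region, in label order.
region_means <- function(raster, labels) {
  idx <- which(labels > 0)
  ids <- labels[idx]
  as.numeric(rowsum(raster[idx], ids)) / tabulate(ids)
}
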