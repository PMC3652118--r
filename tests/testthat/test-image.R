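# Small deterministic rasters plus generator fields exercise every stage of
# the morphometry pipeline.

disc_mask <- function(n, cy, cx, r) {
  outer(seq_len(n), seq_len(n), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

test_that("level enhancement is identity at default parameters and clips", {
  img <- array(runif(3 * 20 * 20, 0, 255), c(20, 20, 3))
  expect_equal(enhance_levels(img), img)
  expect_error(enhance_levels(array(100, c(5, 5, 3)), stretch = c(0.01, 0.99)),
               class = "agcdx_input_error")
  stretched <- enhance_levels(img, stretch = c(0.01, 0.99))
  expect_equal(min(stretched), 0)
  expect_equal(max(stretched), 255)
  expect_true(all(stretched >= 0 & stretched <= 255))
})

test_that("channel separation is lossless and grayscale is a convex mix", {
  img <- array(0, c(4, 4, 3))
  img[1, 1, ] <- c(0, 255, 0)
  img[2, 2, ] <- c(100, 100, 100)
  ch <- split_channels(img)
  expect_equal(ch$green[1, 1], 255)
  expect_equal(ch$red[1, 1], 0)
  recombined <- array(c(ch$red, ch$green, ch$blue), dim(img))
  expect_equal(recombined, img)
  g <- to_grayscale(img)
  expect_equal(g[2, 2], 100)            # equal channels: any convex weighting
  white <- array(255, c(2, 2, 3)); black <- array(0, c(2, 2, 3))
  expect_equal(to_grayscale(white)[1, 1], 255)
  expect_equal(to_grayscale(black)[1, 1], 0)
  expect_error(split_channels(g), class = "agcdx_input_error")
})

test_that("staining scale inverts darkness onto the 0-150 range", {
  g <- matrix(c(0, 255, 127.5), 1, 3)
  expect_equal(staining_raster(g)[1, ], c(150, 0, 75))
  expect_equal(staining_raster(g, invert = FALSE), g)
})

test_that("otsu thresholding recovers a bimodal nucleus mask", {
  truth <- disc_mask(60, 30, 30, 12)
  green <- matrix(200, 60, 60); green[truth] <- 60
  mask <- threshold_nuclei(green)
  expect_equal(mask, truth)
  manual <- threshold_nuclei(green, method = "manual", manual_value = 130)
  expect_equal(manual, truth)
  expect_error(threshold_nuclei(green, method = "manual"),
               class = "agcdx_input_error")
  expect_warning(empty <- threshold_nuclei(matrix(90, 10, 10)), "uniform")
  expect_false(any(empty))
})

test_that("morphological cleanup is identity at zero radius and removes debris", {
  holed <- disc_mask(40, 20, 20, 10) & !disc_mask(40, 20, 20, 3)
  expect_equal(morph_cleanup(holed, radius = 0, min_area = 0), holed)
  salt <- disc_mask(60, 30, 30, 12)
  set.seed(1)
  specks <- sample(which(!salt & !disc_mask(60, 30, 30, 16)), 25)
  noisy <- salt; noisy[specks] <- TRUE
  cleaned <- morph_cleanup(noisy, radius = 2, min_area = 20)
  expect_false(any(cleaned[specks]))              # all debris removed
  expect_gt(mean(cleaned == salt), 0.995)         # disc essentially intact
  lone <- matrix(FALSE, 10, 10); lone[5, 5] <- TRUE
  expect_false(any(morph_cleanup(lone, radius = 0, min_area = 2)))
})

test_that("labeling uses 8-connectivity and measures moments correctly", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE      # diagonal touch: one component
  regions <- label_nuclei(m)
  expect_equal(nrow(regions$table), 1L)
  expect_equal(regions$table$area, 2)
  # perfect disc: eccentricity near zero
  d <- disc_mask(80, 40, 40, 25)
  rd <- label_nuclei(d)$table
  expect_lte(rd$eccentricity, 0.05)
  expect_equal(rd$area, sum(d))
  expect_equal(rd$centroid_row, 39, tolerance = 0.05)  # 0-based coordinates
  # 5:1 axis ratio: closed form e = sqrt(1 - (b/a)^2) = 0.98
  el <- outer(seq_len(120), seq_len(220), function(i, j)
    ((i - 60) / 10)^2 + ((j - 110) / 50)^2 <= 1)
  re <- label_nuclei(el)$table
  expect_gte(re$eccentricity, 0.9)
  expect_equal(re$eccentricity, sqrt(1 - (10 / 50)^2), tolerance = 0.02)
  expect_equal(nrow(label_nuclei(matrix(FALSE, 5, 5))$table), 0L)
})

test_that("generator ellipse areas are recovered within two percent", {
  gen <- generate_image(image_spec(n_nuclei = 4, seed = 11, noise_sd = 0))
  px <- extract_features(gen$image)
  tab <- px$regions$table
  expect_equal(nrow(tab), 4L)
  gt <- gen$truth$table
  # match by centroid proximity
  for (i in seq_len(nrow(tab))) {
    j <- which.min((gt$centroid_row - tab$centroid_row[i])^2 +
                     (gt$centroid_col - tab$centroid_col[i])^2)
    expect_equal(tab$area[i], gt$area[j], tolerance = 0.02)
    expect_equal(tab$eccentricity[i], gt$eccentricity_drawn[j], tolerance = 0.05)
  }
})

test_that("nucleolus detection counts planted dark spots and size-filters", {
  n <- 80
  nucleus <- disc_mask(n, 40, 40, 30)
  gray <- matrix(200, n, n); gray[nucleus] <- 120
  regions <- label_nuclei(nucleus)
  # uniform nucleus: zero nucleoli
  r0 <- detect_nucleoli(gray, regions)
  expect_equal(r0$table$nucleolus_count, 0L)
  # two planted dark spots
  gray2 <- gray
  gray2[disc_mask(n, 32, 32, 3)] <- 40
  gray2[disc_mask(n, 50, 48, 3)] <- 40
  r2 <- detect_nucleoli(gray2, regions)
  expect_equal(r2$table$nucleolus_count, 2L)
  # a spot covering most of the nucleus is not a nucleolus
  gray3 <- gray
  gray3[disc_mask(n, 40, 40, 22)] <- 40
  r3 <- detect_nucleoli(gray3, regions)
  expect_equal(r3$table$nucleolus_count, 0L)
})

test_that("feature aggregation is the arithmetic of per-region measurements", {
  lab <- matrix(0L, 200, 100)
  lab[1:40, 1:100] <- 1L                # 4000
  lab[101:160, 1:100] <- 2L             # 6000
  stain <- matrix(80, 200, 100); stain[lab == 2L] <- 120
  regions <- structure(list(table = data.frame(
    id = 1:2, area = c(4000, 6000), perimeter = NA, centroid_row = NA,
    centroid_col = NA, eccentricity = c(0.2, 0.4), nucleolus_count = c(1L, 2L)),
    labels = lab), class = "nucleus_regions")
  fv <- compute_features(stain, regions)
  expect_equal(fv$DN, 5000)
  expect_equal(fv$TN, mean(c(80, 120)))
  expect_equal(fv$HN, 0.3)
  expect_equal(fv$PN, 3L)
  expect_equal(fv$n_nuclei, 2L)
  # single region: TN equals that region's mean staining
  lab1 <- matrix(0L, 10, 10); lab1[3:6, 3:6] <- 1L
  s1 <- matrix(seq(0, 99), 10, 10)
  regions1 <- structure(list(table = data.frame(
    id = 1L, area = 16, perimeter = NA, centroid_row = NA, centroid_col = NA,
    eccentricity = 0, nucleolus_count = 0L), labels = lab1),
    class = "nucleus_regions")
  expect_equal(compute_features(s1, regions1)$TN, mean(s1[lab1 == 1L]))
  empty <- structure(list(table = regions1$table[0, ], labels = lab1 * 0L),
                     class = "nucleus_regions")
  expect_error(compute_features(s1, empty), class = "agcdx_compute_error")
})

test_that("features match a brute-force per-pixel oracle on ground truth", {
  gen <- generate_image(image_spec(width = 220, height = 220, n_nuclei = 2,
                                   area_mean = 2500, area_sd = 200, seed = 3))
  stain <- staining_raster(to_grayscale(gen$image))
  want <- oracle_features(stain, gen$truth$labels)
  expect_equal(mean(gen$truth$table$area), want$DN)
  expect_equal(mean(gen$truth$table$mean_staining), want$TN)
  expect_equal(gen$truth$table$area, want$areas)
})

test_that("features are invariant to translation and 90-degree rotation", {
  gen <- generate_image(image_spec(width = 300, height = 300, n_nuclei = 3,
                                   area_mean = 2800, area_sd = 200, seed = 5))
  base <- extract_features(gen$image)$features
  shifted <- array(200, dim(gen$image) + c(40, 40, 0))
  bg <- gen$image[1, 1, ]
  for (ch in 1:3) shifted[, , ch] <- bg[ch]
  shifted[41:340, 41:340, ] <- gen$image
  fs <- extract_features(shifted)$features
  rot <- aperm(gen$image, c(2, 1, 3))[dim(gen$image)[2]:1, , ]
  fr <- extract_features(rot)$features
  for (f in list(fs, fr)) {
    expect_equal(f$n_nuclei, base$n_nuclei)
    expect_equal(f$DN, base$DN, tolerance = 0.02)
    expect_equal(f$HN, base$HN, tolerance = 0.02)
    expect_equal(f$PN, base$PN)
  }
})

test_that("the pipeline is deterministic for a fixed image and config", {
  gen <- generate_image(image_spec(n_nuclei = 3, seed = 9))
  a <- extract_features(gen$image)
  b <- extract_features(gen$image)
  expect_identical(unclass(a$features), unclass(b$features))
  expect_identical(a$regions$table, b$regions$table)
})
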