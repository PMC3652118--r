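fixture_case <- function(case, seed = 1L) {
  recs <- worked_case_records()
  rec <- switch(case, normal = recs$case1, agc = recs$case5,
                positive = recs$case8)
  gen <- generate_image(diagnosis_image_spec(case, seed = seed))
  list(record = rec, image = gen$image)
}

test_that("end-to-end fixtures land in the three diagnostic classes", {
  rm <- risk_model_default(); im <- injury_model_default()
  for (case in c("normal", "agc", "positive")) {
    fx <- fixture_case(case)
    rep <- diagnose(fx$record, fx$image, risk_model = rm, injury_model = im)
    expect_equal(rep$injury$label, case)
    expect_gte(rep$injury$score, 0); expect_lte(rep$injury$score, 100)
    expect_equal(rep$risk$label, "negative")
  }
})

test_that("reports embed provenance and reproduce byte for byte", {
  fx <- fixture_case("normal")
  rm <- risk_model_default(); im <- injury_model_default()
  rep1 <- diagnose(fx$record, fx$image, risk_model = rm, injury_model = im)
  rep2 <- diagnose(fx$record, fx$image, risk_model = rm, injury_model = im)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, f1); write_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_report(f1)
  expect_equal(back$injury$label, rep1$injury$label)
  expect_equal(back$injury$score, rep1$injury$score)
  expect_match(back$provenance$config_hash$risk, "^[0-9a-f]{32}$")
  expect_match(back$provenance$inputs$image_hash, "^[0-9a-f]{32}$")
  expect_true(nrow(back$provenance$injury_rules_fired) >= 1)
})

test_that("batch risk command appends scores and validates rows", {
  csv <- withr::local_tempfile(fileext = ".csv")
  recs <- worked_case_records()
  df <- do.call(rbind, lapply(recs, function(r) as.data.frame(unclass(r))))
  write.csv(df, csv, row.names = FALSE)
  out <- withr::local_tempfile(fileext = ".csv")
  res <- cmd_risk(csv, out)
  expect_equal(res$risk_label, rep("negative", 3))
  expect_true(file.exists(out))
  expect_equal(read.csv(out)$risk_label, rep("negative", 3))
  # empty input: empty output with a warning
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("age,ivsa,ps,ng,pg,ets,le", empty)
  expect_warning(res0 <- cmd_risk(empty), "empty")
  expect_equal(nrow(res0), 0L)
  # invariant violation names the row
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,ivsa,ps,ng,pg,ets,le",
               "30,20,1,1,25,no,no",
               "18,25,1,0,,no,no"), bad)
  expect_error(cmd_risk(bad), "row 2", class = "agcdx_input_error")
})

test_that("feature command writes deterministic JSON and a region table", {
  png <- withr::local_tempfile(fileext = ".png")
  gen <- cmd_simulate(png, spec = image_spec(n_nuclei = 3, seed = 4))
  expect_true(file.exists(png))
  fj1 <- withr::local_tempfile(fileext = ".json")
  fj2 <- withr::local_tempfile(fileext = ".json")
  rcsv <- withr::local_tempfile(fileext = ".csv")
  cmd_features(png, fj1, rcsv)
  cmd_features(png, fj2)
  expect_identical(readLines(fj1), readLines(fj2))
  fv <- jsonlite::read_json(fj1)
  expect_equal(fv$n_nuclei, 3L)
  expect_equal(nrow(read.csv(rcsv)), 3L)
  # a blank image has no nuclei to measure
  blank <- withr::local_tempfile(fileext = ".png")
  write_cytology_image(array(180, c(64, 64, 3)), blank)
  expect_error(suppressWarnings(cmd_features(blank)),
               class = "agcdx_compute_error")
})

test_that("PNG round-trip preserves the 8-bit image", {
  gen <- generate_image(image_spec(n_nuclei = 2, width = 256, height = 224,
                                   seed = 6))
  png <- withr::local_tempfile(fileext = ".png")
  write_cytology_image(gen$image, png)
  back <- read_cytology_image(png)
  expect_equal(dim(back), dim(gen$image))
  expect_equal(as.numeric(back), as.numeric(gen$image), tolerance = 1e-6)
})

test_that("diagnose command runs from files and writes a report", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,ivsa,ps,ng,pg,ets,le", "47,23,2,1,27,no,no"), csv)
  png <- withr::local_tempfile(fileext = ".png")
  cmd_simulate(png, spec = diagnosis_image_spec("normal", seed = 2))
  out <- withr::local_tempfile(fileext = ".json")
  rep <- cmd_diagnose(csv, png, out)
  expect_true(file.exists(out))
  expect_equal(rep$injury$label, "normal")
  expect_output(print(rep), "Injury resolution")
})

test_that("rule enumeration command reports both shipped models", {
  expect_message(r <- cmd_enumerate_rules("risk"), "972")
  expect_equal(nrow(r), 972L)
  expect_message(i <- cmd_enumerate_rules("injury"), "108")
  expect_equal(nrow(i), 108L)
})

test_that("error conditions map onto the documented exit codes", {
  expect_equal(agcdx:::cli_exit_code(simpleError("x")), 3L)
  input_err <- tryCatch(read_records("does-not-exist.csv"), error = identity)
  expect_equal(agcdx:::cli_exit_code(input_err), 1L)
  config_err <- tryCatch(load_fuzzy_model("missing.yaml"), error = identity)
  expect_equal(agcdx:::cli_exit_code(config_err), 2L)
})
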