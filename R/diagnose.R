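#' Full two-stage diagnosis of one case
#'
#' Runs the complete expert system on one patient: risk assessment from the
#' clinical record, morphometry extraction from the cytology image, and
#' injury resolution fusing both. The report carries full provenance: the
#' fired rules with activations, configuration hashes, input fingerprints,
#' and package version, so re-running with identical inputs reproduces it
#' byte for byte.
#'
#' @param record a [clinical_record()] (or named list of its fields).
#' @param image `[row, col, 3]` array or path to a PNG/TIFF.
#' @param risk_model,injury_model models; built from the shipped
#'   configurations when omitted.
#' @param params image-pipeline parameters from [pipeline_params()].
#' @return object of class `diagnosis_report`.
#' @export
diagnose <- function(record, image,
                     risk_model = build_risk_model(),
                     injury_model = build_injury_model(),
                     params = pipeline_params()) {
  if (!inherits(record, "clinical_record")) record <- do.call(clinical_record, record)
  risk <- assess_risk(record, risk_model)
  image_fp <- fingerprint_image(image)
  px <- extract_features(image, params)
  injury <- resolve_injury(px$features, risk, injury_model)
  structure(list(
    record = unclass(record),
    risk = list(score = risk$score, label = risk$label),
    features = unclass(px$features),
    injury = list(score = injury$score, label = injury$label),
    provenance = list(
      risk_rules_fired = risk$fired,
      injury_rules_fired = injury$fired,
      params = params,
      config_hash = list(risk = model_hash(risk_model),
                         injury = model_hash(injury_model)),
      inputs = list(record_hash = object_hash(unclass(record)),
                    image_hash = image_fp),
      package_version = as.character(utils::packageVersion("agcdx")))),
    class = "diagnosis_report")
}

model_hash <- function(model) {
  object_hash(list(inputs = lapply(model$inputs, variable_to_config),
                   output = variable_to_config(model$output),
                   rules = model$rules, options = model$options))
}

fingerprint_image <- function(image) {
  if (is.character(image)) return(unname(tools::md5sum(image)))
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  writeBin(as.double(image), con)
  writeBin(as.integer(dim(image)), con)
  close(con)
  unname(tools::md5sum(f))
}

#' @export
print.diagnosis_report <- function(x, ...) {
  lab <- c(normal = "Normal", agc = "AGC", positive = "Positive to malignity",
           negative = "Negative", positive_r = "Positive")
  cat("=== Diagnosis report ===\n")
  cat("Background evaluation:\n")
  cat(sprintf("  risk: %s (score %.3f)\n",
              if (x$risk$label == "negative") "Negative" else "Positive",
              x$risk$score))
  cat("Image data:\n")
  cat(sprintf("  nuclei: %d   DN: %.1f px   TN: %.1f   HN: %.3f   PN: %d\n",
              x$features$n_nuclei, x$features$DN, x$features$TN,
              x$features$HN, x$features$PN))
  cat("Injury resolution:\n")
  cat(sprintf("  %s (score %.2f / 100)\n",
              lab[x$injury$label] %||% x$injury$label, x$injury$score))
  invisible(x)
}

#' Serialize / read a diagnosis report
#'
#' Reports are JSON-first; the printed text rendering is produced from the
#' same structure. Round-trips losslessly (data frames of fired rules are
#' stored row-wise).
#'
#' @param report a `diagnosis_report`.
#' @param path output/input JSON path.
#' @return `path` (write) or the report list (read).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_input(paste("report not found:", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(rep, class = "diagnosis_report")
}
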