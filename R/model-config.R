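#' Label synonym normalization
#'
#' The printed model tables use inconsistent spellings for the same
#' linguistic set (e.g. "Little"/"Few", "Not common"/"Unusual",
#' "Light"/"Clear", "Medium"/"Media", "Positive to malignity"/"Positive").
#' All configuration loading funnels labels through this normalizer:
#' lower-cased, trimmed, then mapped through a fixed synonym table.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  syn <- c("little"       = "few",
           "not common"   = "unusual",
           "not-common"   = "unusual",
           "light"        = "clear",
           "media"        = "medium",
           "null"         = "null",
           "positive to malignity" = "positive",
           "positive-to-malignity" = "positive",
           "no variation" = "normal")
  hit <- x %in% names(syn)
  x[hit] <- syn[x[hit]]
  x
}

variable_from_config <- function(cfg) {
  if (is.null(cfg$name) || is.null(cfg$universe) || is.null(cfg$sets))
    stop_config("variable config needs 'name', 'universe' and 'sets'")
  sets <- lapply(cfg$sets, function(s) {
    if (is.null(s$label) || is.null(s$shape) || is.null(s$params))
      stop_config(sprintf("variable '%s': each set needs label/shape/params", cfg$name))
    shape <- tolower(s$shape)
    if (shape == "triangular") shape <- "triangle"
    fuzzy_set(normalize_label(s$label), shape, unlist(s$params))
  })
  fuzzy_variable(cfg$name, unlist(cfg$universe), sets)
}

variable_to_config <- function(variable) {
  list(name = variable$name,
       universe = variable$universe,
       sets = lapply(variable$sets, function(s)
         list(label = s$label, shape = s$shape, params = s$params)))
}

#' Load a Mamdani model definition from YAML or JSON
#'
#' The schema has top-level keys `inputs` (list of variables), `output` (one
#' variable), optional `rules` (list of label maps with a `consequent`
#' entry), and optional `engine` (AND operator, implication, resolution).
#' Each variable has `name`, `universe: [lo, hi]`, and `sets`, each set
#' `label`, `shape` (triangle/trapezoid) and `params` (breakpoints). Labels
#' are passed through [normalize_label()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` model definition.
#' @param rules optional rule data frame overriding any inline rules.
#' @return a [mamdani_model].
#' @export
load_fuzzy_model <- function(path, rules = NULL) {
  if (!file.exists(path)) stop_config(paste("model config not found:", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  model_from_config(cfg, rules = rules)
}

model_from_config <- function(cfg, rules = NULL) {
  if (is.null(cfg$inputs) || is.null(cfg$output))
    stop_config("model config needs 'inputs' and 'output'")
  inputs <- lapply(cfg$inputs, variable_from_config)
  output <- variable_from_config(cfg$output)
  if (is.null(rules) && !is.null(cfg$rules)) {
    rules <- do.call(rbind, lapply(cfg$rules, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    for (nm in setdiff(names(rules), "enabled"))
      rules[[nm]] <- normalize_label(rules[[nm]])
  }
  eng <- cfg$engine %||% list()
  mamdani_model(inputs, output, rules = rules,
                and_op = eng$and %||% "min",
                implication = eng$implication %||% "min",
                aggregation = eng$aggregation %||% "max",
                defuzzification = eng$defuzzification %||% "centroid",
                resolution = eng$resolution %||% 1001L)
}

#' Write a variable definition as a config fragment
#'
#' Serializes a [fuzzy_variable] to YAML (or JSON), in the same schema
#' accepted by [load_fuzzy_model()]. Used to export calibrated membership
#' functions (see [intervals_to_membership()]).
#'
#' @param variable a [fuzzy_variable].
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_variable_config <- function(variable, path) {
  cfg <- variable_to_config(variable)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Read a rule base from CSV
#'
#' One row per rule: one column per input variable holding a set label, a
#' `consequent` column, optionally `enabled` (logical). Labels are
#' normalized.
#'
#' @param path CSV path.
#' @return rule data frame.
#' @export
read_rules_csv <- function(path) {
  if (!file.exists(path)) stop_config(paste("rule file not found:", path))
  rules <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in setdiff(names(rules), "enabled"))
    rules[[nm]] <- normalize_label(rules[[nm]])
  if ("enabled" %in% names(rules)) rules$enabled <- as.logical(rules$enabled)
  rules
}

#' @rdname read_rules_csv
#' @param rules rule data frame.
#' @export
write_rules_csv <- function(rules, path) {
  utils::write.csv(rules, path, row.names = FALSE)
  invisible(path)
}

system_config <- function(name) {
  p <- system.file("extdata", name, package = "agcdx")
  if (!nzchar(p)) stop_config(paste("shipped config not found:", name))
  p
}
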