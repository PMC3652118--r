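#' Build the injury-resolution model
#'
#' Loads the injury-resolution model definition (by default the shipped
#' configuration: inputs DN, TN, HN, PN and the crisp risk score R; output
#' DL with sets Normal / AGC / Positive-to-malignity on \[0, 100\]) and
#' attaches a rule base, by default generated over the full 108-combination
#' antecedent space by [generate_injury_rules()].
#'
#' @param config path to a model YAML/JSON; default: the shipped definition.
#' @param rules rule data frame, `NULL` to generate the default base, or
#'   `NA` for an empty base.
#' @return a [mamdani_model].
#' @export
build_injury_model <- function(config = NULL, rules = NULL) {
  config <- config %||% system_config("injury_model.yaml")
  model <- load_fuzzy_model(config)
  if (is.null(rules)) {
    rules <- generate_injury_rules(model)
  } else if (length(rules) == 1 && is.na(rules)) {
    rules <- NULL
  }
  mamdani_model(model$inputs, model$output, rules = rules,
                and_op = model$options$and_op,
                implication = model$options$implication,
                resolution = model$options$resolution)
}

#' Severity-scoring policy for the injury rule base
#'
#' Only five of the validated injury-resolution rules are published. This
#' documented, non-clinical heuristic fills in the remaining consequents by
#' counting malignancy indicators: enlarged nuclei (medium +1, large +3),
#' hyperchromatic staining (medium +1, dark +2), irregular nuclear shape +2,
#' unusually many nucleoli +1, and positive clinical risk +2. Scores <= 2
#' map to normal, 3-4 to AGC, >= 5 to positive-to-malignity. The policy is
#' constrained (and tested) to agree with every printed reference rule.
#'
#' @param antecedent named list: labels for DN, TN, HN, PN, R.
#' @return `"normal"`, `"agc"` or `"positive"`.
#' @export
injury_severity_policy <- function(antecedent) {
  a <- lapply(antecedent, normalize_label)
  score <- switch(a$DN, small = 0, medium = 1, large = 3) +
    switch(a$TN, clear = 0, medium = 1, dark = 2) +
    switch(a$HN, regular = 0, irregular = 2) +
    switch(a$PN, "null" = 0, few = 0, many = 1) +
    switch(a$R, negative = 0, positive = 2)
  if (score <= 2) "normal" else if (score <= 4) "agc" else "positive"
}

# A dark (strongly hyperchromatic) nucleus masks its nucleoli, so rules
# pairing dark staining with detected nucleoli are physically invalid.
injury_combination_valid <- function(antecedent) {
  !(normalize_label(antecedent$TN) == "dark" &&
      normalize_label(antecedent$PN) %in% c("few", "many"))
}

#' Generate the default injury-resolution rule base
#'
#' Enumerates all 108 antecedent combinations, assigns consequents via a
#' severity policy (default [injury_severity_policy()]), disables physically
#' invalid combinations (dark staining with detected nucleoli), and verifies
#' the base against the locked printed reference rules.
#'
#' @param model injury [mamdani_model] (rules ignored).
#' @param severity_policy function mapping an antecedent label list to an
#'   output label.
#' @param reference locked reference rules, or `NULL` to skip the check.
#' @return rule data frame with `consequent` and `enabled` columns.
#' @export
generate_injury_rules <- function(model, severity_policy = injury_severity_policy,
                                  reference = printed_injury_rules()) {
  space <- enumerate_rule_space(model)
  space$consequent <- vapply(seq_len(nrow(space)), function(i)
    severity_policy(as.list(space[i, , drop = FALSE])), "")
  space$enabled <- vapply(seq_len(nrow(space)), function(i)
    injury_combination_valid(as.list(space[i, , drop = FALSE])), TRUE)
  check_against_reference(space, reference)
  space
}

#' Resolve the injury diagnosis from image features and clinical risk
#'
#' Runs the injury-resolution model on a [feature_vector] (DN, TN, HN, PN)
#' and a `risk_result` (crisp risk score), producing the final crisp injury
#' score on \[0, 100\] and its Normal / AGC / Positive-to-malignity label.
#' Inputs outside their universes (e.g. a mean eccentricity below 0.5) are
#' clamped with a warning.
#'
#' @param features a [feature_vector] or named list with `DN`, `TN`, `HN`,
#'   `PN` (and optionally `n_nuclei >= 1`).
#' @param risk a `risk_result` from [assess_risk()], or a single crisp risk
#'   value.
#' @param model injury model from [build_injury_model()]; built on demand
#'   when omitted.
#' @return list of class `injury_result`: `score`, `label`, `activations`,
#'   `fired` (rule provenance with activations).
#' @export
resolve_injury <- function(features, risk, model = build_injury_model()) {
  if (!is.null(features$n_nuclei) && features$n_nuclei < 1)
    stop_input("resolve_injury: feature vector has no nuclei")
  r <- if (is.numeric(risk)) risk else risk$score
  res <- infer(model, list(DN = features$DN, TN = features$TN,
                           HN = features$HN, PN = features$PN, R = r))
  structure(list(score = res$score, label = res$label,
                 activations = res$activations, fired = res$fired),
            class = "injury_result")
}

#' @export
print.injury_result <- function(x, ...) {
  lab <- c(normal = "Normal", agc = "AGC", positive = "Positive to malignity")
  cat(sprintf("<injury_result> %s (score %.2f / 100)\n",
              lab[x$label] %||% x$label, x$score))
  invisible(x)
}

#' Classify a crisp injury score
#'
#' Maps a score on \[0, 100\] to the output label with maximal DL-set
#' membership. In the overlap bands (31-41 and 58-68) the winner switches at
#' the membership crossing (36 and 63); exact ties go to the more severe
#' label.
#'
#' @param score numeric vector of scores in \[0, 100\].
#' @param model injury model (for its output sets).
#' @return character vector of labels.
#' @export
classify_score <- function(score, model = build_injury_model(rules = NA)) {
  if (any(score < 0 | score > 100)) stop_input("score must be in [0, 100]")
  vapply(score, function(s) label_at(model$output, s), "")
}
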