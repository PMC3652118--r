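#' Clinical record of one patient
#'
#' The seven clinical-background inputs of the risk model: age, onset of
#' sexual activity (IVSA), number of sexual partners, number of pregnancies,
#' age at first pregnancy, STD history, and cervical lesions on exploration.
#'
#' @param age years.
#' @param ivsa years, onset of sexual activity; must not exceed `age`.
#' @param ps number of sexual partners (count, >= 0).
#' @param ng number of pregnancies (count, >= 0).
#' @param pg age at first pregnancy in years, `NA` when `ng = 0`; when
#'   present must be at least `ivsa`.
#' @param ets logical, history of sexually transmitted disease.
#' @param le logical, cervical lesions found on exploration.
#' @return an object of class `clinical_record` (a named list).
#' @examples
#' clinical_record(age = 47, ivsa = 23, ps = 2, ng = 1, pg = 27,
#'                 ets = FALSE, le = FALSE)
#' @export
clinical_record <- function(age, ivsa, ps, ng, pg = NA, ets = FALSE, le = FALSE) {
  rec <- list(age = as.numeric(age), ivsa = as.numeric(ivsa),
              ps = as.numeric(ps), ng = as.numeric(ng),
              pg = as.numeric(pg), ets = as.logical(ets), le = as.logical(le))
  validate_clinical_record(rec)
  structure(rec, class = "clinical_record")
}

validate_clinical_record <- function(rec, where = "record") {
  with(rec, {
    if (any(!is.finite(c(age, ivsa, ps, ng))))
      stop_input(paste(where, ": age/ivsa/ps/ng must be finite"))
    if (ps < 0 || ng < 0) stop_input(paste(where, ": counts must be >= 0"))
    if (age < ivsa) stop_input(sprintf("%s: age (%g) < ivsa (%g)", where, age, ivsa))
    if (ng > 0 && is.na(pg)) stop_input(paste(where, ": pg required when ng > 0"))
    if (!is.na(pg) && pg < ivsa)
      stop_input(sprintf("%s: pg (%g) < ivsa (%g)", where, pg, ivsa))
    if (is.na(ets) || is.na(le)) stop_input(paste(where, ": ets/le must be TRUE/FALSE"))
  })
  invisible(rec)
}

#' @export
print.clinical_record <- function(x, ...) {
  cat(sprintf("<clinical_record> age %g, ivsa %g, partners %g, pregnancies %g (first at %s), STD %s, lesions %s\n",
              x$age, x$ivsa, x$ps, x$ng,
              if (is.na(x$pg)) "-" else format(x$pg),
              if (x$ets) "yes" else "no", if (x$le) "yes" else "no"))
  invisible(x)
}

#' Build the clinical-background risk model
#'
#' Loads the risk model definition (by default the shipped configuration:
#' seven inputs E, IVSA, PS, NG, PG, ETS, LE and a two-set risk output) and
#' attaches a rule base. By default the rule base is generated over the full
#' antecedent space by [generate_default_rules()], pinned to the locked
#' table of printed reference rules.
#'
#' @param config path to a model YAML/JSON; default: the shipped definition.
#' @param rules rule data frame, or `NULL` to generate the default base, or
#'   `NA` to build the model with an empty rule base.
#' @return a [mamdani_model] for risk assessment.
#' @export
build_risk_model <- function(config = NULL, rules = NULL) {
  config <- config %||% system_config("risk_model.yaml")
  model <- load_fuzzy_model(config)
  if (is.null(rules)) {
    rules <- generate_default_rules(model)
  } else if (length(rules) == 1 && is.na(rules)) {
    rules <- NULL
  }
  mamdani_model(model$inputs, model$output, rules = rules,
                and_op = model$options$and_op,
                implication = model$options$implication,
                resolution = model$options$resolution)
}

#' Enumerate the full antecedent space of a model
#'
#' Yields every combination of one set label per input variable, exactly
#' once, in lexicographic order with the first input variable most
#' significant (set order as configured per variable). The number of rows is
#' the product of per-input set counts: 972 for the shipped risk model
#' (3 x 3 x 3 x 3 x 3 x 2 x 2) and 108 for the shipped injury-resolution
#' model (3 x 3 x 2 x 3 x 2).
#'
#' @param model a [mamdani_model].
#' @return data frame with one column per input variable.
#' @export
enumerate_rule_space <- function(model) {
  stopifnot(inherits(model, "mamdani_model"))
  labs <- lapply(model$inputs, var_labels)
  # expand.grid varies the first factor fastest; reverse to make the first
  # input most significant, then restore column order.
  grid <- expand.grid(rev(labs), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  names(grid) <- names(model$inputs)
  rownames(grid) <- NULL
  grid
}

#' Severity-scoring policy for the risk rule base
#'
#' Only a 20-row excerpt of the validated risk rule base is published; the
#' remaining consequents must be filled in to run the system on arbitrary
#' records. This documented, non-clinical heuristic scores each antecedent
#' combination by counting high-risk indicators and maps the score to a
#' consequent. It is constrained (and tested) to agree with every printed
#' reference rule; it is not a clinical instrument.
#'
#' Indicator weights: many partners +2, unusually many partners +3, many
#' pregnancies +2 (+1 more when the first pregnancy was at a young age),
#' STD history +0.5, cervical lesions +0.5, sexual onset at a young age
#' +0.5. Combinations scoring >= 2 are labeled positive, otherwise negative.
#'
#' @param antecedent named character vector/list: one set label per input
#'   variable (labels as in the shipped configuration).
#' @return `"negative"` or `"positive"`.
#' @export
risk_severity_policy <- function(antecedent) {
  a <- lapply(antecedent, normalize_label)
  score <- 0
  score <- score + switch(a$PS, few = 0, many = 2, unusual = 3)
  if (a$NG == "many") {
    score <- score + 2
    if (a$PG == "young") score <- score + 1
  }
  if (a$ETS == "yes") score <- score + 0.5
  if (a$LE == "yes") score <- score + 0.5
  if (a$IVSA == "young") score <- score + 0.5
  if (score >= 2) "positive" else "negative"
}

# Antecedent combinations that cannot occur for any real patient: the
# temporal orderings ivsa <= age, pg <= age, ivsa <= pg are impossible when
# the corresponding set supports are disjoint in the wrong order. For
# nulliparous combinations (NG null) the PG label is a dummy — no first
# pregnancy ever happened — so PG-based orderings are not enforced there.
risk_combination_valid <- function(antecedent, inputs) {
  sup <- function(var, lab) set_support(inputs[[var]]$sets[[lab]])
  ok_le <- function(lhs, rhs) lhs[1] <= rhs[2]   # exists x in lhs <= y in rhs
  if (!ok_le(sup("IVSA", antecedent$IVSA), sup("E", antecedent$E))) return(FALSE)
  if (normalize_label(antecedent$NG) == "null") return(TRUE)
  ok_le(sup("PG", antecedent$PG), sup("E", antecedent$E)) &&
    ok_le(sup("IVSA", antecedent$IVSA), sup("PG", antecedent$PG))
}

#' Generate the default risk rule base
#'
#' Enumerates all antecedent combinations of the risk model, assigns each a
#' consequent via a severity policy (default [risk_severity_policy()]),
#' disables clinically impossible combinations (e.g. sexual onset at an age
#' older than any age in the patient's age set), and verifies the result
#' against the locked table of printed reference rules. A policy that
#' contradicts a printed rule aborts with a consistency error naming the
#' offending row.
#'
#' @param model risk [mamdani_model] (rules ignored).
#' @param severity_policy function mapping an antecedent label list to an
#'   output label.
#' @param reference data frame of locked reference rules (antecedent columns
#'   plus `consequent`), or `NULL` to skip the consistency check. Default:
#'   the shipped printed excerpt.
#' @return rule data frame (972 rows for the shipped model) with columns for
#'   every input variable, `consequent`, and `enabled`.
#' @export
generate_default_rules <- function(model, severity_policy = risk_severity_policy,
                                   reference = printed_risk_rules()) {
  space <- enumerate_rule_space(model)
  space$consequent <- vapply(seq_len(nrow(space)), function(i)
    severity_policy(as.list(space[i, , drop = FALSE])), "")
  space$enabled <- vapply(seq_len(nrow(space)), function(i)
    risk_combination_valid(as.list(space[i, setdiff(names(space), c("consequent", "enabled")),
                                         drop = FALSE]), model$inputs), TRUE)
  check_against_reference(space, reference)
  space
}

check_against_reference <- function(rules, reference) {
  if (is.null(reference)) return(invisible(rules))
  ante <- setdiff(names(reference), c("consequent", "enabled"))
  key <- function(df) do.call(paste, c(df[ante], sep = "\r"))
  idx <- match(key(reference), key(rules))
  if (anyNA(idx)) stop_config("reference rules outside the enumerated space")
  bad <- which(rules$consequent[idx] != reference$consequent)
  if (length(bad))
    stop_config(sprintf(
      "severity policy contradicts printed rule(s) %s (e.g. row %d: %s -> policy '%s', printed '%s')",
      paste(bad, collapse = ", "), bad[1],
      paste(unlist(reference[bad[1], ante]), collapse = "/"),
      rules$consequent[idx[bad[1]]], reference$consequent[bad[1]]))
  invisible(rules)
}

#' Printed reference rules
#'
#' The published excerpts of the two validated rule bases, shipped as locked
#' fixtures: 20 risk rules and 5 injury-resolution rules.
#'
#' @return data frame of rules (antecedent columns plus `consequent`).
#' @export
printed_risk_rules <- function() read_rules_csv(system_config("rules_risk_printed.csv"))

#' @rdname printed_risk_rules
#' @export
printed_injury_rules <- function() read_rules_csv(system_config("rules_injury_printed.csv"))

#' Assess the risk of cervical neoplasia from a clinical record
#'
#' Runs the risk model on one [clinical_record()]. Boolean fields are mapped
#' to 0/1 on their input universes. For nulliparous records (`ng = 0`) the
#' age at first pregnancy is undefined; it is imputed as the midpoint of the
#' PG universe (with a message) — the NG "null" membership dominates the
#' fired rules, so the imputed value does not drive the outcome.
#'
#' @param record a [clinical_record()] (or a named list with its fields).
#' @param model risk model from [build_risk_model()]; built on demand when
#'   omitted.
#' @return list of class `risk_result`: `score` (crisp risk value), `label`
#'   (`"negative"` or `"positive"`), `activations`, `fired`.
#' @export
assess_risk <- function(record, model = build_risk_model()) {
  if (!inherits(record, "clinical_record")) record <- do.call(clinical_record, record)
  pg <- record$pg
  if (is.na(pg)) {
    pg <- mean(model$inputs$PG$universe)
    message(sprintf("nulliparous record: PG imputed as universe midpoint (%g)", pg))
  }
  res <- infer(model, list(E = record$age, IVSA = record$ivsa, PS = record$ps,
                           NG = record$ng, PG = pg,
                           ETS = as.numeric(record$ets), LE = as.numeric(record$le)))
  structure(list(score = res$score, label = res$label,
                 activations = res$activations, fired = res$fired),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> %s (score %.3f)\n", x$label, x$score))
  invisible(x)
}
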