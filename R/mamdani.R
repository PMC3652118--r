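#' Mamdani fuzzy inference model
#'
#' Assembles a complete Mamdani fuzzy inference system: a list of input
#' [fuzzy_variable]s, one output variable, a rule base, and engine options.
#' The classic Mamdani cycle is: fuzzify each crisp input, fire every rule by
#' combining its antecedent degrees with the AND operator, clip (or scale)
#' the consequent output set by the rule activation, aggregate all clipped
#' sets with the OR operator, and defuzzify the aggregated surface by its
#' centroid.
#'
#' Rules are rows of a data frame with one column per input variable holding
#' a set label, a `consequent` column holding an output set label, and an
#' optional logical `enabled` column (disabled rules never fire but are kept
#' for provenance).
#'
#' @param inputs list of [fuzzy_variable] objects (the antecedent variables).
#' @param output a single [fuzzy_variable] (the consequent variable).
#' @param rules data frame rule base as described above; may be empty.
#' @param and_op antecedent conjunction: `"min"` (default) or `"prod"`.
#' @param implication rule implication: `"min"` (clipping, default) or
#'   `"prod"` (scaling).
#' @param aggregation aggregation of rule outputs: `"max"` (default).
#' @param defuzzification `"centroid"` (the only method shipped).
#' @param resolution number of uniform samples of the output universe used
#'   by centroid defuzzification (default 1001).
#' @return an object of class `mamdani_model`.
#' @seealso [infer()], [predict.mamdani_model()], [defuzzify_centroid()]
#' @export
mamdani_model <- function(inputs, output, rules = NULL,
                          and_op = c("min", "prod"),
                          implication = c("min", "prod"),
                          aggregation = "max",
                          defuzzification = "centroid",
                          resolution = 1001L) {
  and_op <- match.arg(and_op)
  implication <- match.arg(implication)
  if (!identical(aggregation, "max"))
    stop_config("only max aggregation is supported")
  if (!identical(defuzzification, "centroid"))
    stop_config("only centroid defuzzification is supported")
  if (resolution < 3) stop_config("resolution must be >= 3")
  for (v in inputs) stopifnot(inherits(v, "fuzzy_variable"))
  stopifnot(inherits(output, "fuzzy_variable"))
  names(inputs) <- vapply(inputs, `[[`, "", "name")
  if (anyDuplicated(names(inputs))) stop_config("duplicate input variable names")
  if (output$name %in% names(inputs))
    stop_config("output variable name collides with an input")
  rules <- validate_rules(rules, inputs, output)
  structure(list(inputs = inputs, output = output, rules = rules,
                 options = list(and_op = and_op, implication = implication,
                                aggregation = aggregation,
                                defuzzification = defuzzification,
                                resolution = as.integer(resolution))),
            class = "mamdani_model")
}

validate_rules <- function(rules, inputs, output) {
  if (is.null(rules))
    rules <- as.data.frame(c(stats::setNames(rep(list(character(0)), length(inputs)),
                                             names(inputs)),
                             list(consequent = character(0), enabled = logical(0))))
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(inputs), names(rules))
  if (length(missing_cols))
    stop_config(paste("rule table lacks antecedent columns:",
                      paste(missing_cols, collapse = ", ")))
  if (!"consequent" %in% names(rules))
    stop_config("rule table lacks a 'consequent' column")
  if (!"enabled" %in% names(rules)) rules$enabled <- TRUE
  for (vn in names(inputs)) {
    bad <- setdiff(unique(rules[[vn]]), var_labels(inputs[[vn]]))
    if (length(bad))
      stop_config(sprintf("rules reference unknown '%s' labels: %s",
                          vn, paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(rules$consequent), var_labels(output))
  if (length(bad))
    stop_config(paste("rules reference unknown output labels:",
                      paste(bad, collapse = ", ")))
  rules[c(names(inputs), "consequent", "enabled")]
}

#' @export
print.mamdani_model <- function(x, ...) {
  cat("Mamdani fuzzy inference model\n")
  cat(sprintf("  inputs : %s\n",
              paste(sprintf("%s(%d)", names(x$inputs),
                            vapply(x$inputs, function(v) length(v$sets), 0L)),
                    collapse = ", ")))
  cat(sprintf("  output : %s(%d) on [%g, %g]\n", x$output$name,
              length(x$output$sets), x$output$universe[1], x$output$universe[2]))
  cat(sprintf("  rules  : %d (%d enabled)\n", nrow(x$rules), sum(x$rules$enabled)))
  cat(sprintf("  engine : AND=%s, implication=%s, aggregation=%s, %s @ %d samples\n",
              x$options$and_op, x$options$implication, x$options$aggregation,
              x$options$defuzzification, x$options$resolution))
  invisible(x)
}

#' @export
summary.mamdani_model <- function(object, ...) {
  print(object)
  for (v in c(object$inputs, list(object$output))) print(v)
  if (nrow(object$rules)) {
    tab <- table(factor(object$rules$consequent, levels = var_labels(object$output)),
                 object$rules$enabled)
    cat("consequent x enabled:\n"); print(tab)
  }
  invisible(object)
}

#' Fire one rule against fuzzified inputs
#'
#' Combines the membership degrees of a rule's antecedent labels with the
#' model's AND operator (default: minimum). Disabled rules have activation 0.
#'
#' @param rule one-row data frame (or named list) with one label per input
#'   variable and optionally `enabled`.
#' @param degrees named list: for each input variable name, the named degree
#'   vector returned by [fuzzify()].
#' @param and_op `"min"` or `"prod"`.
#' @return activation in `[0, 1]`.
#' @export
fire_rule <- function(rule, degrees, and_op = "min") {
  if (isFALSE(rule$enabled %||% TRUE)) return(0)
  vars <- setdiff(names(degrees), c("consequent", "enabled"))
  need <- setdiff(names(rule), c("consequent", "enabled"))
  need <- need[!vapply(rule[need], is.na, TRUE)]
  if (!all(need %in% names(degrees)))
    stop_input(paste("fire_rule: degrees missing for",
                     paste(setdiff(need, names(degrees)), collapse = ", ")))
  d <- vapply(need, function(vn) {
    lab <- as.character(rule[[vn]])
    val <- degrees[[vn]][lab]
    if (is.na(val)) stop_input(sprintf("fire_rule: no degree for %s='%s'", vn, lab))
    val
  }, numeric(1))
  if (and_op == "prod") prod(d) else min(d)
}

# Aggregated output membership sampled on x: max over output sets of the
# activation-combined set membership (min clipping or prod scaling).
aggregate_surface <- function(output, activations, x, implication = "min") {
  mu <- numeric(length(x))
  for (lab in names(activations)) {
    a <- activations[[lab]]
    if (a <= 0) next
    m <- membership(output$sets[[lab]], x)
    m <- if (implication == "prod") m * a else pmin(m, a)
    mu <- pmax(mu, m)
  }
  mu
}

#' Centroid defuzzification
#'
#' Computes the crisp output as the center of gravity of the aggregated
#' output membership surface: every activated output set is clipped (min
#' implication) or scaled (prod) at its activation, the clipped sets are
#' combined by pointwise maximum, and the centroid
#' \eqn{\int x\,\mu(x)\,dx / \int \mu(x)\,dx} is evaluated by the composite
#' trapezoid rule on a uniform sampling of the output universe.
#'
#' @param output the output [fuzzy_variable].
#' @param activations named numeric vector/list: activation per output set
#'   label (labels with activation 0 may be omitted).
#' @param resolution number of uniform samples (default 1001).
#' @param implication `"min"` or `"prod"`.
#' @return crisp value inside the output universe.
#' @export
defuzzify_centroid <- function(output, activations, resolution = 1001L,
                               implication = "min") {
  activations <- as.list(activations)
  bad <- setdiff(names(activations), var_labels(output))
  if (length(bad))
    stop_config(paste("unknown output labels:", paste(bad, collapse = ", ")))
  if (length(activations) == 0 || all(unlist(activations) <= 0))
    stop_compute("no rule fired: all output activations are zero",
                 data = activations)
  x <- seq(output$universe[1], output$universe[2], length.out = resolution)
  mu <- aggregate_surface(output, activations, x, implication)
  w <- rep(1, resolution); w[c(1, resolution)] <- 0.5   # trapezoid weights
  denom <- sum(w * mu)
  if (denom <= 0)
    stop_compute("no rule fired: aggregated output surface is zero",
                 data = activations)
  sum(w * mu * x) / denom
}

#' Run Mamdani inference on crisp inputs
#'
#' Full inference cycle: fuzzification, rule firing, aggregation, centroid
#' defuzzification, and labeling of the crisp output. The winning label is
#' the output set with maximal membership at the crisp value; exact ties are
#' broken in favor of the later (more severe) set in the output variable's
#' configured order — for a screening system a false negative is costlier
#' than a false positive.
#'
#' @param model a [mamdani_model].
#' @param values named list/vector of crisp values, one per input variable.
#' @return list with elements `score` (crisp output), `label` (winning output
#'   set), `activations` (per output set), and `fired` (data frame of rules
#'   with activation > 0).
#' @export
infer <- function(model, values) {
  stopifnot(inherits(model, "mamdani_model"))
  values <- as.list(values)
  missing_vars <- setdiff(names(model$inputs), names(values))
  if (length(missing_vars))
    stop_input(paste("infer: missing input variables:",
                     paste(missing_vars, collapse = ", ")))
  degrees <- lapply(model$inputs, function(v) fuzzify(v, as.numeric(values[[v$name]])))

  rules <- model$rules
  if (nrow(rules) == 0)
    stop_compute("no rule fired: rule base is empty", data = values)
  act_rule <- vapply(seq_len(nrow(rules)), function(i)
    fire_rule(rules[i, , drop = FALSE], degrees, model$options$and_op), numeric(1))

  out_labels <- var_labels(model$output)
  activations <- stats::setNames(
    vapply(out_labels,
           function(lab) max(0, act_rule[rules$consequent == lab]),
           numeric(1)),
    out_labels)
  if (all(activations <= 0))
    stop_compute("no rule fired for the supplied inputs",
                 data = list(inputs = values,
                             degrees = lapply(degrees, round, digits = 4)))
  score <- defuzzify_centroid(model$output, activations,
                              resolution = model$options$resolution,
                              implication = model$options$implication)
  fired <- rules[act_rule > 0, , drop = FALSE]
  fired$activation <- act_rule[act_rule > 0]
  list(score = score,
       label = label_at(model$output, score),
       activations = activations,
       fired = fired)
}

# Output label with maximal membership at a crisp value; ties go to the
# later (more severe) set in configured order.
label_at <- function(output, score) {
  mu <- vapply(output$sets, membership, numeric(1), x = score)
  labs <- var_labels(output)
  labs[max(which(mu == max(mu)))]
}

#' Predict method for Mamdani models
#'
#' Applies [infer()] row-wise to a data frame of crisp inputs.
#'
#' @param object a [mamdani_model].
#' @param newdata data frame with one column per input variable.
#' @param ... unused.
#' @return data frame with columns `score` and `label`.
#' @export
predict.mamdani_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  res <- lapply(seq_len(nrow(newdata)), function(i)
    infer(object, as.list(newdata[i, names(object$inputs), drop = FALSE])))
  data.frame(score = vapply(res, `[[`, numeric(1), "score"),
             label = vapply(res, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}
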