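# Cached model builds shared across test files (building the risk base
# evaluates the severity policy over all 972 combinations).
.agcdx_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .agcdx_cache))
    assign(name, force(expr), envir = .agcdx_cache)
  get(name, envir = .agcdx_cache)
}

risk_model_default <- function() cached("risk_model", build_risk_model())
injury_model_default <- function() cached("injury_model", build_injury_model())

# Bare models (no rule base) for classification / enumeration checks.
risk_model_bare <- function() cached("risk_bare", build_risk_model(rules = NA))
injury_model_bare <- function() cached("injury_bare", build_injury_model(rules = NA))

# The three published worked-case clinical records.
worked_case_records <- function() list(
  case1 = clinical_record(age = 47, ivsa = 23, ps = 2, ng = 1, pg = 27,
                          ets = FALSE, le = FALSE),
  case5 = clinical_record(age = 43, ivsa = 16, ps = 1, ng = 7, pg = 28,
                          ets = FALSE, le = FALSE),
  case8 = clinical_record(age = 50, ivsa = 19, ps = 3, ng = 7, pg = 20,
                          ets = FALSE, le = TRUE))
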