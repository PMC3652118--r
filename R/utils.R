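# Error conditions carrying the CLI exit-code taxonomy:
#   input error (1), configuration error (2), computation error (3).

stop_input <- function(msg, data = NULL) {
  stop(structure(class = c("agcdx_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), data = data)))
}

stop_config <- function(msg) {
  stop(structure(class = c("agcdx_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_compute <- function(msg, data = NULL) {
  stop(structure(class = c("agcdx_compute_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), data = data)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable fingerprint of an R object (used for config/report provenance).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse_json(x), f)
  unname(tools::md5sum(f))
}

deparse_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                force = TRUE, null = "null"))
}
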