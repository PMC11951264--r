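# Condition constructors. Every error raised by the package carries a
# subclass of "hfa_error" so callers can catch specific failure modes.

abort_hfa <- function(message, class, ...) {
  stop(structure(
    class = c(class, "hfa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

design_error        <- function(msg, ...) abort_hfa(msg, "hfa_design_error", ...)
schema_error        <- function(msg, ...) abort_hfa(msg, "hfa_schema_error", ...)
mass_gain_error     <- function(msg, ...) abort_hfa(msg, "hfa_mass_gain_error", ...)
value_error         <- function(msg, ...) abort_hfa(msg, "hfa_value_error", ...)
undefined_ratio_error <- function(msg, ...) abort_hfa(msg, "hfa_undefined_ratio_error", ...)
incomplete_design_error <- function(msg, ...) abort_hfa(msg, "hfa_incomplete_design_error", ...)
empty_sample_error  <- function(msg, ...) abort_hfa(msg, "hfa_empty_sample_error", ...)
insufficient_data_error <- function(msg, ...) abort_hfa(msg, "hfa_insufficient_data_error", ...)
degenerate_factor_error <- function(msg, ...) abort_hfa(msg, "hfa_degenerate_factor_error", ...)
degenerate_predictor_error <- function(msg, ...) abort_hfa(msg, "hfa_degenerate_predictor_error", ...)
format_error        <- function(msg, ...) abort_hfa(msg, "hfa_format_error", ...)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation helpers have no side
# effects on the session RNG. seed = NULL uses (and advances) the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
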