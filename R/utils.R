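#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a labelled draw (day/mode/site), derived from the
# scenario seed so every emitted dataset is reproducible stream by stream.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "|")
  codes <- utf8ToInt(parts)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("biofilmNMR_input_error", "error")))
}

stop_config <- function(key, msg) {
  stop(errorCondition(
    sprintf("invalid configuration key '%s': %s", key, msg),
    class = c("biofilmNMR_config_error", "error")
  ))
}

stop_computation <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("biofilmNMR_computation_error", "error")
  ))
}

stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("biofilmNMR_fit_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
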