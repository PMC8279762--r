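# internal argument checking helpers ----------------------------------------

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("smc_param_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("smc_format_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (length(x) == 0 && allow_zero_len) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("'", name, "' must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_param("'", name, "' must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != floor(x))) {
    stop_param("'", name, "' must contain non-negative integer counts")
  }
  invisible(x)
}

# deterministic child seed derived from a user seed; kept below 2^31
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
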