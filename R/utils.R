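# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#'
#' All package errors carry class `thrombolyzer_error` plus a specific
#' subclass so callers (and tests) can distinguish failure modes.
#' @noRd
stop_with <- function(subclass, msg, call = FALSE) {
  cond <- structure(
    class = c(subclass, "thrombolyzer_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call)) sys.call(-1) else NULL)
  )
  stop(cond)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_with("thrombolyzer_invalid_input",
              sprintf("`%s` must be a single finite number", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop_with("thrombolyzer_invalid_input",
              sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

#' Evaluate code with a local, restorable RNG state
#'
#' Seeds are always explicit function arguments in this package; the global
#' RNG stream of the caller is left untouched.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stable 31-bit string hash
#'
#' Deterministic across sessions and platforms (pure modular arithmetic on
#' UTF-8 bytes), used to derive per-animal seeds so that adding a group to a
#' study never perturbs the data of existing animals.
#' @noRd
stable_hash <- function(s) {
  b <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (k in b) h <- (h * 31 + k) %% 2147483647
  h
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
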