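stopf <- function(fmt, ..., class = "mcdose_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || (!allow_zero && x == lower))
    stopf("`%s` must be %s %s", name, if (allow_zero) ">=" else ">", format(lower))
  invisible(x)
}

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' Uses a polynomial rolling hash of the stage name (mod 2^31 - 1) combined
#' with the master seed, so that one master seed deterministically fans out
#' to every stage of a workflow without seed collisions between stages.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  check_number(master_seed, "master_seed")
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# round a positive scale up to the nearest power of two so that
# scale/unscale round-trips are exact in floating point
pow2_ceiling <- function(x) {
  stopifnot(x > 0)
  2^ceiling(log2(x))
}
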