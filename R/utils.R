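# Seed plumbing and small numeric helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so library internals never perturb user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Deterministically hashes a base seed together with any number of string or
#' integer labels into a 32-bit-safe positive integer. Every stochastic stage
#' (per-patient angle draws, per-epoch shuffles, per-image augmentation, ...)
#' draws its seed through this, so whole simulations are pure functions of one
#' top-level seed.
#'
#' @param ... integers and/or character labels; the first is conventionally
#'   the base seed.
#' @return a positive integer < 2^31.
#' @export
derive_seed <- function(...) {
  parts <- list(...)
  m <- 2147483629  # largest prime < 2^31; keeps arithmetic exact in doubles
  h <- 17
  for (p in parts) {
    if (is.character(p)) {
      codes <- utf8ToInt(paste(p, collapse = "\x1f"))
    } else {
      codes <- as.numeric(p)
      codes[!is.finite(codes)] <- 0
      codes <- abs(codes) %% m
    }
    for (cc in codes) h <- (h * 31 + cc + 7) %% m
  }
  as.integer(h) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fedspine <- function(msg, class) {
  stop(structure(class = c(class, "fedspine_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
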