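#' Canonical muscle channel order
#'
#' The seven surface-EMG channels used throughout the package, in canonical
#' order: Rectus Femoris (RF), Vastus Lateralis (VL), Vastus Medialis (VM),
#' Semitendinosus (Se), Biceps Femoris (BF), Medial Gastrocnemius (MG) and
#' Tibialis Anterior (TA).  RF/VL/VM are the quadriceps knee extensors,
#' Se/BF are hamstring flexors, MG is a biarticular flexor at the knee and
#' TA acts about the ankle.
#'
#' @format Character vector of length 7.
#' @export
knee_muscles <- c("RF", "VL", "VM", "Se", "BF", "MG", "TA")

## Run `code` with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

## Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(root, ...) {
  parts <- c(root, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 104729) %% 2147483629
  as.integer(s) + 1L
}

cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}
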