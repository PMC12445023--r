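#' @keywords internal
"_PACKAGE"

#' @useDynLib twinscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

ts_error <- function(code, msg) {
  stop(errorCondition(msg, class = c(code, "twinscreen_error", "error", "condition")))
}

ts_warning <- function(code, msg) {
  warning(warningCondition(msg, class = c(code, "twinscreen_warning", "warning", "condition")))
}

# 32-bit FNV-1a over a character string; arithmetic kept exact in doubles by
# splitting the 32-bit state before the prime multiplication.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% two16), b) + (h %/% two16) * two16
    lo <- h %% two16
    hi <- h %/% two16
    h <- (lo * p + ((hi * p) %% two16) * two16) %% two32
  }
  h
}

# Deterministic sub-seed (< 2^31) from a master seed and arbitrary labels.
derive_seed <- function(master_seed, ...) {
  key <- paste(c(format(master_seed), vapply(list(...), format, character(1))),
               collapse = "|")
  as.integer(fnv1a32(key) %% 2147483647) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable short hash of an R object (used for run manifests).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  format(fnv1a32(s), scientific = FALSE)
}
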