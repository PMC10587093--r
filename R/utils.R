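# Internal helpers: deterministic seed derivation and cheap hashing.

# FNV-1a 32-bit over a character string, reduced into [1, .Machine$integer.max].
# Arithmetic done in double; all intermediates < 2^53 so this is exact.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# bitwXor for doubles holding 32-bit unsigned values.
bitwXor_dbl <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

#' Derive a named child seed from a master seed
#'
#' Hierarchical seeding: every stochastic stage of the pipeline (cohort
#' generation, replicate generation, CV plan, permutation shuffles,
#' bootstrap, perturbation) draws its own seed deterministically from a
#' single master seed plus a stream name, so stages can be re-run
#' independently and whole runs replayed exactly.
#'
#' @param seed integer master seed.
#' @param stream character stream name, e.g. `"cohort"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- fnv1a32(paste0(format(seed, scientific = FALSE), "/", stream))
  as.integer(h %% 2147483646) + 1L
}

# Config fingerprint used in run manifests; the output directory is not
# part of a run's identity.
config_hash <- function(x) {
  x$out_dir <- NULL
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  h <- fnv1a32(txt)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
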