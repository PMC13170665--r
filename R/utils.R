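# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed and restore the caller's RNG state,
# so generators are reproducible without clobbering the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' One master seed fans out to per-stage seeds by a fixed polynomial string
#' hash, so each stage can be rerun independently yet reproducibly. The
#' result is always a valid R integer seed in `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"wue_noise"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps every intermediate exact in doubles
  h <- 17
  for (code in utf8ToInt(paste0(format(seed), ":", stage))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Small stable hash for provenance blocks (FNV-1a over bytes, folded to
# 31 bits so arithmetic stays exact in doubles).
text_hash <- function(x) {
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- (bitwXor(as.integer(h), code) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# OLS slope (per year) of y on t, NAs dropped; NA when < 2 points or no
# time spread.
ols_slope <- function(y, t) {
  ok <- is.finite(y) & is.finite(t)
  if (sum(ok) < 2L) return(NA_real_)
  y <- y[ok]; t <- t[ok]
  tc <- t - mean(t)
  den <- sum(tc^2)
  if (den <= 0) return(NA_real_)
  sum(tc * (y - mean(y))) / den
}
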