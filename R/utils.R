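`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_bad_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE) {
  ok <- is.numeric(x) & !is.na(x) &
    (if (open_lo) x > lo else x >= lo) &
    (if (open_hi) x < hi else x <= hi)
  if (!all(ok))
    stop_bad_arg(sprintf("`%s` must lie in %s%g, %g%s", name,
                         if (open_lo) "(" else "[", lo, hi,
                         if (open_hi) ")" else "]"))
  as.numeric(x)
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Hashes the global seed together with a stage label so that each pipeline
#' stage gets an independent but reproducible RNG stream. The result is kept
#' below 2^31.
#'
#' @param seed single integer global seed.
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  key <- paste0(as.integer(seed), ":", stage)
  # FNV-1a over the key bytes, folded into a positive 31-bit integer
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483562L + 1L)
}
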