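#' Derive a deterministic sub-stream seed for a named pipeline stage
#'
#' One global seed drives the whole pipeline; each stage (atlas, expression,
#' activation, ...) draws from its own sub-stream so stages can be regenerated
#' independently without replaying the ones before them. The stage name is
#' hashed (order-sensitive) into an offset and combined with the global seed
#' modulo a prime below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "atlas")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  b <- utf8ToInt(stage)
  h <- sum(b * seq_along(b) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483587)
}

#' 32-bit FNV-1a hash of a character scalar
#'
#' Used to stamp output files with a short provenance hash of the
#' configuration that produced them.
#'
#' @param txt character scalar.
#' @return hexadecimal hash string.
#' @export
fnv1a_hash <- function(txt) {
  stopifnot(is.character(txt), length(txt) == 1L)
  mulmod32 <- function(h, m) {
    hi <- h %/% 65536
    lo <- h %% 65536
    (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    # xor the low byte only; bytes are < 256 so this is exact in doubles
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_imtx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
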