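# Internal helpers shared across modules.

# Coordinate conventions used throughout:
#   * variant and pileup positions are 1-based (VCF convention)
#   * fragment intervals are 0-based half-open (BED convention)
# Converters are exported so the two never get mixed silently.

#' Convert between BED-style and VCF-style coordinates
#'
#' Fragment tables use 0-based half-open intervals (BED); variant positions
#' use 1-based coordinates (VCF). `bed_to_pos()` returns the 1-based position
#' of the first base of a 0-based interval start; `pos_to_bed()` is the
#' inverse.
#'
#' @param start0 Integer vector of 0-based interval starts.
#' @param pos1 Integer vector of 1-based positions.
#' @return Integer vector in the other convention.
#' @examples
#' bed_to_pos(0L) # 1
#' pos_to_bed(1L) # 0
#' @export
bed_to_pos <- function(start0) {
  as.integer(start0) + 1L
}

#' @rdname bed_to_pos
#' @export
pos_to_bed <- function(pos1) {
  as.integer(pos1) - 1L
}

# inverse logit / logit with clamping for numerical safety
inv_logit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

# FNV-1a 32-bit digest of a character scalar; used to fingerprint locked
# model feature panels without an external digest dependency.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- h %% 2^32
    # 32-bit multiply by FNV prime 16777619 via split arithmetic
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 2^32
  }
  # h is a double holding an unsigned 32-bit value; format as hex manually
  digits <- integer(8)
  for (i in 8:1) {
    digits[i] <- h %% 16
    h <- h %/% 16
  }
  paste(strsplit("0123456789abcdef", "")[[1]][digits + 1], collapse = "")
}

# Derive a bounded substream seed from a master seed and a stream index.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647)
}

assert_prob <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "cfmonitor_config_error")
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(is.na(x)) || any(x <= 0) else any(is.na(x)) || any(x < 0)
  if (bad) {
    abort(sprintf("`%s` must be %s.", name, if (strict) "> 0" else ">= 0"),
          class = "cfmonitor_config_error")
  }
  invisible(x)
}
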