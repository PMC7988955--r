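# internal helpers shared across modules

CONTEXTS <- c("CpG", "CHG", "CHH", "Dam", "Dcm")
H_BASES <- c("A", "C", "T")

#' @noRd
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

#' @noRd
comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_chr(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# base vector lookup with circular wrap; out-of-range positions give NA on
# linear sequences so windows falling off an end never match
#' @noRd
base_at <- function(chars, idx, circular) {
  len <- length(chars)
  if (circular) {
    chars[wrap_pos(idx, len)]
  } else {
    out <- rep(NA_character_, length(idx))
    ok <- idx >= 1L & idx <= len
    out[ok] <- chars[idx[ok]]
    out
  }
}

# forward-strand start positions of a literal motif, circular-aware
#' @noRd
find_motif <- function(chars, motif, circular) {
  k <- nchar(motif)
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  len <- length(chars)
  lim <- if (circular) len else len - k + 1L
  if (lim < 1L) return(integer(0))
  idx <- seq_len(lim)
  ok <- rep(TRUE, lim)
  for (j in seq_len(k)) {
    b <- base_at(chars, idx + j - 1L, circular)
    ok <- ok & !is.na(b) & b == m[j]
  }
  idx[ok]
}

#' @noRd
seq_chars <- function(genome) strsplit(genome$sequence, "", fixed = TRUE)[[1]]

#' @noRd
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed %% .Machine$integer.max)
}

# 1-based inclusive interval overlap on a circle: does position p fall in
# [start, end] where end may run past the sequence end (wrapped feature)?
#' @noRd
pos_in_interval <- function(pos, start, end, len = NULL) {
  if (!is.null(len) && end > len) {
    pos >= start | pos <= wrap_pos(end, len)
  } else {
    pos >= start & pos <= end
  }
}
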