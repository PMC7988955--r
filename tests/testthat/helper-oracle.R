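# Independent per-position context classifier used as the oracle for the
# vectorized scanner: every position/strand is classified from its local
# 9-bp window alone (no global motif search, no shared code path).

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTNX", "TGCANX", x), "")[[1]]), collapse = "")
}

oracle_scan <- function(seq, circular) {
  L <- nchar(seq)
  p <- 4L
  ext <- if (circular) {
    paste0(substr(seq, L - p + 1L, L), seq, substr(seq, 1L, p))
  } else {
    paste0(strrep("X", p), seq, strrep("X", p))
  }
  idx <- seq_len(L)
  w_plus <- substring(ext, idx, idx + 8L)
  ext_rc <- oracle_revcomp(ext)
  centre_rc <- L + p - idx + 1L
  w_minus <- substring(ext_rc, centre_rc - 4L, centre_rc + 4L)

  classify <- function(w) {
    a <- function(i) substr(w, i, i)
    h <- c("A", "C", "T")
    c4 <- a(4); c5 <- a(5); c6 <- a(6); c7 <- a(7); c8 <- a(8); c9 <- a(9)
    dam <- c5 == "A" & c4 == "G" & c6 == "T" & c7 == "C"
    dcm <- c5 == "C" & c4 == "C" & c6 %in% c("A", "T") & c7 == "G" & c8 == "G"
    dcm_first <- c5 == "C" & c6 == "C" & c7 %in% c("A", "T") & c8 == "G" &
      c9 == "G"
    cpg <- c5 == "C" & c6 == "G"
    chg <- c5 == "C" & c6 %in% h & c7 == "G"
    chh <- c5 == "C" & c6 %in% h & c7 %in% h
    out <- rep(NA_character_, length(w))
    out[chh] <- "CHH"
    out[chg] <- "CHG"
    out[cpg] <- "CpG"
    out[dcm_first] <- NA_character_   # unscorable first C of CCWGG
    out[dcm] <- "Dcm"
    out[dam] <- "Dam"
    out
  }
  cp <- classify(w_plus)
  cm <- classify(w_minus)
  out <- rbind(
    data.frame(position = idx[!is.na(cp)], strand = "+",
               context = cp[!is.na(cp)], stringsAsFactors = FALSE),
    data.frame(position = idx[!is.na(cm)], strand = "-",
               context = cm[!is.na(cm)], stringsAsFactors = FALSE)
  )
  out[order(out$position, out$strand, out$context), , drop = FALSE]
}

random_seq <- function(n, gc = 0.45, n_frac = 0) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
  if (n_frac > 0) {
    k <- rbinom(1, n, n_frac)
    if (k > 0) bases[sample.int(n, k)] <- "N"
  }
  paste(bases, collapse = "")
}

# rotate a circular sequence so old position (offset+1) becomes position 1
rotate_seq <- function(seq, offset) {
  L <- nchar(seq)
  offset <- offset %% L
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1, L), substr(seq, 1, offset))
}

scan_triples <- function(sites) {
  s <- sites[order(sites$position, sites$strand, sites$context),
             c("position", "strand", "context")]
  rownames(s) <- NULL
  s
}

make_records <- function(position, context, fraction, coverage = 50,
                         strand = "+", contig = "chr", base = NULL) {
  n <- length(position)
  if (is.null(base)) base <- ifelse(rep(context, length.out = n) == "Dam", "A", "C")
  data.frame(contig = rep(contig, length.out = n), position = position,
             strand = rep(strand, length.out = n),
             base = rep(base, length.out = n),
             context = rep(context, length.out = n),
             coverage = rep(coverage, length.out = n),
             fraction = rep(fraction, length.out = n),
             stringsAsFactors = FALSE)
}
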