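#' Select highly modified sites for de novo motif discovery
#'
#' Foreground selection for \code{\link{enrich_kmers}}: sites of the given
#' base with coverage and modification fraction above threshold. Accepts
#' any table with \code{position, strand, base, coverage, fraction}
#' columns (a genome-wide de novo call table is not restricted to the five
#' canonical contexts).
#'
#' @param records Per-site call table.
#' @param base \code{"A"} or \code{"C"}.
#' @param min_fraction Minimum fraction modified (default 0.5).
#' @param min_cov Minimum coverage (default 10).
#' @return Data.frame \code{position, strand, fraction}.
#' @export
select_modified_sites <- function(records, base, min_fraction = 0.5,
                                  min_cov = 10L) {
  keep <- records$base == base & records$coverage >= min_cov &
    records$fraction >= min_fraction
  out <- records[keep, c("position", "strand", "fraction"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# strand-oriented sequence windows of half-width `flank` around each site;
# reverse-strand windows are reverse complemented so the modified base
# reads in its own 5'->3' context. Returns a character matrix (sites x
# window positions); rows containing N or running off a linear end are
# dropped together with the corresponding entries of `extra`.
#' @noRd
site_windows <- function(genome, position, strand, flank, extra = NULL) {
  s <- seq_chars(genome)
  len <- length(s)
  circ <- genome$circular
  offs <- -flank:flank
  w <- matrix(NA_character_, nrow = length(position), ncol = length(offs))
  fwd <- strand == "+"
  for (j in seq_along(offs)) {
    w[fwd, j] <- base_at(s, position[fwd] + offs[j], circ)
    w[!fwd, j] <- comp_chr(base_at(s, position[!fwd] - offs[j], circ))
  }
  ok <- rowSums(is.na(w) | w == "N") == 0L
  list(windows = w[ok, , drop = FALSE],
       extra = if (is.null(extra)) NULL else extra[ok])
}

# (kmer, offset) token counts over a window matrix. Tokens are
# "KMER@o" where o is the 1-based offset of the modified base inside the
# k-mer. Returns a list with the token table and, optionally, the long
# (row, token) map for per-site bookkeeping.
#' @noRd
kmer_tokens <- function(windows, k, flank, keep_map = FALSE) {
  centre <- flank + 1L
  width <- 2L * flank + 1L
  starts <- max(1L, centre - k + 1L):min(centre, width - k + 1L)
  toks <- character(0)
  rows <- integer(0)
  wstr <- apply(windows, 1L, paste, collapse = "")
  for (st in starts) {
    kmer <- substring(wstr, st, st + k - 1L)
    toks <- c(toks, paste0(kmer, "@", centre - st + 1L))
    if (keep_map) rows <- c(rows, seq_along(wstr))
  }
  list(tab = table(toks), map = if (keep_map)
    data.frame(row = rows, token = toks, stringsAsFactors = FALSE) else NULL)
}

#' Count background k-mer contexts for a base
#'
#' Tokenizes the sequence context of every occurrence of \code{base} on
#' both strands of the genome. Using all same-base positions as background
#' makes the enrichment test immune to genome composition bias. The result
#' can be precomputed once and reused across \code{\link{enrich_kmers}}
#' calls on the same genome.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param base \code{"A"} or \code{"C"}.
#' @param k K-mer length (default 5).
#' @param flank Window half-width (default 4).
#' @return List with the token count table and the number of background
#'   sites.
#' @export
kmer_background <- function(genome, base, k = 5L, flank = 4L) {
  s <- seq_chars(genome)
  pos <- c(which(s == base), which(s == comp_chr(base)))
  strand <- rep(c("+", "-"), c(sum(s == base), sum(s == comp_chr(base))))
  sw <- site_windows(genome, pos, strand, flank)
  tk <- kmer_tokens(sw$windows, k, flank)
  list(tab = tk$tab, n_sites = nrow(sw$windows), k = k, flank = flank,
       base = base)
}

#' De novo discovery of enriched methylated-base motifs
#'
#' For each foreground site the strand-oriented window of half-width
#' \code{flank} around the modified base is extracted; every k-mer/offset
#' pair containing the modified base is counted and compared against the
#' same counts over all genomic occurrences of that base. Enrichment is
#' \code{log2[((f+1)/(F+2)) / ((b+1)/(B+2))]} (pseudocounts keep it
#' finite); significance is a one-sided binomial test at the background
#' rate, Bonferroni-corrected over the tested pairs. Surviving motifs are
#' ranked by enrichment and overlapping/nested motifs (consistent on all
#' shared positions relative to the modified base) are collapsed to the
#' highest-scoring representative.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param sites Foreground sites from \code{\link{select_modified_sites}}.
#' @param k K-mer length (default 5).
#' @param flank Window half-width (default 4).
#' @param min_sites Minimum foreground sites, overall and per reported
#'   motif (default 20).
#' @param alpha Bonferroni-corrected significance level (default 0.01).
#' @param background Optional precomputed \code{\link{kmer_background}}.
#' @return Data.frame of motifs ranked by enrichment: \code{consensus}
#'   (modified base bracketed, e.g. \code{"G(A)ACT"}), \code{kmer},
#'   \code{mod_offset}, \code{fg_count}, \code{bg_count},
#'   \code{log2_enrichment}, \code{p_value}, \code{p_adj},
#'   \code{frac_median}, \code{frac_q1}, \code{frac_q3}. Zero rows when
#'   nothing passes the corrected threshold.
#' @export
enrich_kmers <- function(genome, sites, k = 5L, flank = 4L, min_sites = 20L,
                         alpha = 0.01, background = NULL) {
  if (nrow(sites) < min_sites) {
    stop("too few foreground sites (", nrow(sites), " < ", min_sites, ")",
         call. = FALSE)
  }
  if (is.null(background)) {
    base <- infer_base(genome, sites)
    background <- kmer_background(genome, base, k = k, flank = flank)
  }
  stopifnot(background$k == k, background$flank == flank)
  sw <- site_windows(genome, sites$position, sites$strand, flank,
                     extra = sites$fraction)
  n_fg <- nrow(sw$windows)
  if (n_fg < min_sites) {
    stop("too few usable foreground windows", call. = FALSE)
  }
  tk <- kmer_tokens(sw$windows, k, flank, keep_map = TRUE)
  fg_tab <- tk$tab
  bg_tab <- background$tab
  n_bg <- background$n_sites

  tokens <- names(fg_tab)
  f <- as.integer(fg_tab)
  b <- as.integer(bg_tab[tokens])
  b[is.na(b)] <- 0L
  enr <- log2(((f + 1) / (n_fg + 2)) / ((b + 1) / (n_bg + 2)))
  pval <- stats::pbinom(f - 1L, n_fg, pmax(b, 1L) / n_bg, lower.tail = FALSE)
  n_tests <- length(tokens)
  p_adj <- pmin(1, pval * n_tests)
  pass <- p_adj < alpha & f >= min_sites
  if (!any(pass)) {
    return(empty_motif_frame())
  }
  cand <- data.frame(token = tokens[pass], fg_count = f[pass],
                     bg_count = b[pass], log2_enrichment = enr[pass],
                     p_value = pval[pass], p_adj = p_adj[pass],
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$log2_enrichment, cand$p_adj), , drop = FALSE]

  parse_token <- function(tok) {
    sp <- strsplit(tok, "@", fixed = TRUE)[[1]]
    list(kmer = sp[1], off = as.integer(sp[2]))
  }
  relmap <- function(tok) {
    p <- parse_token(tok)
    bases <- strsplit(p$kmer, "")[[1]]
    stats::setNames(bases, seq_along(bases) - p$off)
  }
  consistent <- function(a, b) {
    shared <- intersect(names(a), names(b))
    length(shared) > 0L && all(a[shared] == b[shared])
  }
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    rm_i <- relmap(cand$token[i])
    if (!any(vapply(kept, consistent, logical(1), b = rm_i))) {
      kept[[length(kept) + 1L]] <- rm_i
      attr(kept[[length(kept)]], "row") <- i
    }
  }
  rows <- vapply(kept, attr, integer(1), "row")
  out <- cand[rows, , drop = FALSE]

  info <- lapply(out$token, parse_token)
  out$kmer <- vapply(info, `[[`, character(1), "kmer")
  out$mod_offset <- vapply(info, `[[`, integer(1), "off")
  out$consensus <- mapply(function(kmer, off) {
    paste0(substr(kmer, 1, off - 1), "(", substr(kmer, off, off), ")",
           substr(kmer, off + 1, nchar(kmer)))
  }, out$kmer, out$mod_offset, USE.NAMES = FALSE)

  # per-motif distribution of foreground fractions
  qs <- t(vapply(out$token, function(tok) {
    rows_tok <- tk$map$row[tk$map$token == tok]
    fr <- sw$extra[unique(rows_tok)]
    stats::quantile(fr, c(0.25, 0.5, 0.75), names = FALSE)
  }, numeric(3)))
  out$frac_q1 <- qs[, 1]; out$frac_median <- qs[, 2]; out$frac_q3 <- qs[, 3]
  out$token <- NULL
  rownames(out) <- NULL
  out[, c("consensus", "kmer", "mod_offset", "fg_count", "bg_count",
          "log2_enrichment", "p_value", "p_adj", "frac_median",
          "frac_q1", "frac_q3")]
}

#' @noRd
infer_base <- function(genome, sites) {
  s <- seq_chars(genome)
  len <- length(s)
  i <- which(sites$strand == "+")[1]
  if (!is.na(i)) return(s[wrap_pos(sites$position[i], len)])
  comp_chr(s[wrap_pos(sites$position[1], len)])
}

#' @noRd
empty_motif_frame <- function() {
  data.frame(consensus = character(0), kmer = character(0),
             mod_offset = integer(0), fg_count = integer(0),
             bg_count = integer(0), log2_enrichment = numeric(0),
             p_value = numeric(0), p_adj = numeric(0),
             frac_median = numeric(0), frac_q1 = numeric(0),
             frac_q3 = numeric(0), stringsAsFactors = FALSE)
}
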