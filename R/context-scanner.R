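#' Enumerate methylation-context sites on both strands
#'
#' Scans a (possibly circular) genome for the five contexts the methylome
#' pipeline scores:
#' \itemize{
#'   \item \strong{Dam}: the palindrome \code{GATC}; one duplex locus yields
#'     two adenine sites, one per strand.
#'   \item \strong{Dcm}: \code{CCWGG} (\code{CCAGG}/\code{CCTGG}, a
#'     self-complementary motif set); the scorable base is the second
#'     cytosine of each strand's reading.
#'   \item \strong{CpG / CHG / CHH}: cytosine trinucleotide contexts
#'     (H = A, C or T), assigned per strand with precedence
#'     CpG > CHG > CHH for cytosines not inside a Dcm occurrence.
#' }
#' The forward strand is scanned directly; the reverse strand is scanned as
#' the reverse complement with positions mapped back to forward coordinates.
#' On circular genomes motifs may span the origin. Windows containing
#' \code{N} yield no site.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @return Data.frame with columns \code{contig, position, strand, context,
#'   duplex_locus}; \code{position} is the scorable base (the C, or the A of
#'   GATC), \code{duplex_locus} the leftmost forward-strand coordinate of the
#'   motif occurrence (used to collapse palindromic sites).
#' @export
scan_contexts <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  s <- seq_chars(genome)
  len <- length(s)
  circ <- genome$circular

  res <- list()
  add <- function(position, strand, context, duplex) {
    if (length(position) == 0L) return()
    res[[length(res) + 1L]] <<- data.frame(
      position = wrap_pos(position, len), strand = strand, context = context,
      duplex_locus = wrap_pos(duplex, len), stringsAsFactors = FALSE)
  }

  # palindromic adenine motif: GATC
  p <- find_motif(s, "GATC", circ)
  add(p + 1L, "+", "Dam", p)
  add(p + 2L, "-", "Dam", p)

  # CCWGG: second C of each strand's 5'->3' reading is scorable
  pd <- sort(c(find_motif(s, "CCAGG", circ), find_motif(s, "CCTGG", circ)))
  add(pd + 1L, "+", "Dcm", pd)
  add(pd + 3L, "-", "Dcm", pd)

  # cytosines inside a Dcm occurrence carry no trinucleotide label
  dcm_mask_fwd <- wrap_pos(c(pd, pd + 1L), len)       # forward-strand C's
  dcm_mask_rev <- wrap_pos(c(pd + 3L, pd + 4L), len)  # reverse-strand C's

  # forward-strand cytosines
  ci <- setdiff(which(s == "C"), dcm_mask_fwd)
  if (length(ci)) {
    b1 <- base_at(s, ci + 1L, circ)
    b2 <- base_at(s, ci + 2L, circ)
    is_cpg <- !is.na(b1) & b1 == "G"
    h1 <- !is.na(b1) & b1 %in% H_BASES
    is_chg <- h1 & !is.na(b2) & b2 == "G"
    is_chh <- h1 & !is.na(b2) & b2 %in% H_BASES
    add(ci[is_cpg], "+", "CpG", ci[is_cpg])
    add(ci[is_chg], "+", "CHG", ci[is_chg])
    add(ci[is_chh], "+", "CHH", ci[is_chh])
  }

  # reverse-strand cytosines sit opposite forward G's; their downstream
  # bases are the complements of the forward bases immediately 5' of the G
  gi <- setdiff(which(s == "G"), dcm_mask_rev)
  if (length(gi)) {
    r1 <- comp_chr(base_at(s, gi - 1L, circ))
    r2 <- comp_chr(base_at(s, gi - 2L, circ))
    is_cpg <- !is.na(r1) & r1 == "G"
    h1 <- !is.na(r1) & r1 %in% H_BASES
    is_chg <- h1 & !is.na(r2) & r2 == "G"
    is_chh <- h1 & !is.na(r2) & r2 %in% H_BASES
    add(gi[is_cpg], "-", "CpG", gi[is_cpg] - 1L)
    add(gi[is_chg], "-", "CHG", gi[is_chg] - 2L)
    add(gi[is_chh], "-", "CHH", gi[is_chh] - 2L)
  }

  if (length(res) == 0L) {
    out <- data.frame(position = integer(0), strand = character(0),
                      context = character(0), duplex_locus = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
  }
  out <- cbind(contig = rep(genome$name, nrow(out)), out,
               stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of context sites and duplex loci
#'
#' Counts per-strand sites and distinct duplex loci for every context, the
#' "number of motifs" denominators of a methylome summary table. CHH, being
#' asymmetric, is additionally reported split by strand.
#'
#' @param sites Data.frame from \code{\link{scan_contexts}}.
#' @return Data.frame with columns \code{context, n_sites, n_duplex_loci};
#'   rows for each of the five contexts plus \code{CHH_fwd} and
#'   \code{CHH_rev}.
#' @export
context_census <- function(sites) {
  one <- function(label, sub) {
    data.frame(context = label, n_sites = nrow(sub),
               n_duplex_loci = length(unique(sub$duplex_locus)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(CONTEXTS, function(cx) one(cx, sites[sites$context == cx, ]))
  rows <- c(rows, list(
    one("CHH_fwd", sites[sites$context == "CHH" & sites$strand == "+", ]),
    one("CHH_rev", sites[sites$context == "CHH" & sites$strand == "-", ])
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
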