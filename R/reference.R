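#' Published reference values for the DRI-13 chromosome
#'
#' The printed summary values for the closed *Thermanaerosceptrum
#' fracticalcis* DRI-13 chromosome (JGI 2842667859 / NCBI GCA_000746025.2)
#' that this package's simulation preset emulates and that
#' \code{\link{verify_reference_assembly}} checks a downloaded assembly
#' against: genome metrics, the per-context methylation summary, the
#' strand-resolved gene counts per Mb, both CRISPR arrays (coordinates,
#' repeat sequences, element counts) and the four prophage intervals.
#'
#' @return A list of reference constants.
#' @export
dri13_reference <- function() {
  list(
    genome_length = 3805411L,
    gc = 0.45,
    genes_total = 4022L,
    cds_total = 3884L,
    methylation = data.frame(
      context = c("CpG", "Dcm", "Dam", "CHH_fwd", "CHH_rev"),
      n_motifs = c(133910L, 18831L, 4903L, 363179L, 365658L),
      methylation_pct = c(4.28, 3.81, 76.40, 17.41, 17.39),
      coverage = c(121, 94, 42, 54, 53.5),
      stringsAsFactors = FALSE
    ),
    strand_counts = data.frame(
      bin = 1:4,
      forward = c(740L, 175L, 385L, 675L),
      reverse = c(325L, 836L, 596L, 152L),
      stringsAsFactors = FALSE
    ),
    arrays = list(
      array1 = list(region = c(638577L, 639957L),
                    repeat_seq = "GTTGCAATGCCTAGCTCAGAGGTTTAAAGACTGAGAC",
                    n_repeats = 19L, n_spacers = 18L),
      array2 = list(region = c(1393508L, 1399131L),
                    repeat_seq = "CTTTCAGTCCCCATGTATCGGGTCTATTCAATGGAAC",
                    n_repeats = 76L, n_spacers = 75L)
    ),
    prophages = data.frame(
      start = c(566157L, 1114566L, 2229417L, 3768183L),
      length = c(14900L, 22300L, 20500L, 36100L),
      stringsAsFactors = FALSE
    ),
    enriched_motifs = c(A = "G(A)ACT", C = "C(C)GG")
  )
}

#' Check a downloaded reference assembly against the published values
#'
#' Recomputes, from a local copy of the GCA_000746025.2 chromosome (FASTA)
#' and its annotation (GFF3), the quantities whose published values
#' \code{\link{dri13_reference}} records: genome length, Dam/Dcm/CHH motif
#' counts, CRISPR spacer counts from the printed regions and repeats,
#' per-Mb strand-resolved CDS counts, and the CDS total. The assembly is
#' not shipped with the package and must be supplied by the user.
#'
#' @param fasta_path Path to the chromosome FASTA.
#' @param gff_path Path to the GFF3 annotation.
#' @return Data.frame with columns \code{quantity, expected, observed}.
#' @export
verify_reference_assembly <- function(fasta_path, gff_path) {
  ref <- dri13_reference()
  genome <- read_genome(fasta_path, circular = TRUE)[[1]]
  sites <- scan_contexts(genome)
  cen <- context_census(sites)
  cval <- function(cx, col) cen[cen$context == cx, col]
  a1 <- parse_crispr_array(genome, ref$arrays$array1$region,
                           ref$arrays$array1$repeat_seq)
  a2 <- parse_crispr_array(genome, ref$arrays$array2$region,
                           ref$arrays$array2$repeat_seq)
  genes <- read_annotation(gff_path, keep_types = "CDS")
  sct <- strand_gene_counts(genes, length(genome))
  totals <- sct[is.na(sct$bin), ]
  rows <- rbind(
    data.frame(quantity = "genome_length", expected = ref$genome_length,
               observed = length(genome)),
    data.frame(quantity = "dam_duplex_loci",
               expected = ref$methylation$n_motifs[3],
               observed = cval("Dam", "n_duplex_loci")),
    data.frame(quantity = "dcm_duplex_loci",
               expected = ref$methylation$n_motifs[2],
               observed = cval("Dcm", "n_duplex_loci")),
    data.frame(quantity = "chh_fwd_sites",
               expected = ref$methylation$n_motifs[4],
               observed = cval("CHH_fwd", "n_sites")),
    data.frame(quantity = "chh_rev_sites",
               expected = ref$methylation$n_motifs[5],
               observed = cval("CHH_rev", "n_sites")),
    data.frame(quantity = "array1_spacers",
               expected = ref$arrays$array1$n_spacers,
               observed = a1$n_spacers),
    data.frame(quantity = "array2_spacers",
               expected = ref$arrays$array2$n_spacers,
               observed = a2$n_spacers),
    data.frame(quantity = "cds_total", expected = ref$cds_total,
               observed = totals$sum)
  )
  for (i in 1:4) {
    rows <- rbind(rows,
      data.frame(quantity = sprintf("forward_genes_mb%d", i),
                 expected = ref$strand_counts$forward[i],
                 observed = sct$forward[i]),
      data.frame(quantity = sprintf("reverse_genes_mb%d", i),
                 expected = ref$strand_counts$reverse[i],
                 observed = sct$reverse[i]))
  }
  rownames(rows) <- NULL
  rows
}
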