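#' Construct a genome sequence object
#'
#' A named DNA sequence over \code{A,C,G,T,N} with a circularity flag. All
#' scanning functions in the package take this object; coordinates are
#' 1-based inclusive throughout, matching how bacterial genome positions are
#' printed in annotation reports.
#'
#' @param name Sequence identifier.
#' @param sequence DNA string; lower case is accepted and upper-cased.
#' @param circular Logical; circular chromosomes let motifs and windows span
#'   the origin.
#' @return An object of class \code{genome_sequence} with fields
#'   \code{name}, \code{sequence}, \code{circular}.
#' @export
genome_sequence <- function(name, sequence, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("empty sequence for record '", name, "'", call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("illegal character '", substr(sequence, bad, bad),
         "' at position ", bad, " in record '", name, "'", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "genome_sequence")
}

#' @export
length.genome_sequence <- function(x) nchar(x$sequence)

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %s bp, %s\n", x$name,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (one record per chromosome).
#' @param circular Logical flag applied to every record.
#' @return A list of \code{\link{genome_sequence}} objects, named by record.
#' @export
read_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  out <- lapply(seq_along(set), function(i) {
    nm <- sub("\\s.*$", "", names(set)[i])
    genome_sequence(nm, as.character(set[[i]]), circular = circular)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write a genome to FASTA
#'
#' @param genome A \code{genome_sequence} or list of them.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  if (inherits(genome, "genome_sequence")) genome <- list(genome)
  set <- Biostrings::DNAStringSet(vapply(genome, `[[`, character(1), "sequence"))
  names(set) <- vapply(genome, `[[`, character(1), "name")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Coordinates are kept 1-based inclusive as in the GFF3 standard. Features
#' without a strand are dropped with a warning: every downstream use (strand
#' counts, metaplots) needs an orientation.
#'
#' @param path GFF3 file.
#' @param keep_types Feature types to retain (e.g. \code{"CDS"}).
#' @return A data.frame with columns \code{contig, start, end, strand,
#'   feature_id, feature_type}.
#' @export
read_annotation <- function(path, keep_types = "CDS") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import.gff3(path)
  gr <- gr[as.character(gr$type) %in% keep_types]
  str <- as.character(BiocGenerics::strand(gr))
  n_drop <- sum(str == "*")
  if (n_drop > 0L) {
    warning(n_drop, " feature(s) without strand dropped", call. = FALSE)
    gr <- gr[str != "*"]
    str <- str[str != "*"]
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  fallback <- gr$locus_tag
  if (!is.null(fallback)) ids[is.na(ids)] <- fallback[is.na(ids)]
  ids[is.na(ids)] <- sprintf("feature_%05d", which(is.na(ids)))
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = str,
    feature_id = ids,
    feature_type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  bad <- which(df$end < df$start)
  if (length(bad)) {
    stop("feature with end < start: ", df$feature_id[bad[1]], call. = FALSE)
  }
  df
}

#' Write gene features to GFF3
#'
#' @param genes Data.frame as returned by \code{\link{read_annotation}}.
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(genes, path, source = "bactometh") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- genes$feature_type
  gr$phase <- ifelse(genes$feature_type == "CDS", 0L, NA_integer_)
  gr$ID <- genes$feature_id
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a per-site methylation table
#'
#' The table is a bedMethyl-like TSV dialect with a fixed header
#' \code{contig position strand base context coverage fraction}: one row per
#' called site, \code{position} the 1-based coordinate of the modified base,
#' \code{fraction} the proportion of reads carrying the modification.
#'
#' @param path TSV file with header.
#' @return Data.frame of validated methylation records.
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expected <- c("contig", "position", "strand", "base", "context",
                "coverage", "fraction")
  if (!identical(names(df), expected)) {
    stop("header must be: ", paste(expected, collapse = " "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)
  validate_methylation_records(df, line_offset = 1L)
  df
}

#' @noRd
validate_methylation_records <- function(df, line_offset = 0L) {
  fail <- function(i, msg) {
    stop(msg, " (line ", i + line_offset, ")", call. = FALSE)
  }
  bad <- which(!df$context %in% CONTEXTS)
  if (length(bad)) fail(bad[1], paste0("unknown context '", df$context[bad[1]], "'"))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) fail(bad[1], paste0("invalid strand '", df$strand[bad[1]], "'"))
  bad <- which(is.na(df$fraction) | df$fraction < 0 | df$fraction > 1)
  if (length(bad)) fail(bad[1], paste0("fraction out of [0,1]: ", df$fraction[bad[1]]))
  bad <- which(is.na(df$coverage) | df$coverage < 0)
  if (length(bad)) fail(bad[1], "negative or missing coverage")
  bad <- which(df$base == "A" & df$context != "Dam")
  if (length(bad)) fail(bad[1], "base A must carry context Dam")
  bad <- which(df$base == "C" & !df$context %in% c("CpG", "CHG", "CHH", "Dcm"))
  if (length(bad)) fail(bad[1], "base C must carry a cytosine context")
  bad <- which(!df$base %in% c("A", "C"))
  if (length(bad)) fail(bad[1], paste0("invalid base '", df$base[bad[1]], "'"))
  invisible(df)
}

#' Write a per-site methylation table
#'
#' Inverse of \code{\link{read_methylation_table}}; the round trip is exact.
#'
#' @param records Methylation record data.frame.
#' @param path Output file.
#' @export
write_methylation_table <- function(records, path) {
  cols <- c("contig", "position", "strand", "base", "context",
            "coverage", "fraction")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED or bedGraph
#'
#' Internal coordinates are 1-based inclusive; the output is converted to
#' the 0-based half-open convention of BED/bedGraph (start - 1, end).
#'
#' @param values Data.frame with \code{contig, start, end} and either
#'   \code{value} (bedGraph) or \code{label} (BED).
#' @param path Output file.
#' @param format \code{"bedGraph"} or \code{"BED"}.
#' @export
write_track <- function(values, path, format = c("bedGraph", "BED")) {
  format <- match.arg(format)
  if (nrow(values) > 1L && is.unsorted(values$start)) {
    stop("intervals must be sorted by start", call. = FALSE)
  }
  if (format == "bedGraph" && nrow(values) > 1L) {
    if (any(values$start[-1] <= values$end[-nrow(values)])) {
      stop("overlapping intervals not allowed in bedGraph", call. = FALSE)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = values$contig,
    ranges = IRanges::IRanges(values$start, values$end)
  )
  if (format == "bedGraph") {
    gr$score <- values$value
    rtracklayer::export.bedGraph(gr, path)
  } else {
    if (!is.null(values$label)) gr$name <- values$label
    rtracklayer::export.bed(gr, path)
  }
  invisible(path)
}

#' Read BED intervals into the internal 1-based inclusive convention
#'
#' @param path BED file.
#' @return Data.frame with \code{contig, start, end, strand, label}.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    label = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE
  )
}
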