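#' Filter methylation records by per-context coverage cutoffs
#'
#' Sites below the read-depth cutoff for their context are removed before
#' any statistic is computed. Defaults follow a 30X cutoff for the
#' symmetric, motif-driven contexts (CpG, Dcm, Dam) and keep every called
#' asymmetric site (CHG/CHH cutoff 1). The boundary is inclusive: coverage
#' equal to the cutoff is kept.
#'
#' @param records Methylation record data.frame.
#' @param min_cov Named vector of per-context cutoffs; entries override the
#'   defaults \code{c(CpG = 30, Dcm = 30, Dam = 30, CHG = 1, CHH = 1)}.
#' @return The filtered records.
#' @export
filter_by_coverage <- function(records, min_cov = NULL) {
  cutoffs <- c(CpG = 30, Dcm = 30, Dam = 30, CHG = 1, CHH = 1)
  if (!is.null(min_cov)) {
    if (any(min_cov < 0)) stop("negative coverage cutoff", call. = FALSE)
    bad <- setdiff(names(min_cov), CONTEXTS)
    if (length(bad)) stop("unknown context in cutoff map: ", bad[1], call. = FALSE)
    cutoffs[names(min_cov)] <- min_cov
  }
  keep <- records$coverage >= cutoffs[records$context]
  records[keep, , drop = FALSE]
}

#' Per-context methylation percentage
#'
#' The per-context methylation level is the sum of the individual per-site
#' modification fractions divided by the number of called sites of that
#' context, expressed as a percent: an unweighted mean of fractions, not a
#' read-weighted one. Quartiles of the per-site fractions (linear
#' interpolation) describe the distribution behind the mean.
#'
#' @param records Coverage-filtered methylation records.
#' @param context One of \code{CpG, CHG, CHH, Dam, Dcm}, or the
#'   strand-split \code{CHH_fwd} / \code{CHH_rev}.
#' @return One-row data.frame: \code{context, n_motifs, methylation_pct,
#'   mean_coverage, median_coverage, q1, median, q3}.
#' @export
context_methylation_pct <- function(records, context) {
  sub <- subset_context(records, context)
  if (nrow(sub) == 0L) {
    stop("no called motifs for context ", context, call. = FALSE)
  }
  qs <- stats::quantile(sub$fraction, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(
    context = context,
    n_motifs = nrow(sub),
    methylation_pct = 100 * mean(sub$fraction),
    mean_coverage = mean(sub$coverage),
    median_coverage = stats::median(sub$coverage),
    q1 = qs[1], median = qs[2], q3 = qs[3],
    stringsAsFactors = FALSE
  )
}

#' @noRd
subset_context <- function(records, context) {
  if (context == "CHH_fwd") {
    records[records$context == "CHH" & records$strand == "+", , drop = FALSE]
  } else if (context == "CHH_rev") {
    records[records$context == "CHH" & records$strand == "-", , drop = FALSE]
  } else {
    records[records$context == context, , drop = FALSE]
  }
}

#' Summary table over all contexts present
#'
#' Convenience wrapper producing one \code{\link{context_methylation_pct}}
#' row per context present in the records, with CHH reported split by
#' strand (the asymmetric context has no duplex partner).
#'
#' @param records Coverage-filtered methylation records.
#' @return Data.frame, one row per context.
#' @export
context_summary_table <- function(records) {
  ctxs <- intersect(CONTEXTS, unique(records$context))
  ctxs <- setdiff(ctxs, "CHH")
  if (any(records$context == "CHH")) ctxs <- c(ctxs, "CHH_fwd", "CHH_rev")
  out <- do.call(rbind, lapply(ctxs, function(cx) {
    sub <- subset_context(records, cx)
    if (nrow(sub) == 0L) return(NULL)
    context_methylation_pct(records, cx)
  }))
  rownames(out) <- NULL
  out
}

#' Binned genome-wide methylation profile
#'
#' Partitions the chromosome into non-overlapping bins (default 100 kb;
#' the last bin may be partial) and reports the unweighted mean modification
#' fraction (x100) of the called records in each bin, per context. CHH is
#' additionally split by strand so asymmetric depletion on one strand is
#' visible. Bins with no called record carry \code{NA}, which is distinct
#' from 0\% methylation.
#'
#' @param records Coverage-filtered methylation records.
#' @param genome_length Chromosome length in bp.
#' @param width Bin width in bp (default 100,000).
#' @return Data.frame with columns \code{bin, start, end, context,
#'   mean_pct, n_sites}.
#' @export
bin_genome <- function(records, genome_length, width = 100000L) {
  stopifnot(width >= 1)
  if (nrow(records) > 0L && any(records$position > genome_length)) {
    stop("record position beyond genome length", call. = FALSE)
  }
  n_bins <- ceiling(genome_length / width)
  bins <- data.frame(
    bin = seq_len(n_bins),
    start = (seq_len(n_bins) - 1) * width + 1,
    end = pmin(seq_len(n_bins) * width, genome_length)
  )
  ctxs <- intersect(CONTEXTS, unique(records$context))
  if (any(records$context == "CHH")) ctxs <- c(ctxs, "CHH_fwd", "CHH_rev")
  out <- do.call(rbind, lapply(ctxs, function(cx) {
    sub <- subset_context(records, cx)
    b <- (sub$position - 1) %/% width + 1
    mean_pct <- rep(NA_real_, n_bins)
    n_sites <- integer(n_bins)
    if (nrow(sub) > 0L) {
      agg <- tapply(sub$fraction, b, mean)
      idx <- as.integer(names(agg))
      mean_pct[idx] <- 100 * as.numeric(agg)
      cnt <- table(b)
      n_sites[as.integer(names(cnt))] <- as.integer(cnt)
    }
    cbind(bins, data.frame(context = cx, mean_pct = mean_pct,
                           n_sites = n_sites, stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
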