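#' Strand-resolved gene counts per genomic bin
#'
#' Counts forward- and reverse-strand genes per non-overlapping bin
#' (default 1 Mb; the last bin may be partial). A gene belongs to the bin
#' containing its start coordinate by default (\code{by = "midpoint"}
#' anchors on the midpoint instead). A totals row (bin \code{NA}) closes
#' the table.
#'
#' @param genes Gene data.frame (\code{start, end, strand}).
#' @param genome_length Chromosome length in bp.
#' @param width Bin width in bp (default 1,000,000).
#' @param by Bin-membership anchor: \code{"start"} or \code{"midpoint"}.
#' @return Data.frame \code{bin, start, end, forward, reverse, sum,
#'   difference}; \code{difference = |forward - reverse|}.
#' @export
strand_gene_counts <- function(genes, genome_length, width = 1000000L,
                               by = c("start", "midpoint")) {
  by <- match.arg(by)
  n_bins <- ceiling(genome_length / width)
  anchor <- if (by == "start") genes$start else
    floor((genes$start + genes$end) / 2)
  if (nrow(genes) > 0L &&
      (any(anchor < 1L) || any(anchor > genome_length))) {
    stop("gene outside [1, genome_length]", call. = FALSE)
  }
  b <- (anchor - 1) %/% width + 1
  fwd <- tabulate(b[genes$strand == "+"], nbins = n_bins)
  rev <- tabulate(b[genes$strand == "-"], nbins = n_bins)
  out <- data.frame(
    bin = seq_len(n_bins),
    start = (seq_len(n_bins) - 1) * width + 1,
    end = pmin(seq_len(n_bins) * width, genome_length),
    forward = fwd, reverse = rev, sum = fwd + rev,
    difference = abs(fwd - rev)
  )
  totals <- data.frame(bin = NA_integer_, start = NA_real_, end = NA_real_,
                       forward = sum(fwd), reverse = sum(rev),
                       sum = sum(fwd) + sum(rev),
                       difference = abs(sum(fwd) - sum(rev)))
  rbind(out, totals)
}

#' GC content and GC skew tracks
#'
#' Per-window GC content \code{(G+C)/(A+C+G+T)} and GC skew
#' \code{(G-C)/(G+C)} (0 where the window has no G or C; positive when G
#' leads). Windows tile the chromosome with the given step; on circular
#' genomes the final window wraps the origin to keep full width, on linear
#' genomes it is truncated.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param window Window width in bp (default 10,000).
#' @param step Step between window starts (default = window).
#' @return Data.frame \code{start, end, gc_content, gc_skew}; \code{end}
#'   is the wrapped coordinate when a window spans the origin.
#' @export
gc_tracks <- function(genome, window = 10000L, step = window) {
  stopifnot(window >= 1, step >= 1)
  s <- seq_chars(genome)
  len <- length(s)
  g_cum <- cumsum(s == "G")
  c_cum <- cumsum(s == "C")
  n_cum <- cumsum(s == "N")
  count_to <- function(cum, i) if (i < 1L) 0L else cum[min(i, len)]
  range_count <- function(cum, a, b) count_to(cum, b) - count_to(cum, a - 1L)
  starts <- seq(1L, len, by = step)
  res <- lapply(starts, function(a) {
    b <- a + window - 1L
    if (b <= len) {
      g <- range_count(g_cum, a, b)
      cc <- range_count(c_cum, a, b)
      nn <- range_count(n_cum, a, b)
      width <- b - a + 1L
    } else if (genome$circular) {
      rem <- b - len
      g <- range_count(g_cum, a, len) + count_to(g_cum, rem)
      cc <- range_count(c_cum, a, len) + count_to(c_cum, rem)
      nn <- range_count(n_cum, a, len) + count_to(n_cum, rem)
      width <- window
      b <- rem
    } else {
      b <- len
      g <- range_count(g_cum, a, b)
      cc <- range_count(c_cum, a, b)
      nn <- range_count(n_cum, a, b)
      width <- b - a + 1L
    }
    denom <- width - nn
    c(end = b,
      gc_content = if (denom > 0) (g + cc) / denom else NA_real_,
      gc_skew = if (g + cc > 0) (g - cc) / (g + cc) else 0)
  })
  m <- do.call(rbind, res)
  data.frame(start = starts, end = as.integer(m[, "end"]),
             gc_content = m[, "gc_content"], gc_skew = m[, "gc_skew"])
}

#' Correlation between strand-biased gene placement and strand-specific
#' CHH methylation
#'
#' Spearman rank correlation between per-bin gene counts on one strand and
#' the per-bin mean CHH methylation on the same strand, with a permutation
#' p-value. Both inputs must be binned at the same width. With few bins
#' (a handful of Mb-scale bins on one chromosome) the test is underpowered
#' and the report should be read qualitatively.
#'
#' @param strand_table \code{\link{strand_gene_counts}} output (the totals
#'   row is ignored).
#' @param meth_bins \code{\link{bin_genome}} output containing
#'   \code{CHH_fwd} and \code{CHH_rev} rows, binned at the strand table's
#'   width.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return Data.frame with one row per strand: \code{strand, n, rho,
#'   p_value}; \code{rho} is \code{NA} with a warning when there are fewer
#'   than 4 bins or no variation.
#' @export
strand_bias_methylation_correlation <- function(strand_table, meth_bins,
                                                n_perm = 1000L, seed = 1L) {
  st <- strand_table[!is.na(strand_table$bin), , drop = FALSE]
  one <- function(strand_label, counts, ctx) {
    mb <- meth_bins[meth_bins$context == ctx, , drop = FALSE]
    mb <- mb[order(mb$bin), , drop = FALSE]
    if (nrow(mb) != nrow(st)) {
      stop("strand table and methylation bins use different binnings",
           call. = FALSE)
    }
    y <- mb$mean_pct
    ok <- !is.na(y)
    x <- counts[ok]; y <- y[ok]
    n <- length(y)
    if (n < 4L || stats::sd(y) == 0 || stats::sd(x) == 0) {
      warning("correlation undefined for ", strand_label,
              " strand (too few bins or no variation)", call. = FALSE)
      return(data.frame(strand = strand_label, n = n, rho = NA_real_,
                        p_value = NA_real_))
    }
    rho <- stats::cor(x, y, method = "spearman")
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(check_seed(seed))
    rp <- replicate(n_perm, stats::cor(x, sample(y), method = "spearman"))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    p <- (1 + sum(abs(rp) >= abs(rho))) / (n_perm + 1)
    data.frame(strand = strand_label, n = n, rho = rho, p_value = p)
  }
  rbind(one("forward", st$forward, "CHH_fwd"),
        one("reverse", st$reverse, "CHH_rev"))
}
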