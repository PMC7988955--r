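#' Gene-anchored methylation metaplot matrix
#'
#' Builds the per-gene, position-normalized methylation matrix behind a
#' TSS/TTS metagene plot. Each gene body is rescaled to \code{body_bins}
#' equal-width windows; fixed-width upstream and downstream flanks add
#' \code{flank_bins} columns on each side, so every row has
#' \code{2 * flank_bins + body_bins} columns regardless of gene length.
#' Rows are oriented 5'->3' of their gene: reverse-strand genes are flipped
#' so column 1 is always the distal upstream flank and the TSS sits at the
#' boundary between columns \code{flank_bins} and \code{flank_bins + 1}.
#'
#' A window's value is the mean modification fraction of the called sites
#' of the requested context falling inside it, on either genome strand
#' unless a strand-specific context (\code{CHH_fwd}, \code{CHH_rev}) is
#' requested; windows with no site are \code{NA}. Flanks wrap the origin on
#' circular genomes. Genes shorter than \code{body_bins} bp are skipped
#' with a warning.
#'
#' @param records Coverage-filtered methylation records.
#' @param genes Gene data.frame (\code{start, end, strand, feature_id}).
#' @param context Context to profile.
#' @param flank Flank width in bp on each side (default 1000).
#' @param body_bins Number of gene-body windows (default 100: a 1-kb
#'   equivalent axis at 10 bp per window).
#' @param flank_bins Number of windows per flank (default 50).
#' @param genome_length Chromosome length (needed for origin wrapping).
#' @param circular Whether flanks may wrap the origin.
#' @return Numeric matrix, genes x columns, with attributes \code{flank},
#'   \code{flank_bins}, \code{body_bins}, \code{context}.
#' @export
gene_metaplot <- function(records, genes, context, flank = 1000L,
                          body_bins = 100L, flank_bins = 50L,
                          genome_length, circular = TRUE) {
  stopifnot(flank >= 0, body_bins >= 1, flank_bins >= 1)
  glen <- genes$end - genes$start + 1
  short <- glen < body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than body_bins skipped",
            call. = FALSE)
    genes <- genes[!short, , drop = FALSE]
    glen <- glen[!short]
  }
  n_col <- 2L * flank_bins + body_bins
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_col,
                dimnames = list(genes$feature_id, NULL))
  sub <- subset_context(records, context)

  if (nrow(sub) > 0L && nrow(genes) > 0L) {
    pos <- sub$position
    frac <- sub$fraction
    if (circular) {
      pos <- c(pos, pos - genome_length, pos + genome_length)
      frac <- rep(frac, 3L)
    }
    win <- IRanges::IRanges(genes$start - flank, genes$end + flank)
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), win)
    g <- S4Vectors::subjectHits(hits)
    q <- pos[S4Vectors::queryHits(hits)]
    f <- frac[S4Vectors::queryHits(hits)]
    if (length(g)) {
      gs <- genes$start[g]; ge <- genes$end[g]; gl <- glen[g]
      fwd <- genes$strand[g] == "+"
      col <- integer(length(g))
      up <- ifelse(fwd, q < gs, q > ge)
      dn <- ifelse(fwd, q > ge, q < gs)
      body <- !up & !dn
      # upstream flank: distance from the distal edge, 1..flank
      r_up <- ifelse(fwd, q - (gs - flank) + 1, (ge + flank) - q + 1)
      col[up] <- ceiling(r_up[up] / flank * flank_bins)
      # gene body: fractional position along the oriented gene
      r_bd <- ifelse(fwd, q - gs + 1, ge - q + 1)
      col[body] <- flank_bins + ceiling(r_bd[body] / gl[body] * body_bins)
      # downstream flank: distance past the TTS, 1..flank
      r_dn <- ifelse(fwd, q - ge, gs - q)
      col[dn] <- flank_bins + body_bins +
        ceiling(r_dn[dn] / flank * flank_bins)
      col <- pmin(pmax(col, 1L), n_col)
      agg <- tapply(f, list(gene = g, col = col), mean)
      gi <- as.integer(rownames(agg))
      ci <- as.integer(colnames(agg))
      mat[cbind(gi[row(agg)[!is.na(agg)]], ci[col(agg)[!is.na(agg)]])] <-
        agg[!is.na(agg)]
    }
  }
  structure(mat, flank = flank, flank_bins = flank_bins,
            body_bins = body_bins, context = context)
}

#' Aggregate a metaplot matrix into a per-column profile
#'
#' Column means ignoring missing cells, with the number of contributing
#' genes per column. Columns where no gene has a called site stay
#' \code{NA}.
#'
#' @param mat Matrix from \code{\link{gene_metaplot}}.
#' @return Data.frame with \code{column, mean_fraction, n}.
#' @export
aggregate_profile <- function(mat) {
  if (nrow(mat) == 0L) stop("empty metaplot matrix", call. = FALSE)
  n <- colSums(!is.na(mat))
  m <- colMeans(mat, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  data.frame(column = seq_len(ncol(mat)), mean_fraction = as.numeric(m),
             n = as.integer(n))
}

#' Cluster genes by promoter methylation
#'
#' K-means clustering of the promoter-window columns of a metaplot matrix,
#' used to isolate the subset of genes with elevated methylation just
#' upstream of the TSS. The promoter window spans TSS-200 bp to TSS+50 bp
#' by default (covering the -35 promoter element); missing cells are
#' imputed as 0 for the clustering step only. The enriched cluster is the
#' one maximizing mean promoter-window methylation.
#'
#' @param mat Matrix from \code{\link{gene_metaplot}}.
#' @param k Number of clusters (default 6).
#' @param promoter_window Window in bp relative to the TSS,
#'   \code{c(upstream, downstream)} (default \code{c(-200, 50)}).
#' @param seed Random seed for the k-means restarts.
#' @param nstart Number of random restarts (default 50).
#' @return List of class \code{promoter_clusters}: \code{k} (effective
#'   cluster count), \code{assignment} (named vector gene -> cluster),
#'   \code{enriched_cluster}, \code{members} (gene ids of the enriched
#'   cluster), \code{cluster_means}, \code{promoter_cols},
#'   \code{promoter_mean} (per-gene mean promoter methylation).
#' @export
cluster_promoters <- function(mat, k = 6L, promoter_window = c(-200, 50),
                              seed = 1L, nstart = 50L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  pc <- promoter_columns(mat, promoter_window)
  x <- mat[, pc, drop = FALSE]
  usable <- rowSums(!is.na(x)) > 0L
  if (!all(usable)) {
    warning(sum(!usable), " gene(s) with no promoter-window site dropped",
            call. = FALSE)
    x <- x[usable, , drop = FALSE]
  }
  if (nrow(x) < k) stop("fewer usable genes than clusters", call. = FALSE)
  prom_mean <- rowMeans(x, na.rm = TRUE)
  xi <- x
  xi[is.na(xi)] <- 0
  k_eff <- min(k, nrow(unique(xi)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(check_seed(seed))
  km <- stats::kmeans(xi, centers = k_eff, nstart = nstart, iter.max = 100L)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  assignment <- stats::setNames(km$cluster, rownames(xi))
  cluster_means <- tapply(prom_mean, km$cluster, mean)
  enriched <- as.integer(names(cluster_means)[which.max(cluster_means)])
  structure(list(
    k = k_eff,
    assignment = assignment,
    enriched_cluster = enriched,
    members = names(assignment)[assignment == enriched],
    cluster_means = cluster_means,
    promoter_cols = pc,
    promoter_mean = prom_mean
  ), class = "promoter_clusters")
}

# columns of the metaplot matrix covering [pw1, pw2] bp around the TSS;
# body columns are mapped on the nominal 1-kb-equivalent axis
#' @noRd
promoter_columns <- function(mat, promoter_window) {
  fb <- attr(mat, "flank_bins"); fl <- attr(mat, "flank")
  bb <- attr(mat, "body_bins")
  up_bp <- -promoter_window[1]
  dn_bp <- promoter_window[2]
  cols <- integer(0)
  if (up_bp > 0) {
    n_up <- min(fb, ceiling(up_bp / (fl / fb)))
    cols <- c(cols, (fb - n_up + 1L):fb)
  }
  if (dn_bp > 0) {
    n_dn <- min(bb, ceiling(dn_bp / (1000 / bb)))
    cols <- c(cols, fb + seq_len(n_dn))
  }
  cols
}

#' @export
print.promoter_clusters <- function(x, ...) {
  cat(sprintf("<promoter_clusters> k = %d, enriched cluster %d (%d genes, mean promoter methylation %.3f)\n",
              x$k, x$enriched_cluster, length(x$members),
              x$cluster_means[as.character(x$enriched_cluster)]))
  invisible(x)
}
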