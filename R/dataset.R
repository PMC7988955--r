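#' Simulate a complete desk-scale methylome study
#'
#' One call produces every input the analysis pipeline consumes — genome,
#' gene annotation, CRISPR arrays, prophage intervals and the per-site
#' methylation table — with the statistical structure the pipeline is
#' designed to detect. The \code{"dri13"} preset emulates a 3.8 Mb, 45\%
#' GC circular chromosome scaled by \code{scale} (default 0.1 for
#' desk-scale runs): a planted GATC density matching the published Dam
#' motif count, per-Mb gene strand bias matching the published strand
#' table, both published CRISPR repeat sequences, reverse-strand CHH
#' depletion in the reverse-gene-rich segment, and a small gene cluster
#' with boosted promoter CpG.
#'
#' @param seed Random seed; all generators derive from it.
#' @param scale Linear genome scale factor (default 0.1).
#' @param preset Currently only \code{"dri13"}.
#' @param outdir Optional directory: writes \code{genome.fa},
#'   \code{genes.gff3}, \code{meth.tsv}, \code{arrays.bed},
#'   \code{prophages.bed} and \code{truth.json} (needs jsonlite).
#' @return List: \code{genome}, \code{genes}, \code{records},
#'   \code{arrays} (list of \code{\link{plant_crispr}} truths),
#'   \code{prophages}, \code{model}, \code{cluster_genes},
#'   \code{depletion_region}.
#' @export
simulate_dataset <- function(seed = 1L, scale = 0.1, preset = "dri13",
                             outdir = NULL) {
  preset <- match.arg(preset, "dri13")
  seed <- check_seed(seed)
  ref <- dri13_reference()
  len <- round(ref$genome_length * scale)
  gen <- simulate_genome(len, gc = ref$gc, seed = seed,
                         plant = c(GATC = round(ref$methylation$n_motifs[3] *
                                                  scale)))
  genome <- gen$genome

  arrays <- list()
  a_ref <- ref$arrays
  locs <- round(c(a_ref$array1$region[1], a_ref$array2$region[1]) * scale)
  reps <- c(a_ref$array1$n_repeats, a_ref$array2$n_repeats)
  seqs <- c(a_ref$array1$repeat_seq, a_ref$array2$repeat_seq)
  for (i in 1:2) {
    pl <- plant_crispr(genome, seqs[i], n_repeats = reps[i],
                       spacer_len = 37L, location = locs[i],
                       seed = seed + i,
                       avoid = if (i == 2)
                         data.frame(start = arrays[[1]]$region[1],
                                    end = arrays[[1]]$region[2]))
    genome <- pl$genome
    arrays[[i]] <- pl
  }

  bias <- ref$strand_counts$forward /
    (ref$strand_counts$forward + ref$strand_counts$reverse)
  genes <- simulate_annotation(genome, n_genes = round(ref$cds_total * scale),
                               strand_bias_by_bin = bias,
                               bin_width = round(1e6 * scale), seed = seed + 3L)

  prophages <- data.frame(
    start = round(ref$prophages$start * scale),
    end = round(ref$prophages$start * scale) +
      round(ref$prophages$length * scale) - 1L,
    label = sprintf("prophage_%d", 1:4), stringsAsFactors = FALSE
  )

  n_cluster <- max(2L, round(45 * scale))
  set.seed(seed + 4L)
  cluster_genes <- sample(genes$feature_id, n_cluster)
  depletion_region <- round(c(1e6, 2e6) * scale)
  model <- methylome_model(depletion_region = depletion_region,
                           cluster_genes = cluster_genes)
  sim <- simulate_methylome(genome, model, genes = genes, arrays = arrays,
                            seed = seed + 5L)

  out <- list(genome = genome, genes = genes, records = sim$records,
              sites = sim$sites, arrays = arrays, prophages = prophages,
              model = model, cluster_genes = cluster_genes,
              depletion_region = depletion_region)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(outdir, "genome.fa"))
    write_gff3(genes, file.path(outdir, "genes.gff3"))
    write_methylation_table(sim$records, file.path(outdir, "meth.tsv"))
    array_bed <- do.call(rbind, lapply(seq_along(arrays), function(i) {
      data.frame(contig = genome$name, start = arrays[[i]]$region[1],
                 end = arrays[[i]]$region[2],
                 label = sprintf("array_%d", i))
    }))
    write_track(array_bed, file.path(outdir, "arrays.bed"), format = "BED")
    write_track(cbind(contig = genome$name,
                      prophages[, c("start", "end", "label")]),
                file.path(outdir, "prophages.bed"), format = "BED")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      truth <- list(seed = seed, scale = scale,
                    genome_length = length(genome),
                    cluster_genes = cluster_genes,
                    depletion_region = depletion_region,
                    arrays = lapply(arrays, function(a)
                      list(region = a$region, repeats = a$repeats,
                           spacers = a$spacers)),
                    model = unclass(model))
      jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
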