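#' Methylome simulation model
#'
#' Parameters of the per-site generative model used by
#' \code{\link{simulate_methylome}}: each context site receives coverage
#' \code{~ Poisson(lambda)} and a modification fraction
#' \code{~ Beta(mean = mu, concentration = kappa)}, with optional
#' structured effects (reverse-strand CHH depletion in one segment, a
#' promoter CpG boost for a planted gene cluster, spacer/repeat CHH means
#' inside CRISPR arrays). Defaults emulate a genome with high Dam (GATC)
#' methylation, low symmetric 5mC and intermediate asymmetric CHH.
#'
#' @param mu Named per-context mean fractions; \code{CHH_fwd}/\code{CHH_rev}
#'   set the two strands of the asymmetric context separately.
#' @param kappa Beta concentration (site-to-site dispersion; \code{Inf}
#'   makes every fraction exactly its mean).
#' @param lambda Named per-context Poisson coverage means (reads).
#' @param depletion_region Optional \code{c(start, end)} where
#'   reverse-strand CHH means are multiplied by
#'   \code{depletion_multiplier}.
#' @param depletion_multiplier Multiplier for reverse CHH means inside the
#'   depletion region (default 0.2).
#' @param cluster_genes Optional character vector of gene ids receiving a
#'   promoter CpG boost.
#' @param promoter_boost Additive boost to CpG means inside the promoter
#'   window of cluster genes (default 0.3; means are clipped at 1).
#' @param promoter_window Promoter window in bp relative to the TSS
#'   (default \code{c(-200, 50)}).
#' @param spacer_chh_mean,repeat_chh_mean CHH means inside CRISPR spacers
#'   and repeats (defaults 0.4 and 0.02).
#' @return List of class \code{methylome_model}.
#' @export
methylome_model <- function(mu = c(Dam = 0.764, CpG = 0.0428, Dcm = 0.0381,
                                   CHH_fwd = 0.1741, CHH_rev = 0.1739,
                                   CHG = 0.04),
                            kappa = 5,
                            lambda = c(Dam = 42, CpG = 121, Dcm = 94,
                                       CHH = 54, CHG = 54),
                            depletion_region = NULL,
                            depletion_multiplier = 0.2,
                            cluster_genes = NULL,
                            promoter_boost = 0.3,
                            promoter_window = c(-200, 50),
                            spacer_chh_mean = 0.4,
                            repeat_chh_mean = 0.02) {
  stopifnot(all(mu >= 0 & mu <= 1), kappa > 0, all(lambda > 0),
            spacer_chh_mean >= 0, spacer_chh_mean <= 1,
            repeat_chh_mean >= 0, repeat_chh_mean <= 1)
  structure(list(mu = mu, kappa = kappa, lambda = lambda,
                 depletion_region = depletion_region,
                 depletion_multiplier = depletion_multiplier,
                 cluster_genes = cluster_genes,
                 promoter_boost = promoter_boost,
                 promoter_window = promoter_window,
                 spacer_chh_mean = spacer_chh_mean,
                 repeat_chh_mean = repeat_chh_mean),
            class = "methylome_model")
}

#' Simulate a genome with planted motif densities
#'
#' Draws i.i.d. bases at the target GC composition, then adjusts the count
#' of each listed motif by substitution (adding occurrences at random loci
#' or resampling existing ones) until the target count is met within 2\%
#' (at least plus/minus 1). Substitution, not insertion, keeps the genome
#' length and all coordinates stable. Targets refer to forward-strand
#' occurrence counts; for a palindromic motif such as GATC that equals the
#' number of duplex loci.
#'
#' @param length Genome length in bp (>= 10 kb recommended).
#' @param gc GC content in (0, 1).
#' @param seed Random seed (full determinism).
#' @param plant Optional named integer vector, motif -> target count.
#' @param circular Circularity flag of the emitted genome.
#' @param name Sequence name.
#' @return List: \code{genome} (a \code{\link{genome_sequence}}) and
#'   \code{truth} (final motif loci per planted motif).
#' @export
simulate_genome <- function(length, gc = 0.45, seed = 1L, plant = NULL,
                            circular = TRUE, name = "sim_chr") {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  set.seed(check_seed(seed))
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(prob), length, replace = TRUE, prob = prob)
  truth <- list()
  for (motif in names(plant)) {
    target <- plant[[motif]]
    k <- nchar(motif)
    m <- strsplit(motif, "", fixed = TRUE)[[1]]
    tol <- max(1L, round(0.02 * target))
    done <- FALSE
    for (iter in 1:200) {
      occ <- find_motif(s, motif, circular)
      d <- length(occ) - target
      if (abs(d) <= tol) { done <- TRUE; break }
      if (d < 0L) {
        loci <- sample.int(length, -d)
        for (p in loci) s[wrap_pos(p + 0:(k - 1L), length)] <- m
      } else {
        drop <- sample(occ, d)
        for (p in drop) {
          s[wrap_pos(p + 0:(k - 1L), length)] <-
            sample(names(prob), k, replace = TRUE, prob = prob)
        }
      }
    }
    if (!done) stop("could not reach target count for motif ", motif,
                    " (infeasible density?)", call. = FALSE)
    truth[[motif]] <- find_motif(s, motif, circular)
  }
  genome <- genome_sequence(name, paste(s, collapse = ""),
                            circular = circular)
  list(genome = genome, truth = truth)
}

#' Simulate a gene annotation with per-bin strand bias
#'
#' Places non-overlapping genes along the chromosome (lognormal length
#' model, uniform-multinomial intergenic gaps) and assigns each gene a
#' strand with a per-bin forward probability, so Mb-scale strand bias can
#' be planted.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param n_genes Number of genes.
#' @param strand_bias_by_bin Forward-strand probability: a scalar or a
#'   vector with one entry per bin of \code{bin_width}.
#' @param bin_width Width of the strand-bias bins (default 1 Mb).
#' @param mean_len,min_len Gene length model (lognormal with the given
#'   mean, lengths clamped below at \code{min_len}).
#' @param seed Random seed.
#' @return Data.frame of genes (\code{contig, start, end, strand,
#'   feature_id, feature_type}).
#' @export
simulate_annotation <- function(genome, n_genes, strand_bias_by_bin = 0.5,
                                bin_width = 1000000L, mean_len = 800L,
                                min_len = 150L, seed = 1L) {
  len <- length(genome)
  set.seed(check_seed(seed))
  lens <- NULL
  for (try in 1:20) {
    cand <- round(stats::rlnorm(n_genes, log(mean_len), 0.35))
    cand <- pmax(cand, min_len)
    if (sum(cand) <= 0.9 * len) { lens <- cand; break }
  }
  if (is.null(lens)) {
    stop("gene density infeasible: ", n_genes, " genes do not fit in ",
         len, " bp", call. = FALSE)
  }
  free <- len - sum(lens)
  gaps <- as.integer(stats::rmultinom(1, free, rep(1, n_genes + 1L)))
  starts <- cumsum(gaps[seq_len(n_genes)]) +
    cumsum(c(0L, lens[-n_genes])) + 1L
  ends <- starts + lens - 1L
  bias <- strand_bias_by_bin
  n_bins <- ceiling(len / bin_width)
  if (length(bias) == 1L) bias <- rep(bias, n_bins)
  b <- pmin((starts - 1) %/% bin_width + 1, length(bias))
  strand <- ifelse(stats::runif(n_genes) < bias[b], "+", "-")
  data.frame(
    contig = genome$name,
    start = starts, end = ends, strand = strand,
    feature_id = sprintf("gene_%05d", seq_len(n_genes)),
    feature_type = "CDS", stringsAsFactors = FALSE
  )
}

#' Plant a CRISPR array into a simulated genome
#'
#' Writes an alternating repeat/spacer block (beginning and ending with a
#' repeat; spacers random and mutually distinct) at the given location by
#' substitution, and returns the edited genome with the truth intervals.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param repeat_seq Repeat sequence.
#' @param n_repeats Number of repeats (spacers = repeats - 1).
#' @param spacer_len Spacer length in bp (default 37).
#' @param location 1-based start of the array block.
#' @param seed Random seed for the spacer sequences.
#' @param avoid Optional data.frame of intervals the block must not touch.
#' @return List of class \code{crispr_truth}: \code{genome} (edited),
#'   \code{region}, \code{repeats}, \code{spacers} (interval data.frames),
#'   \code{repeat_seq}.
#' @export
plant_crispr <- function(genome, repeat_seq, n_repeats, spacer_len = 37L,
                         location, seed = 1L, avoid = NULL) {
  stopifnot(n_repeats >= 2L, spacer_len >= 1L)
  repeat_seq <- toupper(repeat_seq)
  rl <- nchar(repeat_seq)
  len <- length(genome)
  block_len <- n_repeats * rl + (n_repeats - 1L) * spacer_len
  region <- c(location, location + block_len - 1L)
  if (region[1] < 1L || region[2] > len) {
    stop("array block does not fit at location ", location, call. = FALSE)
  }
  if (!is.null(avoid) && nrow(avoid)) {
    if (any(region[1] <= avoid$end & region[2] >= avoid$start)) {
      stop("array block overlaps an existing planted feature", call. = FALSE)
    }
  }
  set.seed(check_seed(seed))
  spacers <- character(n_repeats - 1L)
  repeat {
    spacers <- vapply(seq_len(n_repeats - 1L), function(i) {
      paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE),
            collapse = "")
    }, character(1))
    if (!anyDuplicated(spacers)) break
  }
  parts <- character(2L * n_repeats - 1L)
  parts[seq(1L, by = 2L, length.out = n_repeats)] <- repeat_seq
  parts[seq(2L, by = 2L, length.out = n_repeats - 1L)] <- spacers
  block <- paste(parts, collapse = "")
  seq <- genome$sequence
  substr(seq, region[1], region[2]) <- block
  rep_starts <- region[1] + (seq_len(n_repeats) - 1L) * (rl + spacer_len)
  sp_starts <- rep_starts[-n_repeats] + rl
  structure(list(
    genome = genome_sequence(genome$name, seq, circular = genome$circular),
    region = region,
    repeats = data.frame(start = rep_starts, end = rep_starts + rl - 1L),
    spacers = data.frame(start = sp_starts, end = sp_starts + spacer_len - 1L,
                         length = spacer_len),
    repeat_seq = repeat_seq
  ), class = "crispr_truth")
}

# circular membership: [a, b] may run out of [1, len] in either direction
#' @noRd
in_interval_circ <- function(pos, a, b, len) {
  a2 <- wrap_pos(a, len)
  b2 <- wrap_pos(b, len)
  if (a2 <= b2) pos >= a2 & pos <= b2 else pos >= a2 | pos <= b2
}

#' Simulate a per-site methylome over scanned context sites
#'
#' Every context site of the genome receives coverage
#' \code{~ Poisson(lambda)} and a fraction \code{~ Beta(mu', kappa)},
#' where \code{mu'} is the context mean modified by the model's structured
#' effects: the reverse-strand CHH depletion segment, the promoter CpG
#' boost for cluster genes, and spacer/repeat CHH means inside planted
#' CRISPR arrays.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param model A \code{\link{methylome_model}}.
#' @param genes Optional gene data.frame (needed for the promoter boost).
#' @param arrays Optional list of \code{\link{plant_crispr}} truths or
#'   \code{\link{parse_crispr_array}} results.
#' @param contexts Optional subset of contexts to simulate (default all
#'   present in the genome).
#' @param seed Random seed.
#' @param sites Optional precomputed \code{\link{scan_contexts}} output.
#' @return List: \code{records} (methylation record data.frame) and
#'   \code{sites}.
#' @export
simulate_methylome <- function(genome, model = methylome_model(),
                               genes = NULL, arrays = NULL, contexts = NULL,
                               seed = 1L, sites = NULL) {
  stopifnot(inherits(model, "methylome_model"))
  if (is.null(sites)) sites <- scan_contexts(genome)
  if (!is.null(contexts)) {
    base_ctx <- sub("_(fwd|rev)$", "", contexts)
    sites <- sites[sites$context %in% base_ctx, , drop = FALSE]
  }
  len <- length(genome)
  set.seed(check_seed(seed))
  key <- sites$context
  chh <- key == "CHH"
  key[chh & sites$strand == "+"] <- "CHH_fwd"
  key[chh & sites$strand == "-"] <- "CHH_rev"
  mu <- unname(model$mu[key])
  if (anyNA(mu)) stop("model$mu lacks a context present in the genome",
                      call. = FALSE)

  if (!is.null(model$depletion_region)) {
    dep <- chh & sites$strand == "-" &
      in_interval_circ(sites$position, model$depletion_region[1],
                       model$depletion_region[2], len)
    mu[dep] <- mu[dep] * model$depletion_multiplier
  }
  if (!is.null(model$cluster_genes) && !is.null(genes)) {
    cg <- genes[genes$feature_id %in% model$cluster_genes, , drop = FALSE]
    pw <- model$promoter_window
    boosted <- rep(FALSE, nrow(sites))
    is_cpg <- sites$context == "CpG"
    for (i in seq_len(nrow(cg))) {
      if (cg$strand[i] == "+") {
        a <- cg$start[i] + pw[1]; b <- cg$start[i] + pw[2]
      } else {
        a <- cg$end[i] - pw[2]; b <- cg$end[i] - pw[1]
      }
      boosted <- boosted |
        (is_cpg & in_interval_circ(sites$position, a, b, len))
    }
    mu[boosted] <- pmin(1, mu[boosted] + model$promoter_boost)
  }
  if (!is.null(arrays)) {
    for (ar in arrays) {
      for (j in seq_len(nrow(ar$spacers))) {
        hit <- chh & sites$position >= ar$spacers$start[j] &
          sites$position <= ar$spacers$end[j]
        mu[hit] <- model$spacer_chh_mean
      }
      for (j in seq_len(nrow(ar$repeats))) {
        hit <- chh & sites$position >= ar$repeats$start[j] &
          sites$position <= ar$repeats$end[j]
        mu[hit] <- model$repeat_chh_mean
      }
    }
  }
  lam_key <- sites$context
  coverage <- stats::rpois(nrow(sites), unname(model$lambda[lam_key]))
  frac <- draw_beta_fractions(mu, model$kappa)
  records <- data.frame(
    contig = sites$contig,
    position = sites$position,
    strand = sites$strand,
    base = ifelse(sites$context == "Dam", "A", "C"),
    context = sites$context,
    coverage = coverage,
    fraction = frac,
    stringsAsFactors = FALSE
  )
  list(records = records, sites = sites)
}

#' @noRd
draw_beta_fractions <- function(mu, kappa) {
  if (is.infinite(kappa)) return(mu)
  mu_c <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  stats::rbeta(length(mu_c), mu_c * kappa, (1 - mu_c) * kappa)
}

#' Simulate per-context records without a genome
#'
#' Draws \code{n_per_context} records for each context directly from the
#' Beta/Poisson model (positions are placeholders). Useful for
#' parameter-recovery studies of the per-context methylation statistic
#' where only the fraction and coverage distributions matter.
#'
#' @param model A \code{\link{methylome_model}}.
#' @param n_per_context Number of records per context.
#' @param contexts Contexts to draw (default the Beta-mean names of the
#'   model).
#' @param seed Random seed.
#' @return Methylation record data.frame.
#' @export
simulate_context_records <- function(model = methylome_model(),
                                     n_per_context = 5000L,
                                     contexts = c("CpG", "Dcm", "Dam",
                                                  "CHH_fwd", "CHH_rev"),
                                     seed = 1L) {
  set.seed(check_seed(seed))
  out <- lapply(contexts, function(cx) {
    base_ctx <- sub("_(fwd|rev)$", "", cx)
    strand <- if (cx == "CHH_rev") "-" else "+"
    data.frame(
      contig = "sim",
      position = seq_len(n_per_context),
      strand = strand,
      base = ifelse(base_ctx == "Dam", "A", "C"),
      context = base_ctx,
      coverage = stats::rpois(n_per_context,
                              unname(model$lambda[base_ctx])),
      fraction = draw_beta_fractions(rep(unname(model$mu[cx]),
                                         n_per_context), model$kappa),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Simulate a genome-wide de novo base-modification call table
#'
#' Emits one record per occurrence of \code{base} on either strand, with a
#' high modification mean at positions sitting at \code{mod_offset} inside
#' occurrences of \code{motif} (read 5'->3' on the site's strand) and a
#' low background mean elsewhere — the input shape of de novo methylated
#' motif discovery.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param base Modified base (\code{"A"} or \code{"C"}).
#' @param motif Planted recognition motif (e.g. \code{"GAACT"}).
#' @param mod_offset 1-based offset of the modified base inside the motif.
#' @param motif_mean,background_mean Beta means at motif and background
#'   positions.
#' @param kappa Beta concentration.
#' @param coverage_lambda Poisson coverage mean.
#' @param seed Random seed.
#' @return Data.frame \code{position, strand, base, coverage, fraction}.
#' @export
simulate_denovo_calls <- function(genome, base = "A", motif = "GAACT",
                                  mod_offset = 2L, motif_mean = 0.8,
                                  background_mean = 0.02, kappa = 5,
                                  coverage_lambda = 50, seed = 1L) {
  s <- seq_chars(genome)
  len <- length(s)
  circ <- genome$circular
  k <- nchar(motif)
  pos_f <- which(s == base)
  pos_r <- which(s == comp_chr(base))
  pos <- c(pos_f, pos_r)
  strand <- rep(c("+", "-"), c(length(pos_f), length(pos_r)))
  occ_f <- find_motif(s, motif, circ)
  occ_r <- find_motif(s, revcomp(motif), circ)
  hot_f <- wrap_pos(occ_f + mod_offset - 1L, len)
  hot_r <- wrap_pos(occ_r + (k - mod_offset), len)
  hot <- (strand == "+" & pos %in% hot_f) |
    (strand == "-" & pos %in% hot_r)
  set.seed(check_seed(seed))
  mu <- ifelse(hot, motif_mean, background_mean)
  data.frame(
    position = pos, strand = strand, base = base,
    coverage = stats::rpois(length(pos), coverage_lambda),
    fraction = draw_beta_fractions(mu, kappa),
    stringsAsFactors = FALSE
  )
}
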