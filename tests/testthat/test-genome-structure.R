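test_that("strand-resolved gene counts bin by start with a totals row", {
  genes <- data.frame(contig = "c",
                      start = c(10, 20, 30, 40, 50) * 1000,
                      end = c(11, 21, 31, 41, 51) * 1000,
                      strand = c("+", "+", "+", "-", "-"),
                      feature_id = paste0("g", 1:5), feature_type = "CDS")
  tab <- strand_gene_counts(genes, genome_length = 3805411)
  expect_equal(tab$forward[1], 3L)
  expect_equal(tab$reverse[1], 2L)
  expect_equal(tab$sum[1], 5L)
  expect_equal(tab$difference[1], 1L)
  expect_equal(nrow(tab), 5L)  # 4 bins (last partial 3-3.8 Mb) + totals
  totals <- tab[is.na(tab$bin), ]
  expect_equal(totals$forward + totals$reverse, totals$sum)
  expect_equal(totals$sum, 5L)

  empty <- strand_gene_counts(genes[0, ], genome_length = 2e6)
  expect_true(all(empty$sum == 0L))
})

test_that("totals equal column sums over random annotations", {
  set.seed(61)
  g <- simulate_annotation(genome_sequence("g", random_seq(100000)),
                           n_genes = 60, seed = 6)
  tab <- strand_gene_counts(g, 100000, width = 10000)
  bins <- tab[!is.na(tab$bin), ]
  totals <- tab[is.na(tab$bin), ]
  expect_equal(sum(bins$forward), totals$forward)
  expect_equal(sum(bins$reverse), totals$reverse)
  expect_equal(totals$sum, nrow(g))
})

test_that("GC content and skew follow their definitions per window", {
  t1 <- gc_tracks(genome_sequence("g", "GCAT", circular = FALSE), window = 4)
  expect_equal(t1$gc_content, 0.5)
  expect_equal(t1$gc_skew, 0)
  t2 <- gc_tracks(genome_sequence("g", "GGGG", circular = FALSE), window = 4)
  expect_equal(t2$gc_content, 1.0)
  expect_equal(t2$gc_skew, 1.0)
  t3 <- gc_tracks(genome_sequence("g", "CCCC", circular = FALSE), window = 4)
  expect_equal(t3$gc_skew, -1.0)
  t4 <- gc_tracks(genome_sequence("g", "AATT", circular = FALSE), window = 4)
  expect_equal(t4$gc_skew, 0)  # no G or C: defined as zero
})

test_that("windowed skew aggregates to the whole-genome skew when tiling", {
  set.seed(63)
  s <- random_seq(40000)
  g <- genome_sequence("g", s, circular = FALSE)
  tr <- gc_tracks(g, window = 8000)
  chars <- strsplit(s, "")[[1]]
  gk <- sum(chars == "G"); ck <- sum(chars == "C")
  # weight each window by its G+C count
  w <- (tr$gc_content) * 8000
  expect_equal(sum(tr$gc_skew * w) / sum(w), (gk - ck) / (gk + ck))
})

test_that("windows wrap the origin on circular genomes", {
  g <- genome_sequence("g", paste0(strrep("A", 6), "GGGG"), circular = TRUE)
  tr <- gc_tracks(g, window = 4, step = 4)
  # third window starts at 9, wraps through positions 9,10,1,2 -> GG,AA
  expect_equal(tr$gc_content[3], 0.5)
  expect_equal(tr$end[3], 2L)
})

test_that("planted reverse-strand CHH suppression gives negative correlation", {
  set.seed(65)
  n_bins <- 10
  counts <- data.frame(bin = 1:n_bins, start = NA, end = NA,
                       forward = c(52, 48, 51, 49, 50, 53, 47, 50, 52, 48),
                       reverse = c(90, 85, 80, 20, 15, 95, 25, 70, 10, 60))
  counts$sum <- counts$forward + counts$reverse
  counts$difference <- abs(counts$forward - counts$reverse)
  tab <- rbind(counts, data.frame(bin = NA, start = NA, end = NA,
                                  forward = sum(counts$forward),
                                  reverse = sum(counts$reverse),
                                  sum = sum(counts$sum),
                                  difference = NA))
  # methylation anti-proportional to reverse gene count, plus noise
  meth <- rbind(
    data.frame(bin = 1:n_bins, start = NA, end = NA, context = "CHH_rev",
               mean_pct = 20 - 0.15 * counts$reverse + rnorm(n_bins, 0, 0.3),
               n_sites = 100L),
    data.frame(bin = 1:n_bins, start = NA, end = NA, context = "CHH_fwd",
               mean_pct = rnorm(n_bins, 17, 0.5), n_sites = 100L))
  res <- strand_bias_methylation_correlation(tab, meth, seed = 3)
  rev_row <- res[res$strand == "reverse", ]
  expect_lt(rev_row$rho, 0)
  expect_lt(rev_row$p_value, 0.05)

  # jointly permuting bins leaves rho unchanged
  perm <- sample(n_bins)
  tab2 <- rbind(counts[perm, ], tab[is.na(tab$bin), ])
  tab2$bin <- c(1:n_bins, NA)
  meth2 <- meth
  meth2$mean_pct <- c(meth$mean_pct[1:n_bins][perm],
                      meth$mean_pct[n_bins + (1:n_bins)][perm])
  res2 <- strand_bias_methylation_correlation(tab2, meth2, seed = 3)
  expect_equal(res2$rho, res$rho)
})

test_that("degenerate correlations are reported as undefined", {
  counts <- data.frame(bin = 1:5, start = NA, end = NA, forward = 1:5,
                       reverse = 5:1, sum = 6, difference = NA)
  tab <- rbind(counts, data.frame(bin = NA, start = NA, end = NA, forward = 15,
                                  reverse = 15, sum = 30, difference = 0))
  meth <- rbind(
    data.frame(bin = 1:5, start = NA, end = NA, context = "CHH_rev",
               mean_pct = 5, n_sites = 10L),
    data.frame(bin = 1:5, start = NA, end = NA, context = "CHH_fwd",
               mean_pct = 5, n_sites = 10L))
  w <- testthat::capture_warnings(
    res <- strand_bias_methylation_correlation(tab, meth))
  expect_true(all(grepl("undefined", w)))
  expect_true(all(is.na(res$rho)))
})
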