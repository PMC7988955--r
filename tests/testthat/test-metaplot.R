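plus_gene <- data.frame(contig = "chr", start = 1001L, end = 2000L,
                        strand = "+", feature_id = "gA",
                        feature_type = "CDS", stringsAsFactors = FALSE)

test_that("sites land in the arithmetically expected body column", {
  rec <- make_records(1500, "CpG", 0.8)
  m <- gene_metaplot(rec, plus_gene, "CpG", genome_length = 10000,
                     circular = FALSE)
  expect_equal(dim(m), c(1L, 200L))
  # body column ceiling((500/1000)*100) = 50, offset by the upstream flank
  expect_equal(unname(m[1, 50 + 50]), 0.8)
  expect_equal(sum(!is.na(m)), 1L)

  minus <- plus_gene
  minus$strand <- "-"
  m2 <- gene_metaplot(rec, minus, "CpG", genome_length = 10000,
                      circular = FALSE)
  expect_equal(unname(m2[1, 50 + 51]), 0.8)  # mirrored by the orientation flip
  expect_equal(sum(!is.na(m2)), 1L)
})

test_that("flank columns and origin wrapping place sites correctly", {
  # 300 bp upstream of the TSS -> upstream window ceiling(701/1000*50) = 36
  rec <- make_records(701, "CpG", 0.4)
  m <- gene_metaplot(rec, plus_gene, "CpG", genome_length = 10000,
                     circular = FALSE)
  expect_equal(unname(m[1, 36]), 0.4)

  # gene at the start of a circular genome: upstream flank wraps the origin
  g0 <- plus_gene
  g0$start <- 1L; g0$end <- 1000L
  rec_wrap <- make_records(9901, "CpG", 0.6)  # 100 bp upstream across origin
  m3 <- gene_metaplot(rec_wrap, g0, "CpG", genome_length = 10000,
                      circular = TRUE)
  expect_equal(unname(m3[1, ceiling(901 / 1000 * 50)]), 0.6)
})

test_that("empty record sets keep matrix dimensions and short genes skip", {
  m <- gene_metaplot(make_records(integer(0), character(0), numeric(0)),
                     plus_gene, "CpG", genome_length = 10000)
  expect_equal(dim(m), c(1L, 200L))
  expect_true(all(is.na(m)))

  short <- plus_gene
  short$end <- short$start + 50L
  expect_warning(
    m2 <- gene_metaplot(make_records(1500, "CpG", 0.5), short, "CpG",
                        genome_length = 10000),
    "shorter than body_bins")
  expect_equal(nrow(m2), 0L)
})

test_that("aggregate profiles are column means over non-missing genes", {
  m <- matrix(NA_real_, 2, 4)
  m[1, 1] <- 0.2; m[2, 1] <- 0.4; m[1, 3] <- 0.9
  attr(m, "flank") <- 1000; attr(m, "flank_bins") <- 1
  attr(m, "body_bins") <- 2
  prof <- aggregate_profile(m)
  expect_equal(prof$mean_fraction[1], 0.3)
  expect_equal(prof$n[1], 2L)
  expect_true(is.na(prof$mean_fraction[2]))
  expect_equal(prof$mean_fraction[3], 0.9)

  single <- aggregate_profile(m[1, , drop = FALSE])
  expect_equal(single$mean_fraction, as.numeric(m[1, ]))
})

test_that("methylation depletion at gene boundaries shows minima at TSS/TTS", {
  set.seed(21)
  L <- 200000L
  genes <- simulate_annotation(genome_sequence("g", random_seq(L)),
                               n_genes = 120, mean_len = 900, seed = 3)
  # methylation high everywhere but suppressed within 80 bp of either gene end
  pos <- sample.int(L, 40000)
  frac <- rep(0.5, length(pos))
  for (i in seq_len(nrow(genes))) {
    near <- abs(pos - genes$start[i]) <= 80 | abs(pos - genes$end[i]) <= 80
    frac[near] <- 0.02
  }
  rec <- make_records(pos, "CpG", frac)
  m <- gene_metaplot(rec, genes, "CpG", genome_length = L)
  prof <- aggregate_profile(m)
  v <- prof$mean_fraction
  tss <- 50.5; tts <- 150.5
  expect_lt(abs(which.min(v[26:75]) + 25 - tss), 5)
  expect_lt(abs(which.min(v[126:175]) + 125 - tts), 5)
})

test_that("orientation flip of genome and annotation preserves the profile", {
  set.seed(33)
  L <- 50000L
  genome <- genome_sequence("g", random_seq(L), circular = TRUE)
  genes <- simulate_annotation(genome, n_genes = 30, seed = 5)
  sim <- simulate_methylome(genome, methylome_model(), seed = 9,
                            contexts = "CpG")
  rec <- sim$records
  m1 <- aggregate_profile(gene_metaplot(rec, genes, "CpG",
                                        genome_length = L))
  # reverse complement the world: positions mirror, strands flip
  rec2 <- rec
  rec2$position <- L - rec$position + 1L
  rec2$strand <- ifelse(rec$strand == "+", "-", "+")
  genes2 <- genes
  genes2$start <- L - genes$end + 1L
  genes2$end <- L - genes$start + 1L
  genes2$strand <- ifelse(genes$strand == "+", "-", "+")
  m2 <- aggregate_profile(gene_metaplot(rec2, genes2, "CpG",
                                        genome_length = L))
  expect_equal(m1, m2)
})

test_that("k-means promoter clustering recovers a planted enriched set", {
  set.seed(12)
  n <- 100L
  m <- matrix(abs(rnorm(n * 200, 0, 0.02)), n, 200,
              dimnames = list(sprintf("g%03d", 1:n), NULL))
  planted <- sprintf("g%03d", 1:20)
  m[1:20, 41:55] <- m[1:20, 41:55] + 0.5
  attr(m, "flank") <- 1000; attr(m, "flank_bins") <- 50
  attr(m, "body_bins") <- 100
  cl <- cluster_promoters(m, k = 2, seed = 4)
  expect_gte(length(intersect(cl$members, planted)), 19L)

  # permuting rows leaves the membership set unchanged
  perm <- sample(n)
  m_perm <- m[perm, ]
  attributes(m_perm)[c("flank", "flank_bins", "body_bins")] <-
    attributes(m)[c("flank", "flank_bins", "body_bins")]
  cl2 <- cluster_promoters(m_perm, k = 2, seed = 4)
  expect_setequal(cl2$members, cl$members)

  expect_error(cluster_promoters(m, k = 1), "at least 2")
  m_small <- m[1:3, ]
  attributes(m_small)[c("flank", "flank_bins", "body_bins")] <-
    attributes(m)[c("flank", "flank_bins", "body_bins")]
  expect_error(cluster_promoters(m_small, k = 6), "fewer usable genes")
})

test_that("identical promoter rows collapse to one effective cluster", {
  m <- matrix(0.25, 10, 200, dimnames = list(paste0("g", 1:10), NULL))
  attr(m, "flank") <- 1000; attr(m, "flank_bins") <- 50
  attr(m, "body_bins") <- 100
  cl <- cluster_promoters(m, k = 6, seed = 2)
  expect_equal(cl$k, 1L)
  expect_setequal(cl$members, rownames(m))
})
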