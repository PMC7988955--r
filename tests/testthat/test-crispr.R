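REPEAT1 <- "GTTGCAATGCCTAGCTCAGAGGTTTAAAGACTGAGAC"

build_array_genome <- function(n_repeats, spacer_len = 30L, pad = 400L,
                               seed = 1L, mutate = NULL) {
  set.seed(seed)
  flank <- random_seq(pad)
  planted <- plant_crispr(
    genome_sequence("g", random_seq(2L * pad + n_repeats * 37L +
                                      (n_repeats - 1L) * spacer_len + 200L),
                    circular = FALSE),
    REPEAT1, n_repeats = n_repeats, spacer_len = spacer_len,
    location = pad + 1L, seed = seed + 1L)
  if (!is.null(mutate)) {
    s <- planted$genome$sequence
    for (p in mutate) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    planted$genome <- genome_sequence("g", s, circular = FALSE)
  }
  planted
}

test_that("constructed arrays are recovered exactly", {
  tr <- build_array_genome(3)
  arr <- parse_crispr_array(tr$genome, tr$region + c(-50L, 50L), REPEAT1)
  expect_equal(arr$n_repeats, 3L)
  expect_equal(arr$n_spacers, 2L)
  expect_equal(arr$repeats$start, tr$repeats$start)
  expect_equal(arr$repeats$end, tr$repeats$end)
  expect_equal(arr$spacers$start, tr$spacers$start)
  expect_equal(arr$spacers$end, tr$spacers$end)
  expect_true(all(arr$repeats$mismatches == 0L))
})

test_that("mismatched repeats are still found within tolerance", {
  tr <- build_array_genome(3, seed = 5)
  # two point mutations inside the second repeat
  mid <- tr$repeats$start[2] + c(3L, 11L)
  tr2 <- build_array_genome(3, seed = 5, mutate = mid)
  arr <- parse_crispr_array(tr2$genome, tr2$region + c(-20L, 20L), REPEAT1,
                            max_mismatch = 3)
  expect_equal(arr$n_repeats, 3L)
  expect_equal(arr$repeats$mismatches[2], 2L)
})

test_that("spacer count is repeat count minus one over random arrays", {
  for (n in c(2L, 5L, 19L)) {
    tr <- build_array_genome(n, seed = n)
    arr <- parse_crispr_array(tr$genome, tr$region, REPEAT1)
    expect_equal(arr$n_spacers, arr$n_repeats - 1L)
    expect_equal(arr$n_repeats, n)
  }
  tr <- build_array_genome(3)
  expect_error(parse_crispr_array(tr$genome, c(1L, 100L), REPEAT1),
               "no repeat occurrence")
  expect_error(parse_crispr_array(tr$genome, c(1L, 10L * length(tr$genome)),
                                  REPEAT1), "outside genome")
})

test_that("reverse-orientation arrays are detected once per array", {
  tr <- build_array_genome(4, seed = 9)
  rc <- genome_sequence("g", oracle_revcomp(tr$genome$sequence),
                        circular = FALSE)
  L <- length(rc)
  region_rc <- c(L - tr$region[2] + 1L, L - tr$region[1] + 1L)
  arr <- parse_crispr_array(rc, region_rc, REPEAT1)
  expect_equal(arr$orientation, "-")
  expect_equal(arr$n_repeats, 4L)
})

test_that("spacer/repeat methylation contrast is detected by permutation", {
  tr <- build_array_genome(10, seed = 13)
  arr <- parse_crispr_array(tr$genome, tr$region, REPEAT1)
  sites <- scan_contexts(tr$genome)
  chh <- sites[sites$context == "CHH", ]
  in_any <- function(p, iv) {
    hit <- rep(FALSE, length(p))
    for (j in seq_len(nrow(iv))) hit <- hit | (p >= iv$start[j] & p <= iv$end[j])
    hit
  }
  frac <- ifelse(in_any(chh$position, arr$spacers), 1.0,
                 ifelse(in_any(chh$position, arr$repeats), 0.0, 0.1))
  rec <- make_records(chh$position, "CHH", frac, strand = chh$strand)
  prof <- array_methylation_profile(arr, rec, n_perm = 2000, seed = 2)
  expect_equal(prof$T_stat, 1.0)
  expect_lte(prof$p_value, 0.001)

  # label-shuffled fractions carry no signal
  set.seed(31)
  null_larger <- 0L
  for (s in 1:20) {
    rec_null <- rec
    rec_null$fraction <- sample(rec$fraction)
    p <- array_methylation_profile(arr, rec_null, n_perm = 500, seed = s)
    if (p$p_value > 0.05) null_larger <- null_larger + 1L
  }
  expect_gte(null_larger, 18L)

  # repeats without sites are excluded with a warning
  rec_sp <- rec[in_any(rec$position, arr$spacers), ]
  expect_warning(p2 <- array_methylation_profile(arr, rec_sp),
                 "without called sites")
  expect_true(is.finite(p2$T_stat) || is.na(p2$T_stat))
})

test_that("self-targeting spacers are found and annotated with prophages", {
  set.seed(17)
  tr <- build_array_genome(4, seed = 17)
  arr <- parse_crispr_array(tr$genome, tr$region, REPEAT1)
  # copy spacer 2 into a distant location inside a declared prophage
  s <- tr$genome$sequence
  sp <- substr(s, arr$spacers$start[2], arr$spacers$end[2])
  target <- length(tr$genome) - 120L
  substr(s, target, target + nchar(sp) - 1L) <- sp
  g2 <- genome_sequence("g", s, circular = FALSE)
  prophages <- data.frame(start = target - 50L, end = target + 100L)
  hits <- map_spacers(arr, g2, prophages, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$spacer_index, 2L)
  expect_equal(hits$start, target)
  expect_true(hits$in_prophage)

  # random spacers against a random genome: no spurious hits
  hits0 <- map_spacers(arr, genome_sequence("r", random_seq(100000),
                                            circular = TRUE),
                       max_mismatch = 0)
  expect_equal(nrow(hits0), 0L)
})

test_that("spacer mapping is rotation invariant on circular genomes", {
  tr <- build_array_genome(3, seed = 23)
  g <- genome_sequence("g", tr$genome$sequence, circular = TRUE)
  arr <- parse_crispr_array(g, tr$region, REPEAT1)
  # plant one spacer copy far from the array
  s <- g$sequence
  sp <- substr(s, arr$spacers$start[1], arr$spacers$end[1])
  substr(s, 30L, 30L + nchar(sp) - 1L) <- sp
  g <- genome_sequence("g", s, circular = TRUE)
  hits <- map_spacers(arr, g, max_mismatch = 0)
  L <- length(g)
  off <- 333L
  g_rot <- genome_sequence("g", rotate_seq(g$sequence, off), circular = TRUE)
  arr_rot <- arr
  arr_rot$region <- ((arr$region - off - 1L) %% L) + 1L
  arr_rot$spacers$start <- ((arr$spacers$start - off - 1L) %% L) + 1L
  arr_rot$spacers$end <- ((arr$spacers$end - off - 1L) %% L) + 1L
  hits_rot <- map_spacers(arr_rot, g_rot, max_mismatch = 0)
  expect_equal(nrow(hits_rot), nrow(hits))
  expect_equal(sort(((hits_rot$start + off - 1L) %% L) + 1L),
               sort(hits$start))
})
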