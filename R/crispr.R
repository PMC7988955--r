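#' Parse CRISPR array structure from a repeat consensus
#'
#' Greedy left-to-right scan of a declared genomic region for occurrences
#' of the repeat consensus within a Hamming mismatch tolerance. Orientation
#' (consensus vs its reverse complement) is chosen once per array by best
#' total score (more occurrences, then fewer total mismatches). Gaps
#' between consecutive repeats with length inside \code{spacer_range}
#' become spacers; larger gaps emit a warning (a run-on gap splits the
#' array biologically) and are not called as spacers.
#'
#' @param genome A \code{\link{genome_sequence}}.
#' @param region Two-element vector \code{c(start, end)}, 1-based inclusive.
#' @param repeat_consensus Repeat sequence (>= 20 bp).
#' @param max_mismatch Maximum Hamming mismatches per repeat (default 3).
#' @param spacer_range Allowed spacer lengths in bp (default \code{c(15, 60)}).
#' @return List of class \code{crispr_array}: \code{region},
#'   \code{consensus}, \code{orientation}, \code{repeats} (data.frame
#'   \code{start, end, mismatches}), \code{spacers} (data.frame
#'   \code{start, end, length}), \code{n_repeats}, \code{n_spacers}.
#' @export
parse_crispr_array <- function(genome, region, repeat_consensus,
                               max_mismatch = 3L, spacer_range = c(15L, 60L)) {
  stopifnot(inherits(genome, "genome_sequence"), length(region) == 2L)
  repeat_consensus <- toupper(repeat_consensus)
  if (nchar(repeat_consensus) < 20L) {
    stop("repeat consensus must be at least 20 bp", call. = FALSE)
  }
  len <- length(genome)
  if (region[1] < 1L || region[2] > len || region[1] > region[2]) {
    stop("region outside genome", call. = FALSE)
  }
  region_seq <- substr(genome$sequence, region[1], region[2])
  subj <- Biostrings::DNAString(region_seq)

  hits_for <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = max_mismatch)
    if (length(m) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        mismatches = integer(0)))
    }
    mm <- vapply(as.character(m), function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(pat, "")[[1]])
    }, integer(1), USE.NAMES = FALSE)
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
               mismatches = mm)
  }
  fwd <- hits_for(repeat_consensus)
  rev <- hits_for(revcomp(repeat_consensus))
  use_fwd <- nrow(fwd) > nrow(rev) ||
    (nrow(fwd) == nrow(rev) && sum(fwd$mismatches) <= sum(rev$mismatches))
  hits <- if (use_fwd) fwd else rev
  if (nrow(hits) == 0L) {
    stop("no repeat occurrence found in region", call. = FALSE)
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  reps <- hits[keep, , drop = FALSE]
  reps$start <- reps$start + region[1] - 1L
  reps$end <- reps$end + region[1] - 1L
  rownames(reps) <- NULL

  sp <- list()
  if (nrow(reps) > 1L) {
    for (i in seq_len(nrow(reps) - 1L)) {
      gs <- reps$end[i] + 1L
      ge <- reps$start[i + 1L] - 1L
      gl <- ge - gs + 1L
      if (gl >= spacer_range[1] && gl <= spacer_range[2]) {
        sp[[length(sp) + 1L]] <- data.frame(start = gs, end = ge, length = gl)
      } else if (gl > spacer_range[2]) {
        warning("gap of ", gl, " bp between repeats ", i, " and ", i + 1L,
                " exceeds the spacer range; array may be split", call. = FALSE)
      }
    }
  }
  spacers <- if (length(sp)) do.call(rbind, sp) else
    data.frame(start = integer(0), end = integer(0), length = integer(0))
  structure(list(
    contig = genome$name,
    region = region,
    consensus = repeat_consensus,
    orientation = if (use_fwd) "+" else "-",
    repeats = reps,
    spacers = spacers,
    n_repeats = nrow(reps),
    n_spacers = nrow(spacers)
  ), class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s:%d-%d, %d repeats / %d spacers (%s orientation)\n",
              x$contig, x$region[1], x$region[2], x$n_repeats, x$n_spacers,
              x$orientation))
  invisible(x)
}

#' Spacer-vs-repeat methylation periodicity
#'
#' Profiles the per-element methylation of a CRISPR array (each repeat and
#' each spacer, per strand and pooled) and tests whether spacers are more
#' methylated than repeats with the statistic
#' \code{T = mean(spacer element means) - mean(repeat element means)} and a
#' one-sided permutation p-value obtained by shuffling the element labels.
#'
#' @param array \code{\link{parse_crispr_array}} result (or any list with
#'   \code{repeats}/\code{spacers} interval data.frames).
#' @param records Coverage-filtered methylation records.
#' @param context Context to profile (default \code{"CHH"}, pooled over
#'   strands).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return List: \code{elements} (per-element table), \code{T_stat},
#'   \code{p_value}, \code{n_perm}.
#' @export
array_methylation_profile <- function(array, records, context = "CHH",
                                      n_perm = 1000L, seed = 1L) {
  if (nrow(array$spacers) == 0L) stop("array has zero spacers", call. = FALSE)
  sub <- subset_context(records, context)
  elem <- rbind(
    data.frame(type = "repeat", index = seq_len(nrow(array$repeats)),
               start = array$repeats$start, end = array$repeats$end),
    data.frame(type = "spacer", index = seq_len(nrow(array$spacers)),
               start = array$spacers$start, end = array$spacers$end)
  )
  stats_for <- function(st, en) {
    in_el <- sub$position >= st & sub$position <= en
    s <- sub[in_el, , drop = FALSE]
    c(mean_fraction = if (nrow(s)) mean(s$fraction) else NA_real_,
      mean_fwd = if (any(s$strand == "+")) mean(s$fraction[s$strand == "+"]) else NA_real_,
      mean_rev = if (any(s$strand == "-")) mean(s$fraction[s$strand == "-"]) else NA_real_,
      n_sites = nrow(s))
  }
  prof <- t(mapply(stats_for, elem$start, elem$end))
  elem <- cbind(elem, as.data.frame(prof))
  ok <- !is.na(elem$mean_fraction)
  if (any(!ok)) {
    warning(sum(!ok), " element(s) without called sites excluded from the ",
            "periodicity statistic", call. = FALSE)
  }
  vals <- elem$mean_fraction[ok]
  is_sp <- elem$type[ok] == "spacer"
  if (!any(is_sp) || !any(!is_sp)) {
    t_obs <- NA_real_
    p <- NA_real_
  } else {
    t_obs <- mean(vals[is_sp]) - mean(vals[!is_sp])
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(check_seed(seed))
    t_perm <- replicate(n_perm, {
      lab <- sample(is_sp)
      mean(vals[lab]) - mean(vals[!lab])
    })
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    p <- (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
  }
  list(elements = elem, T_stat = t_obs, p_value = p, n_perm = n_perm)
}

#' Map CRISPR spacers against the genome
#'
#' Aligns every spacer against both strands of the full (circular) genome
#' by Hamming-distance sliding window, wrapping the origin. Hits that
#' overlap the source array region are removed (every spacer trivially
#' matches itself); remaining hits are self-targeting candidates and are
#' annotated with whether they fall inside a prophage interval.
#'
#' @param array \code{\link{parse_crispr_array}} result.
#' @param genome The \code{\link{genome_sequence}} the array lives on.
#' @param prophages Optional data.frame of intervals (\code{start, end}).
#' @param max_mismatch Maximum mismatches per hit (default 2).
#' @return Data.frame \code{spacer_index, start, end, strand, mismatches,
#'   in_prophage}; zero rows when no spacer maps anywhere outside the
#'   array.
#' @export
map_spacers <- function(array, genome, prophages = NULL, max_mismatch = 2L) {
  if (nrow(array$spacers) == 0L) stop("empty spacer list", call. = FALSE)
  len <- length(genome)
  sp_seq <- substring(genome$sequence, array$spacers$start, array$spacers$end)
  k_max <- max(nchar(sp_seq))
  subj_seq <- if (genome$circular && len > k_max) {
    paste0(genome$sequence, substr(genome$sequence, 1, k_max - 1L))
  } else {
    genome$sequence
  }
  subj <- Biostrings::DNAString(subj_seq)
  out <- list()
  for (i in seq_along(sp_seq)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") sp_seq[i] else revcomp(sp_seq[i])
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = max_mismatch)
      if (length(m) == 0L) next
      st <- BiocGenerics::start(m)
      ok <- st <= len      # starts in the appended wrap are duplicates
      st <- st[ok]
      if (length(st) == 0L) next
      en <- st + nchar(pat) - 1L
      mm <- vapply(as.character(m)[ok], function(s) {
        sum(strsplit(s, "")[[1]] != strsplit(pat, "")[[1]])
      }, integer(1), USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        spacer_index = i, start = st, end = en, strand = str,
        mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(spacer_index = integer(0), start = integer(0),
               end = integer(0), strand = character(0),
               mismatches = integer(0))
  if (nrow(hits)) {
    # drop hits overlapping the source array (intervals may wrap)
    in_array <- overlaps_wrapped(hits$start, hits$end,
                                 array$region[1], array$region[2], len)
    hits <- hits[!in_array, , drop = FALSE]
  }
  hits$in_prophage <- logical(nrow(hits))
  if (nrow(hits) && !is.null(prophages) && nrow(prophages)) {
    for (j in seq_len(nrow(prophages))) {
      hits$in_prophage <- hits$in_prophage |
        overlaps_wrapped(hits$start, hits$end,
                         prophages$start[j], prophages$end[j], len)
    }
  }
  rownames(hits) <- NULL
  hits
}

# interval overlap where the query [s1,e1] may extend past the sequence end
#' @noRd
overlaps_wrapped <- function(s1, e1, s2, e2, len) {
  direct <- s1 <= e2 & e1 >= s2
  wrapped <- e1 > len & wrap_pos(e1, len) >= s2 & 1L <= e2
  direct | wrapped
}
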