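# Genome-wide prediction stage: GC-matched background sampling, 600 bp
# windows centered on genomic GBM, classifier scoring and calling,
# inter-classifier correlation, per-base weight profiles.

#' Sample GC-matched background regions
#'
#' For every positive region, rejection-samples \code{n_per_positive}
#' same-length genomic regions whose GC content is within \code{gc_tol} of
#' that positive, excluding any overlap with the positive intervals.
#' Deterministic given the seed.
#'
#' @param genome Named character vector of contigs.
#' @param positives Region tibble of positive intervals.
#' @param n_per_positive Background regions per positive (default 1).
#' @param gc_tol Maximum |GC difference| (default 0.02).
#' @param seed Integer seed.
#' @param max_attempts Rejection cap per background region.
#' @return List of class \code{background_set}: \code{regions} (tibble with
#'   \code{matched_to} index), \code{sequences}, \code{provenance}.
#' @export
sample_gc_matched_background <- function(genome, positives, n_per_positive = 1L,
                                         gc_tol = 0.02, seed = 1L,
                                         max_attempts = 10000L) {
  validate_regions(positives, genome)
  set.seed(seed)
  pos_gc <- gc_content(region_sequence(genome, positives))
  widths <- positives$end - positives$start
  contigs <- names(genome)
  clens <- nchar(genome)
  pos_gr <- regions_to_granges(positives)
  # one pending slot per (positive, replicate); whole batch is rejection
  # sampled in vectorized rounds
  slot_pos <- rep(seq_len(nrow(positives)), each = n_per_positive)
  slot_rep <- rep(seq_len(n_per_positive), times = nrow(positives))
  res_contig <- character(length(slot_pos))
  res_start <- integer(length(slot_pos))
  res_gc <- numeric(length(slot_pos))
  pending <- seq_along(slot_pos)
  if (any(max(widths) > max(clens))) stop("no contig long enough for positives")
  for (round in seq_len(max_attempts)) {
    if (length(pending) == 0L) break
    w <- widths[slot_pos[pending]]
    ctg <- contigs[sample.int(length(contigs), length(pending), replace = TRUE,
                              prob = pmax(clens - max(widths) + 1, 0))]
    st <- vapply(seq_along(pending), function(i) {
      sample.int(clens[[ctg[i]]] - w[i] + 1L, 1L) - 1L
    }, integer(1))
    cand <- tibble(contig = ctg, start = st, end = st + w)
    sq <- substring(genome[ctg], st + 1L, st + w)
    n_ok <- !grepl("^N+$", sq)
    gc <- rep(NA_real_, length(sq))
    gc[n_ok] <- gc_content(sq[n_ok])
    ok <- n_ok & abs(gc - pos_gc[slot_pos[pending]]) <= gc_tol &
      !IRanges::overlapsAny(regions_to_granges(cand), pos_gr,
                            ignore.strand = TRUE)
    acc <- pending[ok]
    res_contig[acc] <- ctg[ok]
    res_start[acc] <- st[ok]
    res_gc[acc] <- gc[ok]
    pending <- pending[!ok]
  }
  if (length(pending) > 0L) {
    i <- slot_pos[pending[1L]]
    stop("could not GC-match a background for positive region ", i,
         " (GC = ", round(pos_gc[i], 3), ") after ", max_attempts,
         " rounds")
  }
  regions <- tibble(contig = res_contig, start = res_start,
                    end = res_start + widths[slot_pos], strand = ".",
                    name = sprintf("bg_%d_%d", slot_pos, slot_rep),
                    matched_to = slot_pos, gc = res_gc)
  structure(list(regions = regions,
                 sequences = region_sequence(genome, regions),
                 provenance = list(seed = seed, gc_tol = gc_tol,
                                   n_per_positive = n_per_positive)),
            class = "background_set")
}

#' Fixed-width windows centered on GBM matches
#'
#' For a 12 bp match starting at \code{s}, the window midpoint is
#' \code{s + 6} and the window spans \code{[m - width/2, m + width/2)}.
#' Windows running over a contig edge are discarded (not clipped), keeping
#' every scored window the same length.
#'
#' @param matches Tibble from \code{\link{scan_genome_for_gbm}}.
#' @param genome Named character vector of contigs.
#' @param width Window width (default 600).
#' @return Region tibble with the source-match columns \code{gbm_start},
#'   \code{gbm_strand}, \code{name} (word), \code{tier}.
#' @export
extract_window <- function(matches, genome, width = 600L) {
  if (nrow(matches) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  strand = character(0), name = character(0),
                  tier = character(0), gbm_start = integer(0),
                  gbm_strand = character(0)))
  }
  half <- width %/% 2L
  m <- matches$start + 6L
  st <- m - half
  en <- m + (width - half)
  clen <- nchar(genome)[matches$contig]
  keep <- st >= 0L & en <= clen
  tibble(contig = matches$contig[keep], start = st[keep], end = en[keep],
         strand = ".", name = matches$name[keep], tier = matches$tier[keep],
         gbm_start = matches$start[keep], gbm_strand = matches$strand[keep])
}

#' Scan a genome and score every GBM window
#'
#' Finds all GBM matches, extracts the fixed-width window around each, and
#' scores each window with every supplied classifier, reporting raw score,
#' posterior probability and the sign-based positive/negative call.
#'
#' @param genome Named character vector of contigs.
#' @param library A \code{\link{motif_library}}.
#' @param models Named list of \code{kmer_model}s.
#' @param width Window width (default 600).
#' @return Tibble of scored windows, sorted by (contig, start), with columns
#'   \code{score_<m>}, \code{posterior_<m>}, \code{call_<m>} per model.
#' @export
scan_and_score <- function(genome, library, models, width = 600L) {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  matches <- scan_genome_for_gbm(genome, library)
  win <- extract_window(matches, genome, width = width)
  win <- sort_regions(win)
  if (nrow(win) == 0L) return(win)
  seqs <- region_sequence(genome, win)
  for (nm in names(models)) {
    model <- models[[nm]]
    s <- score_sequences(model, seqs)
    win[[paste0("score_", nm)]] <- s
    win[[paste0("posterior_", nm)]] <-
      if (!is.na(model$platt_a)) posterior_prob(model, s) else NA_real_
    win[[paste0("call_", nm)]] <- ifelse(s > 0, "positive", "negative")
  }
  win
}

#' Pearson correlation between two classifiers' window scores
#'
#' Correlates the raw scores two models assign to the same scored windows,
#' over all windows, only windows both models call positive (both scores
#' > 0), or only high-confidence windows (both scores >= 1, the operational
#' form of posterior probability 1).
#'
#' @param scored Output of \code{\link{scan_and_score}}.
#' @param model_a,model_b Model names (as used in \code{scan_and_score}).
#' @param subset One of \code{"all"}, \code{"positive_only"},
#'   \code{"high_confidence"}.
#' @return Pearson correlation coefficient.
#' @export
classifier_correlation <- function(scored, model_a, model_b,
                                   subset = c("all", "positive_only",
                                              "high_confidence")) {
  subset <- match.arg(subset)
  x <- scored[[paste0("score_", model_a)]]
  y <- scored[[paste0("score_", model_b)]]
  if (is.null(x) || is.null(y)) stop("model scores not found in scored windows")
  keep <- switch(subset,
                 all = rep(TRUE, length(x)),
                 positive_only = x > 0 & y > 0,
                 high_confidence = x >= 1 & y >= 1)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("fewer than 3 windows in subset '", subset, "'")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero score variance in subset '", subset, "'")
  }
  cor(x, y)
}

#' Per-position k-mer weight profile
#'
#' The weight of the canonical k-mer starting at each offset of a sequence
#' (0 for N-containing windows); the profile sums to score minus bias,
#' making per-base contributions to the classifier score directly
#' plottable.
#'
#' @param model A \code{kmer_model}.
#' @param seq A single sequence (length >= k).
#' @return Tibble \code{offset} (0-based start), \code{weight}; class
#'   \code{profile_track}.
#' @export
weight_profile <- function(model, seq) {
  if (nchar(seq) < model$k) stop("sequence shorter than k")
  index <- kmer_index(model$k)
  ids <- kmer_ids(seq_to_codes(seq), model$k)
  cols <- index$canon_col[ids + 1L]
  w <- ifelse(is.na(cols), 0, model$weights[cols])
  out <- tibble(offset = seq_along(ids) - 1L, weight = w)
  class(out) <- c("profile_track", class(out))
  out
}

#' Export a weight profile as bedGraph
#'
#' Offsets are lifted to genomic coordinates and runs of equal weight are
#' merged into single bedGraph intervals.
#'
#' @param profile A \code{\link{weight_profile}} tibble.
#' @param contig Contig name.
#' @param region_start Genomic start (0-based) of the profiled sequence.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
profile_to_bedgraph <- function(profile, contig, region_start, path) {
  r <- rle(profile$weight)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  write_bedgraph(tibble(contig = contig,
                        start = region_start + starts,
                        end = region_start + ends,
                        value = r$values), path)
}

#' Export scored windows as a BED6+ table
#'
#' Standard first six BED columns (name = GBM word, score = first model's
#' raw score, strand = GBM strand) followed by one score, posterior and call
#' column per model; tab-delimited with a header line.
#'
#' @param scored Output of \code{\link{scan_and_score}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
export_scored_windows <- function(scored, path) {
  extra <- setdiff(names(scored),
                   c("contig", "start", "end", "strand", "name", "tier",
                     "gbm_start", "gbm_strand"))
  first_score <- grep("^score_", extra, value = TRUE)[1]
  df <- data.frame(chrom = scored$contig, chromStart = scored$start,
                   chromEnd = scored$end, name = scored$name,
                   score = scored[[first_score]], strand = scored$gbm_strand,
                   tier = scored$tier, gbm_start = scored$gbm_start,
                   check.names = FALSE)
  for (cl in extra) df[[cl]] <- scored[[cl]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
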