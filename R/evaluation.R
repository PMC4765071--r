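# Downstream assessment: overlap enrichment Z-tests, multi-dataset Venn
# counts, GBM-per-peak spectra, motif positional profiles and nearest-gene
# annotation.

#' Two-proportion Z-test from overlap counts
#'
#' Pooled-variance two-proportion statistic comparing the fraction of
#' predicted-positive regions overlapping a feature track with the fraction
#' of predicted-negative regions doing so; the p-value is one-sided in the
#' direction positives > negatives.
#'
#' @param k_pos,n_pos Overlapping and total counts for the positive group.
#' @param k_neg,n_neg Overlapping and total counts for the negative group.
#' @return List of class \code{overlap_stats}: counts, proportions,
#'   \code{z}, one-sided \code{p_value}, and \code{degenerate} (TRUE when
#'   the pooled proportion is 0 or 1 and Z is undefined).
#' @export
overlap_ztest_counts <- function(k_pos, n_pos, k_neg, n_neg) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, k_pos >= 0L, k_neg >= 0L,
            k_pos <= n_pos, k_neg <= n_neg)
  p1 <- k_pos / n_pos
  p2 <- k_neg / n_neg
  pool <- (k_pos + k_neg) / (n_pos + n_neg)
  degenerate <- pool <= 0 || pool >= 1
  z <- if (degenerate) NA_real_ else {
    (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n_pos + 1 / n_neg))
  }
  structure(list(n_pos = n_pos, k_pos = k_pos, n_neg = n_neg, k_neg = k_neg,
                 p_pos = p1, p_neg = p2, z = z,
                 p_value = if (degenerate) NA_real_ else pnorm(z, lower.tail = FALSE),
                 degenerate = degenerate),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap: positives %d/%d (%.3f) vs negatives %d/%d (%.3f)\n",
              x$k_pos, x$n_pos, x$p_pos, x$k_neg, x$n_neg, x$p_neg))
  if (x$degenerate) cat("  pooled proportion degenerate; Z undefined\n")
  else cat(sprintf("  Z = %.4f, one-sided p = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' Overlap enrichment Z-test for predicted regions against a track
#'
#' Counts regions overlapping the track (>= 1 bp, strand-blind) in each
#' group and applies \code{\link{overlap_ztest_counts}}.
#'
#' @param pos_regions,neg_regions Region tibbles (predicted positive /
#'   negative).
#' @param track A \code{\link{feature_track}} or region tibble.
#' @return An \code{overlap_stats} object.
#' @export
overlap_ztest <- function(pos_regions, neg_regions, track) {
  overlap_ztest_counts(sum(overlaps_any(pos_regions, track)), nrow(pos_regions),
                       sum(overlaps_any(neg_regions, track)), nrow(neg_regions))
}

#' Overlap Z-test report for several tracks
#'
#' @param pos_regions,neg_regions Region tibbles.
#' @param tracks Named list of tracks.
#' @return Tibble, one row per track: counts, proportions, Z, p.
#' @export
overlap_ztest_report <- function(pos_regions, neg_regions, tracks) {
  rows <- lapply(names(tracks), function(nm) {
    st <- overlap_ztest(pos_regions, neg_regions, tracks[[nm]])
    tibble(track = nm, k_pos = st$k_pos, n_pos = st$n_pos,
           k_neg = st$k_neg, n_neg = st$n_neg,
           p_pos = st$p_pos, p_neg = st$p_neg, z = st$z, p_value = st$p_value)
  })
  do.call(rbind, rows)
}

#' Canonical Venn subset key
#'
#' @param members Character vector of dataset names.
#' @return Single string, sorted names joined by \code{"+"}.
#' @export
venn_key <- function(members) paste(sort(unique(members)), collapse = "+")

#' Venn overlap counts across peak datasets
#'
#' Merges all regions across datasets; each merged region is assigned the
#' subset of datasets contributing at least one overlapping base, and
#' subsets are counted. Counts are invariant to dataset input order.
#'
#' @param datasets Named list (2-4 entries) of region tibbles.
#' @return Tibble \code{subset} (\code{\link{venn_key}}), \code{n_datasets},
#'   \code{count}; attribute \code{total} holds the number of merged
#'   regions.
#' @export
venn_overlap <- function(datasets) {
  stopifnot(length(datasets) >= 2L, length(datasets) <= 4L,
            !is.null(names(datasets)))
  grs <- lapply(datasets, regions_to_granges)
  merged <- GenomicRanges::reduce(
    do.call(c, unname(lapply(grs, function(g) {
      BiocGenerics::strand(g) <- "*"
      g
    }))))
  member <- sapply(grs, function(g) IRanges::overlapsAny(merged, g,
                                                         ignore.strand = TRUE))
  if (length(merged) == 1L) member <- matrix(member, nrow = 1L,
                                             dimnames = list(NULL, names(datasets)))
  keys <- apply(member, 1, function(row) venn_key(names(datasets)[row]))
  tab <- table(keys)
  out <- tibble(subset = names(tab),
                n_datasets = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                count = as.integer(tab))
  out <- out[order(-out$n_datasets, out$subset), , drop = FALSE]
  attr(out, "total") <- length(merged)
  out
}

#' GBM-count spectrum of a peak set
#'
#' Counts distinct GBM match positions in every peak sequence and returns
#' the frequency of peaks with 1, 2, ... sites, normalized over peaks with
#' at least one site.
#'
#' @param peaks Character vector of peak sequences.
#' @param library A \code{\link{motif_library}}.
#' @return Tibble \code{n_gbm, count, frequency}; attribute
#'   \code{n_with_gbm} and \code{fraction_with_gbm}.
#' @export
gbm_count_spectrum <- function(peaks, library) {
  matches <- scan_sequences_for_gbm(peaks, library)
  per_peak <- integer(length(peaks))
  if (!is.null(matches) && nrow(matches) > 0L) {
    n_distinct <- tapply(matches$start, matches$seq_index,
                         function(s) length(unique(s)))
    per_peak[as.integer(names(n_distinct))] <- as.integer(n_distinct)
  }
  with_gbm <- per_peak[per_peak > 0L]
  if (length(with_gbm) == 0L) {
    out <- tibble(n_gbm = integer(0), count = integer(0), frequency = numeric(0))
  } else {
    tab <- table(with_gbm)
    out <- tibble(n_gbm = as.integer(names(tab)), count = as.integer(tab),
                  frequency = as.integer(tab) / length(with_gbm))
  }
  attr(out, "n_with_gbm") <- length(with_gbm)
  attr(out, "fraction_with_gbm") <- length(with_gbm) / length(peaks)
  out
}

#' Positional profile of motif matches within fixed-width peaks
#'
#' Offsets of every motif-match center from its peak midpoint, histogrammed
#' at the given bin width and density-normalized.
#'
#' @param peaks Character vector of equal-length peak sequences.
#' @param motif_words Words to match (either orientation).
#' @param bin_width Bin width in bp (default 20).
#' @return Tibble \code{bin_center, count, density}.
#' @export
motif_positional_profile <- function(peaks, motif_words, bin_width = 20L) {
  w <- unique(nchar(peaks))
  if (length(w) != 1L) stop("peaks must have a single fixed width")
  mid <- (w - 1) / 2
  offsets <- unlist(lapply(peaks, function(s) {
    unlist(lapply(motif_words, function(word) {
      for_hits <- gregexpr(word, s, fixed = TRUE)[[1]]
      rc <- revcomp(word)
      rc_hits <- if (rc != word) gregexpr(rc, s, fixed = TRUE)[[1]] else -1L
      hits <- c(for_hits[for_hits > 0], rc_hits[rc_hits > 0])
      if (length(hits) == 0L) return(numeric(0))
      (hits - 1) + (nchar(word) - 1) / 2 - mid
    }))
  }))
  if (length(offsets) == 0L) {
    return(tibble(bin_center = numeric(0), count = integer(0),
                  density = numeric(0)))
  }
  bin <- round(offsets / bin_width) * bin_width
  tab <- table(bin)
  tibble(bin_center = as.numeric(names(tab)), count = as.integer(tab),
         density = as.integer(tab) / (length(offsets) * bin_width))
}

#' Annotate regions to their two nearest genes
#'
#' A light-weight stand-in for regulatory-domain annotation: each region is
#' assigned the (up to) two genes with the smallest absolute TSS-to-midpoint
#' distance on its contig, ties broken by gene name.
#'
#' @param regions Region tibble.
#' @param gene_tss Tibble with columns \code{gene}, \code{contig},
#'   \code{tss} (0-based position).
#' @return Tibble \code{region_index, gene, distance, rank}; \code{distance}
#'   is signed (TSS minus region midpoint).
#' @export
annotate_two_nearest_genes <- function(regions, gene_tss) {
  stopifnot(all(c("gene", "contig", "tss") %in% names(gene_tss)))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    g <- gene_tss[gene_tss$contig == regions$contig[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      warning("no genes on contig ", regions$contig[i], " for region ", i)
      return(NULL)
    }
    midpoint <- (regions$start[i] + regions$end[i]) %/% 2L
    d <- g$tss - midpoint
    o <- order(abs(d), g$gene)
    take <- head(o, 2L)
    tibble(region_index = i, gene = g$gene[take], distance = d[take],
           rank = seq_along(take))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble(region_index = integer(0), gene = character(0),
                  distance = numeric(0), rank = integer(0))
  }
  out
}
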