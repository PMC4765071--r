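# GLI binding-motif (GBM) 12-mer library: enriched-word discovery, the
# iterative match-remove-rediscover construction, confidence tiers, PWM
# similarity scoring, genome matching and in silico GLI-site knockout.

GBM_WIDTH <- 12L
# 9-mer GLI core GACCACCCA sits at positions 2-10 of the 12-mer; its
# invariant 6th-position C is 12-mer position 7 (1-based), the base mutated
# to G by the knockout.
GKO_POS <- 7L

#' Is a 12-mer GLI-like?
#'
#' Structural filter standing in for motif-comparison tools: a word is
#' GLI-like when, in either orientation, positions 4, 5 and 7 are C (the
#' near-invariant CCxC run at positions 4-7 of genomic GLI sites, which
#' forces the required concordant C/C at positions 5 and 7).
#'
#' @param word Character vector of 12-mers.
#' @return Logical vector.
#' @export
is_gli_like <- function(word) {
  if (any(nchar(word) != GBM_WIDTH)) stop("GBM words must be exactly 12 bp")
  fwd <- function(w) {
    substr(w, 4, 4) == "C" & substr(w, 5, 5) == "C" & substr(w, 7, 7) == "C"
  }
  fwd(word) | fwd(revcomp(word))
}

# orientation of the GLI frame within a (possibly canonical) word:
# "+" if the word itself carries the CCxC frame, "-" if only its reverse
# complement does; error if neither.
gli_frame_strand <- function(word) {
  f <- function(w) substr(w, 4, 4) == "C" & substr(w, 5, 5) == "C" &
    substr(w, 7, 7) == "C"
  out <- ifelse(f(word), "+", ifelse(f(revcomp(word)), "-", NA))
  if (anyNA(out)) stop("word is not GLI-like in either orientation")
  out
}

#' Confidence tier from dataset presence
#'
#' A motif found in all datasets is high confidence (HC), in two or more
#' (but not all) medium (MC), in exactly one low (LC).
#'
#' @param presence Character vector of dataset names containing the motif.
#' @param n_datasets Total number of datasets (default 4).
#' @return One of \code{"HC"}, \code{"MC"}, \code{"LC"}.
#' @export
classify_confidence <- function(presence, n_datasets = 4L) {
  np <- length(unique(presence))
  if (np < 1L) stop("presence must name at least one dataset")
  if (np > n_datasets) stop("presence exceeds the number of datasets")
  if (np == n_datasets) "HC" else if (np >= 2L) "MC" else "LC"
}

#' Assemble a motif library
#'
#' Canonicalizes words (lexicographic minimum of word and reverse
#' complement), merges duplicate entries' dataset presence and assigns
#' confidence tiers.
#'
#' @param words Character vector of 12-mers.
#' @param presence List (parallel to \code{words}) of dataset-name vectors.
#' @param n_datasets Number of source datasets for tier assignment.
#' @return Tibble of class \code{motif_library} with columns \code{word}
#'   (canonical), \code{tier}, \code{datasets} (comma-joined).
#' @export
motif_library <- function(words, presence = NULL, n_datasets = 4L) {
  if (length(words) == 0L) {
    out <- tibble(word = character(0), tier = character(0),
                  datasets = character(0))
    class(out) <- c("motif_library", class(out))
    return(out)
  }
  if (any(nchar(words) != GBM_WIDTH)) stop("GBM words must be exactly 12 bp")
  canon <- canonical_kmer(words)
  if (anyNA(canon)) stop("library words must not contain N")
  if (is.null(presence)) presence <- rep(list(character(0)), length(words))
  merged <- split(presence, canon)
  uw <- names(merged)
  ds <- lapply(merged, function(p) sort(unique(unlist(p))))
  tier <- vapply(ds, function(p) {
    if (length(p) == 0L) NA_character_ else classify_confidence(p, n_datasets)
  }, character(1))
  out <- tibble(word = uw,
                tier = unname(tier),
                datasets = unname(vapply(ds, paste, character(1),
                                         collapse = ",")))
  out <- out[order(out$word), , drop = FALSE]
  class(out) <- c("motif_library", class(out))
  out
}

# TRUE per sequence if it contains word or its reverse complement.
seqs_contain_word <- function(seqs, word) {
  rc <- revcomp(word)
  hit <- grepl(word, seqs, fixed = TRUE)
  if (rc != word) hit <- hit | grepl(rc, seqs, fixed = TRUE)
  hit
}

#' Discover enriched words
#'
#' Exact-word enrichment discovery: every word of the given length occurring
#' in the positive set (reverse-complement occurrences pooled under the
#' canonical form, presence counted once per sequence) is tested for
#' enrichment against the negative set with a one-sided Fisher exact test
#' (hypergeometric tail), Bonferroni-corrected over all tested words.
#'
#' @param positives,negatives Character vectors of sequences.
#' @param word_length Word length (>= 3; default 12).
#' @param alpha Family-wise significance level after Bonferroni.
#' @return Tibble \code{word, n_pos, n_neg, p, p_adj}, ranked by p, only
#'   rows with \code{p_adj <= alpha}.
#' @export
discover_enriched_words <- function(positives, negatives, word_length = 12L,
                                    alpha = 0.05) {
  if (word_length < 3L) stop("word_length must be >= 3")
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  per_seq_words <- function(seqs) {
    lapply(seqs, function(s) {
      ids <- kmer_ids(seq_to_codes(s), word_length)
      ids <- ids[!is.na(ids)]
      if (length(ids) == 0L) return(integer(0))
      unique(pmin(ids, revcomp_ids(ids, word_length)))
    })
  }
  pos_w <- per_seq_words(positives)
  neg_w <- per_seq_words(negatives)
  cand <- sort(unique(unlist(pos_w)))
  if (length(cand) == 0L) {
    return(tibble(word = character(0), n_pos = integer(0), n_neg = integer(0),
                  p = numeric(0), p_adj = numeric(0)))
  }
  n_pos <- tabulate(match(unlist(pos_w), cand), nbins = length(cand))
  n_neg <- tabulate(match(unlist(neg_w), cand), nbins = length(cand))
  N1 <- length(positives); N2 <- length(negatives)
  # one-sided Fisher exact: P(X >= n_pos) under Hyper(N1, N2, n_pos + n_neg)
  p <- phyper(n_pos - 1L, N1, N2, n_pos + n_neg, lower.tail = FALSE)
  p_adj <- pmin(1, p * length(cand))
  keep <- p_adj <= alpha
  out <- tibble(word = id_to_kmer(cand[keep], word_length),
                n_pos = n_pos[keep], n_neg = n_neg[keep],
                p = p[keep], p_adj = p_adj[keep])
  out[order(out$p, out$word), , drop = FALSE]
}

# base-shuffled copy of each sequence, used as the default discovery
# background (composition preserved, word structure destroyed)
shuffle_sequences <- function(seqs, seed = 1L) {
  set.seed(seed)
  vapply(seqs, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Iteratively build a GBM library from peak datasets
#'
#' For each dataset: sequences matching the current library are removed;
#' enriched words are discovered in the remainder (against per-dataset
#' negatives, by default base-shuffled copies); words passing the GLI-like
#' structural filter join the library; the loop repeats until no new
#' accepted word remains. Presence and confidence tiers are then computed by
#' matching every library word against every full dataset.
#'
#' @param datasets Named list of character vectors of peak sequences.
#' @param seed_words Initial GBM patterns (12-mers), e.g. known consensus
#'   sites; only those actually present in some dataset are retained.
#' @param negatives Optional named list of negative sequence sets (parallel
#'   to \code{datasets}); default base-shuffled copies.
#' @param word_length Word length (12).
#' @param alpha Discovery significance level.
#' @param max_iter Iteration cap per dataset; exceeding it is an error.
#' @param seed Seed for the default shuffled negatives.
#' @return A \code{\link{motif_library}} tibble.
#' @export
iterative_library_build <- function(datasets, seed_words = character(0),
                                    negatives = NULL, word_length = 12L,
                                    alpha = 0.05, max_iter = 25L, seed = 1L) {
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  if (is.null(negatives)) {
    negatives <- lapply(seq_along(datasets), function(i) {
      shuffle_sequences(datasets[[i]], seed = seed + i)
    })
    names(negatives) <- names(datasets)
  }
  words <- unique(canonical_kmer(seed_words))
  for (ds in names(datasets)) {
    remaining <- datasets[[ds]]
    neg <- negatives[[ds]]
    for (it in seq_len(max_iter + 1L)) {
      if (it > max_iter) stop("library construction did not converge within ",
                              max_iter, " iterations for dataset ", ds)
      if (length(words) > 0L && length(remaining) > 0L) {
        hit <- Reduce(`|`, lapply(words, seqs_contain_word, seqs = remaining))
        remaining <- remaining[!hit]
      }
      if (length(remaining) == 0L) break
      found <- discover_enriched_words(remaining, neg,
                                       word_length = word_length, alpha = alpha)
      accepted <- found$word[is_gli_like(found$word)]
      accepted <- setdiff(accepted, words)
      if (length(accepted) == 0L) break
      words <- c(words, accepted)
    }
  }
  if (length(words) == 0L) return(motif_library(character(0)))
  presence <- lapply(words, function(w) {
    names(datasets)[vapply(datasets, function(seqs) any(seqs_contain_word(seqs, w)),
                           logical(1))]
  })
  present <- lengths(presence) > 0L
  motif_library(words[present], presence[present],
                n_datasets = length(datasets))
}

#' Build a position weight matrix from aligned words
#'
#' @param words Equal-length words over A,C,G,T.
#' @param pseudocount Added to every cell: \eqn{f(i,b) = (n_{ib} + c) /
#'   (n + 4c)}.
#' @return Object of class \code{pwm}: list with \code{width} and
#'   \code{freqs} (4 x width matrix, rows A,C,G,T; columns sum to 1).
#' @export
build_pwm <- function(words, pseudocount = 0.01) {
  if (length(words) == 0L) stop("need at least one word")
  w <- unique(nchar(words))
  if (length(w) != 1L) stop("words must have equal length")
  mat <- vapply(seq_len(w), function(i) {
    b <- substr(words, i, i)
    counts <- c(A = sum(b == "A"), C = sum(b == "C"),
                G = sum(b == "G"), T = sum(b == "T"))
    if (sum(counts) != length(words)) stop("words must be over A,C,G,T")
    (counts + pseudocount) / (length(words) + 4 * pseudocount)
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(width = as.integer(w), freqs = mat), class = "pwm")
}

# per-column information weight I(i) = sum_b f ln(4 f), with 0 ln 0 = 0
pwm_information <- function(pwm) {
  apply(pwm$freqs, 2, function(f) {
    nz <- f > 0
    sum(f[nz] * log(4 * f[nz]))
  })
}

#' Matrix similarity score of a sequence against a PWM
#'
#' MATCH-style information-weighted similarity scaled to \code{[0, 1]}:
#' \eqn{(\mathrm{Current}-\mathrm{Min})/(\mathrm{Max}-\mathrm{Min})} with
#' \eqn{\mathrm{Current} = \sum_i I(i) f(i, b_i)} and Max/Min over each
#' column's observed (positive) base frequencies;
#' \eqn{I(i) = \sum_b f \ln(4f)} with \eqn{0 \ln 0 = 0}. Zero-frequency
#' bases (possible only for an unsmoothed matrix) cannot occur in a
#' motif-consistent sequence, so they are excluded from the attainable
#' score range and a sequence using one floors at 0. A degenerate matrix
#' (Max = Min) scores 1.
#'
#' @param pwm A \code{\link{build_pwm}} object.
#' @param seq Sequence of length \code{pwm$width}, no N.
#' @return Score in \code{[0, 1]}.
#' @export
matrix_similarity <- function(pwm, seq) {
  if (nchar(seq) != pwm$width) stop("sequence length must equal PWM width")
  if (grepl("N", seq, fixed = TRUE)) stop("sequence must not contain N")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("invalid base in sequence")
  info <- pwm_information(pwm)
  f_cur <- pwm$freqs[cbind(match(bases, rownames(pwm$freqs)), seq_len(pwm$width))]
  cur <- sum(info * f_cur)
  mx <- sum(info * apply(pwm$freqs, 2, max))
  mn <- sum(info * apply(pwm$freqs, 2, function(f) min(f[f > 0])))
  if (mx == mn) return(1.0)
  max(0, (cur - mn) / (mx - mn))
}

# exact occurrences of canonical library words (both strands) along a code
# vector; returns 0-based starts, strand and the canonical word
match_words_in_codes <- function(codes, words, chunk = 200000L) {
  k <- GBM_WIDTH
  fwd_ids <- kmer_to_id(words)
  rc_words <- revcomp(words)
  pal <- rc_words == words
  rc_ids <- kmer_to_id(rc_words[!pal])
  rc_names <- words[!pal]
  n <- length(codes)
  if (n < k) {
    return(list(start = integer(0), strand = character(0), word = character(0)))
  }
  starts <- integer(0); strands <- character(0); hits <- character(0)
  pos0 <- 1L
  while (pos0 <= n - k + 1L) {
    pos1 <- min(n, pos0 + chunk + k - 2L)
    ids <- kmer_ids(codes[pos0:pos1], k)
    mf <- match(ids, fwd_ids)
    wf <- which(!is.na(mf))
    if (length(wf)) {
      starts <- c(starts, pos0 - 2L + wf)   # 0-based genomic start
      strands <- c(strands, rep("+", length(wf)))
      hits <- c(hits, words[mf[wf]])
    }
    if (length(rc_ids)) {
      mr <- match(ids, rc_ids)
      wr <- which(!is.na(mr))
      if (length(wr)) {
        starts <- c(starts, pos0 - 2L + wr)
        strands <- c(strands, rep("-", length(wr)))
        hits <- c(hits, rc_names[mr[wr]])
      }
    }
    pos0 <- pos0 + chunk
  }
  o <- order(starts, strands)
  list(start = starts[o], strand = strands[o], word = hits[o])
}

#' Find every genomic GBM match
#'
#' Exact occurrences of any library word, on either strand, overlaps
#' allowed; a site matching a word in its canonical orientation is reported
#' on \code{+}, a site matching the reverse complement on \code{-}; a
#' reverse-complement-palindromic word is reported once, on \code{+}.
#'
#' @param genome Named character vector of contigs.
#' @param library A \code{\link{motif_library}} (or tibble with
#'   \code{word}/\code{tier}).
#' @return Region tibble \code{contig,start,end,strand,name,tier}, sorted by
#'   (contig, start); \code{name} is the canonical word.
#' @export
scan_genome_for_gbm <- function(genome, library) {
  if (nrow(library) == 0L) stop("motif library is empty")
  tier_of <- setNames(library$tier, library$word)
  out <- lapply(names(genome), function(ctg) {
    m <- match_words_in_codes(seq_to_codes(genome[[ctg]]), library$word)
    tibble(contig = ctg, start = m$start, end = m$start + GBM_WIDTH,
           strand = m$strand, name = m$word,
           tier = unname(tier_of[m$word]))
  })
  res <- do.call(rbind, out)
  sort_regions(res)
}

#' Find GBM matches inside peak sequences
#'
#' @param seqs Character vector of peak sequences.
#' @param library A \code{\link{motif_library}}.
#' @return Tibble \code{seq_index, start, strand, word, tier} with 0-based
#'   within-sequence starts.
#' @export
scan_sequences_for_gbm <- function(seqs, library) {
  if (nrow(library) == 0L) stop("motif library is empty")
  tier_of <- setNames(library$tier, library$word)
  out <- lapply(seq_along(seqs), function(i) {
    m <- match_words_in_codes(seq_to_codes(seqs[[i]]), library$word)
    tibble(seq_index = i, start = m$start, strand = m$strand, word = m$word,
           tier = unname(tier_of[m$word]))
  })
  do.call(rbind, out)
}

#' In silico GLI-site knockout
#'
#' Reproduces the site-directed mutation used to test GLI dependence:
#' within each matched GBM the invariant core C -- the 6th position of the
#' 9-mer GLI core, i.e. position 7 of the 12-mer in its GLI-frame
#' orientation -- is replaced by G (complementary substitution at the
#' mirrored coordinate for matches whose GLI frame runs on the minus
#' strand). The mutated site no longer matches any GLI-like word.
#'
#' @param seq A single sequence.
#' @param matches Tibble of matches within \code{seq}: columns \code{start}
#'   (0-based), \code{strand}, \code{word} (canonical, as from
#'   \code{\link{scan_sequences_for_gbm}}).
#' @return The mutated sequence.
#' @export
gko_mutate <- function(seq, matches) {
  if (nrow(matches) == 0L) return(seq)
  if (any(matches$start < 0L | matches$start + GBM_WIDTH > nchar(seq))) {
    stop("match outside sequence bounds")
  }
  for (i in seq_len(nrow(matches))) {
    word <- matches$word[i]
    # orientation of the GLI frame in genome coordinates
    genome_word <- if (matches$strand[i] == "+") word else revcomp(word)
    frame <- gli_frame_strand(genome_word)
    if (frame == "+") {
      pos <- matches$start[i] + GKO_POS          # 1-based index in seq
      expected <- "C"; replacement <- "G"
    } else {
      pos <- matches$start[i] + (GBM_WIDTH - GKO_POS) + 1L
      expected <- "G"; replacement <- "C"
    }
    if (substr(seq, pos, pos) != expected) {
      stop("GKO frame inconsistency: expected ", expected, " at position ",
           pos, " but found ", substr(seq, pos, pos))
    }
    substr(seq, pos, pos) <- replacement
  }
  seq
}

#' Write / read a motif library TSV
#'
#' Columns \code{word}, \code{tier}, \code{datasets} (comma-joined).
#'
#' @param library A \code{\link{motif_library}}.
#' @param path File path.
#' @return \code{path} (write) or a \code{motif_library} (read).
#' @export
write_motif_library <- function(library, path) {
  utils::write.table(as.data.frame(library)[, c("word", "tier", "datasets")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_library
#' @export
read_motif_library <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  out <- tibble(word = df$word, tier = df$tier, datasets = df$datasets)
  class(out) <- c("motif_library", class(out))
  out
}

#' Export GBM matches as BED6
#'
#' Name column carries the canonical word; score encodes the tier rank
#' (HC = 1, MC = 2, LC = 3).
#'
#' @param matches Output of \code{\link{scan_genome_for_gbm}}.
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
write_gbm_matches_bed <- function(matches, path) {
  rank <- c(HC = 1, MC = 2, LC = 3)[matches$tier]
  rank[is.na(rank)] <- 0  # library without presence bookkeeping
  write_bed(matches[, c("contig", "start", "end", "strand", "name")], path,
            scores = unname(rank))
}
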