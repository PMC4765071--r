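# Independent oracles and small fixture builders used across the suite.

rand_seq <- function(n, len, gc = 0.5) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
}

# brute-force interval overlap (>= 1 shared bp, half-open)
brute_overlaps_any <- function(query, track_regions) {
  vapply(seq_len(nrow(query)), function(i) {
    any(track_regions$contig == query$contig[i] &
          track_regions$start < query$end[i] &
          track_regions$end > query$start[i])
  }, logical(1))
}

# naive O(n*m) substring scan for canonical library words on both strands;
# mirrors the reporting contract (canonical word; strand from forward match)
naive_gbm_scan <- function(genome, words) {
  out <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    for (w in words) {
      hits <- gregexpr(w, s, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      for (h in hits) {
        out[[length(out) + 1]] <- data.frame(
          contig = ctg, start = h - 1L, end = h - 1L + nchar(w),
          strand = "+", name = w, stringsAsFactors = FALSE)
      }
      rc <- gliscan::revcomp(w)
      if (rc != w) {
        hits <- gregexpr(rc, s, fixed = TRUE)[[1]]
        hits <- hits[hits > 0]
        for (h in hits) {
          out[[length(out) + 1]] <- data.frame(
            contig = ctg, start = h - 1L, end = h - 1L + nchar(w),
            strand = "-", name = w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$strand, df$name), , drop = FALSE]
}

# all-pairs Mann-Whitney concordance (ties half credit)
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# hand-rolled two-proportion pooled Z for cross-checking
oracle_two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

# minimal hand-built model: zero weights except named k-mers
toy_model <- function(weights = c(), bias = 0, k = 8L,
                      platt_a = NA_real_, platt_b = NA_real_) {
  index <- gliscan::kmer_index(k)
  w <- numeric(index$n_features)
  for (nm in names(weights)) {
    canon <- gliscan::canonical_kmer(nm)
    w[match(canon, index$kmers)] <- weights[[nm]]
  }
  structure(list(k = as.integer(k), weights = w, bias = bias,
                 platt_a = platt_a, platt_b = platt_b,
                 meta = list(C = 1, seed = 0L, n_pos = 0L, n_neg = 0L)),
            class = "kmer_model")
}

toy_library <- function(words = gliscan::default_gbm_words(),
                        presence = NULL) {
  gliscan::motif_library(words, presence)
}
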