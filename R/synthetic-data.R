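# Seeded generators for every input the pipeline consumes: i.i.d. genomes,
# peak sets carrying a GLI enhancer grammar (GBM near the peak midpoint,
# a cofactor word offset from it), multi-dataset studies with controlled
# sharing structure, and feature tracks enriched over true enhancers.

#' Default GLI-like grammar words
#'
#' Four 12-mers built on the 9-mer GLI core \code{GACCACCCA} (occupying
#' positions 2-10) with varying flanks, matching the near-invariant
#' \code{xGxCCxCxCxxx} structure of high-confidence genomic GLI sites.
#'
#' @return Character vector of 12-mers.
#' @export
default_gbm_words <- function() {
  c("AGACCACCCAAA", "TGACCACCCACT", "CGACCACCCAGG", "GGACCACCCATC")
}

#' Synthetic enhancer grammar configuration
#'
#' Parameters of the generative model for positive peaks: which GBM words
#' are implanted, the probability a peak carries exactly one GBM (vs two),
#' how far the GBM sits from the peak midpoint, which cofactor words are
#' implanted and at what offset, peak width and background GC.
#'
#' @param gbm_words GLI-like 12-mers to implant.
#' @param cofactor_words Cofactor motifs (an E-box-like and a Sox-like word
#'   by default), one implanted per peak.
#' @param p_single_gbm Probability of exactly one GBM per peak (default
#'   0.88, the mean single-site fraction across the four ChIP contexts).
#' @param gbm_offset_sd SD (bp) of the GBM center around the peak midpoint.
#' @param cofactor_offset_mean,cofactor_offset_sd Cofactor center offset
#'   from the midpoint (bp), random side (defaults 200 / 50).
#' @param peak_width Peak width in bp (default 600).
#' @param gc Background GC fraction (default 0.42, mouse-like).
#' @return List of class \code{grammar_config}.
#' @export
grammar_config <- function(gbm_words = default_gbm_words(),
                           cofactor_words = c(ebox = "GCACCTGT",
                                              sox = "CTTTGTTC"),
                           p_single_gbm = 0.88,
                           gbm_offset_sd = 30,
                           cofactor_offset_mean = 200,
                           cofactor_offset_sd = 50,
                           peak_width = 600L,
                           gc = 0.42) {
  stopifnot(p_single_gbm >= 0, p_single_gbm <= 1, gc > 0, gc < 1,
            peak_width >= 100L, all(nchar(gbm_words) == 12L))
  if (!all(is_gli_like(gbm_words))) stop("gbm_words must be GLI-like 12-mers")
  structure(list(gbm_words = gbm_words, cofactor_words = cofactor_words,
                 p_single_gbm = p_single_gbm, gbm_offset_sd = gbm_offset_sd,
                 cofactor_offset_mean = cofactor_offset_mean,
                 cofactor_offset_sd = cofactor_offset_sd,
                 peak_width = as.integer(peak_width), gc = gc),
            class = "grammar_config")
}

#' @rdname grammar_config
#' @export
default_grammar <- function() grammar_config()

#' Generate an i.i.d. random genome
#'
#' Bases drawn independently with \eqn{P(G) = P(C) = gc/2}; deterministic
#' per seed.
#'
#' @param length Contig length (>= 1000).
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @param contig_name Contig name (default \code{"chrS"}).
#' @return Named character vector with one contig.
#' @export
generate_genome <- function(length, gc = 0.42, seed = 1L,
                            contig_name = "chrS") {
  if (length < 1000L) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0, 1)")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  setNames(paste(bases, collapse = ""), contig_name)
}

# all non-overlapping peak slots (2x width spacing, 0-based starts of the
# usable slot) across contigs
peak_slots <- function(genome, width) {
  out <- lapply(names(genome), function(ctg) {
    n_slot <- nchar(genome[[ctg]]) %/% (2L * width)
    if (n_slot == 0L) return(NULL)
    tibble(contig = ctg, slot_start = (seq_len(n_slot) - 1L) * 2L * width)
  })
  do.call(rbind, out)
}

# apply all implants to the genome in one pass per contig (whole-string
# substr replacement is quadratic over thousands of implants)
apply_implants <- function(genome, truth) {
  for (ctg in unique(truth$contig)) {
    chars <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1]]
    rows <- truth[truth$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      s <- if (rows$strand[i] == "+") rows$word[i] else revcomp(rows$word[i])
      chars[(rows$start[i] + 1L):rows$end[i]] <- strsplit(s, "", fixed = TRUE)[[1]]
    }
    genome[[ctg]] <- paste(chars, collapse = "")
  }
  genome
}

# sample an implant start (0-based, within [0, width - wlen]) around a
# target center, avoiding previously used intervals; NULL if impossible
place_nonoverlapping <- function(width, wlen, center, used, max_tries = 100L) {
  for (tr in seq_len(max_tries)) {
    st <- as.integer(round(center - wlen / 2))
    st <- max(0L, min(width - wlen, st))
    ok <- TRUE
    if (length(used) > 0L) {
      for (u in used) if (st < u[2] && st + wlen > u[1]) { ok <- FALSE; break }
    }
    if (ok) return(st)
    center <- sample.int(width - wlen + 1L, 1L) - 1L + wlen / 2
  }
  NULL
}

#' Generate positive peaks carrying the enhancer grammar
#'
#' Picks \code{n} non-overlapping fixed-width regions on the genome and
#' implants each with one GBM (probability \code{p_single_gbm}) or two,
#' the first near the peak midpoint, plus one cofactor word at a
#' normally-distributed offset from the midpoint on a random side; all
#' implants land on a random strand and overwrite the genome in place
#' (no indels), so truth coordinates stay valid.
#'
#' @param genome Named character vector of contigs.
#' @param grammar A \code{\link{grammar_config}}.
#' @param n Number of peaks.
#' @param seed Integer seed.
#' @return List: \code{genome} (with implants), \code{peaks} (region
#'   tibble), \code{truth} (tibble of implant coordinates: peak, contig,
#'   start, end, strand, word, type).
#' @export
generate_positive_peaks <- function(genome, grammar, n, seed = 1L) {
  w <- grammar$peak_width
  slots <- peak_slots(genome, w)
  if (is.null(slots) || nrow(slots) < n) {
    stop("cannot place ", n, " non-overlapping peaks of width ", w,
         " on this genome")
  }
  set.seed(seed)
  pick <- slots[sample.int(nrow(slots), n), , drop = FALSE]
  starts <- pick$slot_start + (sample.int(w - 1L, n, replace = TRUE) - 1L)
  peaks <- tibble(contig = pick$contig, start = starts, end = starts + w,
                  strand = ".", name = sprintf("peak_%d", seq_len(n)))
  peaks <- sort_regions(peaks)
  peaks$name <- sprintf("peak_%d", seq_len(n))
  truth <- vector("list", n)
  mid <- w / 2
  for (i in seq_len(n)) {
    used <- list()
    implants <- list()
    n_gbm <- 1L + rbinom(1L, 1L, 1 - grammar$p_single_gbm)
    for (g in seq_len(n_gbm)) {
      word <- sample(grammar$gbm_words, 1L)
      center <- if (g == 1L) mid + rnorm(1L, 0, grammar$gbm_offset_sd) else {
        sample.int(w - 12L + 1L, 1L) - 1L + 6
      }
      st <- place_nonoverlapping(w, 12L, center, used)
      if (is.null(st)) stop("could not place GBM implant in peak ", i)
      used <- c(used, list(c(st, st + 12L)))
      implants <- c(implants, list(list(start = st, word = word,
                                        strand = sample(c("+", "-"), 1L),
                                        type = "gbm")))
    }
    cw <- unname(sample(grammar$cofactor_words, 1L))
    side <- sample(c(-1, 1), 1L)
    center <- mid + side * rnorm(1L, grammar$cofactor_offset_mean,
                                 grammar$cofactor_offset_sd)
    st <- place_nonoverlapping(w, nchar(cw), center, used)
    if (is.null(st)) stop("could not place cofactor implant in peak ", i)
    implants <- c(implants, list(list(start = st, word = cw,
                                      strand = sample(c("+", "-"), 1L),
                                      type = "cofactor")))
    rows <- lapply(implants, function(im) {
      gstart <- peaks$start[i] + im$start
      tibble(peak = peaks$name[i], contig = peaks$contig[i],
             start = gstart, end = gstart + nchar(im$word),
             strand = im$strand, word = im$word, type = im$type)
    })
    truth[[i]] <- do.call(rbind, rows)
  }
  truth <- do.call(rbind, truth)
  list(genome = apply_implants(genome, truth), peaks = peaks, truth = truth)
}

#' Generate a multi-dataset study with a fixed sharing design
#'
#' Builds a genome and a set of enhancer peaks, then assigns each peak to
#' the datasets of its design subset, so that \code{\link{venn_overlap}} on
#' the resulting peak lists reproduces the design exactly (regions are
#' separated by construction and never merge).
#'
#' @param grammar A \code{\link{grammar_config}}.
#' @param sharing_design Named integer vector; names are subset keys such
#'   as \code{"LD+CD+MB+NP"} or \code{"LD"} (order-insensitive), values are
#'   region counts.
#' @param seed Integer seed.
#' @param genome_length Optional genome length (default sized to the
#'   design).
#' @return List of class \code{synthetic_study}: \code{genome},
#'   \code{datasets} (named list of region tibbles), \code{truth},
#'   \code{design} (canonical keys), \code{grammar}.
#' @export
generate_multidataset_study <- function(grammar, sharing_design, seed = 1L,
                                        genome_length = NULL) {
  members <- strsplit(names(sharing_design), "+", fixed = TRUE)
  ds_names <- sort(unique(unlist(members)))
  if (length(ds_names) > 4L) stop("at most 4 datasets supported")
  keys <- vapply(members, venn_key, character(1))
  names(sharing_design) <- keys
  total <- sum(sharing_design)
  if (total == 0L) {
    return(structure(list(genome = character(0),
                          datasets = setNames(rep(list(
                            tibble(contig = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   name = character(0))), length(ds_names)),
                            ds_names),
                          truth = NULL, design = sharing_design,
                          grammar = grammar),
                     class = "synthetic_study"))
  }
  if (is.null(genome_length)) {
    genome_length <- max(1000L, as.integer(total * grammar$peak_width * 2L + 2L * grammar$peak_width))
  }
  genome <- generate_genome(genome_length, gc = grammar$gc, seed = seed)
  gp <- generate_positive_peaks(genome, grammar, total, seed = seed + 1L)
  assignment <- rep(keys, times = as.integer(sharing_design))
  datasets <- lapply(ds_names, function(ds) {
    in_ds <- vapply(strsplit(assignment, "+", fixed = TRUE),
                    function(m) ds %in% m, logical(1))
    gp$peaks[in_ds, , drop = FALSE]
  })
  names(datasets) <- ds_names
  structure(list(genome = gp$genome, datasets = datasets, truth = gp$truth,
                 peaks = gp$peaks, design = sharing_design, grammar = grammar),
            class = "synthetic_study")
}

#' Generate a feature track enriched over true enhancers
#'
#' Emulates an epigenomic mark concentrated on active enhancers: each
#' enhancer region is covered by a track interval with probability
#' \code{p_enh}; each background region (supplied, or \code{n_bg} random
#' same-width regions placed off the enhancers) is covered with probability
#' \code{p_bg}.
#'
#' @param enhancers Region tibble of true-enhancer regions.
#' @param p_enh Coverage probability over enhancers.
#' @param background_regions Optional region tibble of background regions.
#' @param p_bg Coverage probability over background regions.
#' @param n_bg Number of random background regions when none are supplied.
#' @param genome Genome (required when sampling random background regions).
#' @param seed Integer seed.
#' @param name Track name.
#' @return A \code{\link{feature_track}}.
#' @export
generate_feature_track <- function(enhancers, p_enh, background_regions = NULL,
                                   p_bg = 0, n_bg = 0L, genome = NULL,
                                   seed = 1L, name = "synthetic_track") {
  stopifnot(p_enh >= 0, p_enh <= 1, p_bg >= 0, p_bg <= 1)
  set.seed(seed)
  keep_enh <- enhancers[runif(nrow(enhancers)) < p_enh, , drop = FALSE]
  bg <- NULL
  if (is.null(background_regions) && n_bg > 0L) {
    if (is.null(genome)) stop("genome required to sample background regions")
    w <- as.integer(round(mean(enhancers$end - enhancers$start)))
    clens <- nchar(genome)
    cand <- list(); tries <- 0L
    while (length(cand) < n_bg && tries < 100L * n_bg) {
      tries <- tries + 1L
      ctg <- sample(names(genome), 1L, prob = clens)
      if (clens[[ctg]] < w) next
      st <- sample.int(clens[[ctg]] - w + 1L, 1L) - 1L
      r <- tibble(contig = ctg, start = st, end = st + w, strand = ".",
                  name = "")
      if (any(overlaps_any(r, enhancers))) next
      cand <- c(cand, list(r))
    }
    background_regions <- do.call(rbind, cand)
  }
  if (!is.null(background_regions) && nrow(background_regions) > 0L) {
    bg <- background_regions[runif(nrow(background_regions)) < p_bg, ,
                             drop = FALSE]
  }
  cols <- c("contig", "start", "end", "strand", "name")
  regions <- rbind(keep_enh[, cols, drop = FALSE],
                   if (!is.null(bg)) bg[, cols, drop = FALSE])
  if (is.null(regions)) {
    regions <- tibble(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0))
  }
  feature_track(name, regions)
}

#' Assemble the default training study
#'
#' End-to-end convenience used by the analysis drivers: a synthetic genome,
#' \code{n_pos} grammar-carrying peaks, and a GC-matched background of equal
#' size, with positive and negative sequences extracted.
#'
#' @param seed Integer seed.
#' @param n_pos Number of positive peaks (default 1000).
#' @param grammar A \code{\link{grammar_config}}.
#' @param genome_length Genome length (default sized to \code{n_pos}).
#' @param gc_tol GC-matching tolerance for the background.
#' @return List: \code{genome, peaks, truth, positives, background,
#'   negatives, grammar}.
#' @export
make_training_study <- function(seed = 1L, n_pos = 1000L,
                                grammar = default_grammar(),
                                genome_length = NULL, gc_tol = 0.02) {
  if (is.null(genome_length)) {
    genome_length <- as.integer(n_pos * grammar$peak_width * 4L)
  }
  genome <- generate_genome(genome_length, gc = grammar$gc, seed = seed)
  gp <- generate_positive_peaks(genome, grammar, n_pos, seed = seed + 1L)
  bg <- sample_gc_matched_background(gp$genome, gp$peaks, gc_tol = gc_tol,
                                     seed = seed + 2L)
  list(genome = gp$genome, peaks = gp$peaks, truth = gp$truth,
       positives = region_sequence(gp$genome, gp$peaks),
       background = bg, negatives = bg$sequences, grammar = grammar)
}
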