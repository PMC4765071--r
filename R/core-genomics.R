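#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom setNames pnorm cor phyper
#' @importFrom utils head read.table write.table
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a named character vector of
#' contig sequences. Bases are uppercased and any non-ACGT character
#' (IUPAC ambiguity codes, gaps) is masked to \code{N}; masked bases never
#' match a motif and never contribute a k-mer.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig, over
#'   \code{A,C,G,T,N}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(nchar(seqs) == 0L)) stop("zero-length contig in FASTA")
  setNames(seqs, nm)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorized over a character vector of sequences over \code{A,C,G,T,N};
#' \code{N} maps to \code{N}. An involution: \code{revcomp(revcomp(s)) == s}.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq))) stop("invalid character in sequence")
  empty <- !nzchar(seq)
  out <- seq
  if (any(!empty)) {
    out[!empty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[!empty])))
  }
  out
}

#' GC content of sequences
#'
#' Fraction (G + C) / (A + C + G + T); \code{N} bases are excluded from the
#' denominator. An all-\code{N} (or empty) sequence has no defined GC
#' content and raises an error.
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector of fractions in \code{[0, 1]}.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("gc_content undefined for empty sequence")
  ss <- Biostrings::DNAStringSet(seq)
  counts <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  if (any(denom == 0)) stop("gc_content undefined for all-N sequence")
  unname((counts[, "C"] + counts[, "G"]) / denom)
}

#' Construct a region table
#'
#' Regions are the package's interval currency: a tibble with 0-based
#' half-open coordinates (BED convention), one row per interval.
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Strand, one of \code{"+"}, \code{"-"}, \code{"."}.
#' @param name Free-text label per region.
#' @param ... Further columns, recycled as in \code{tibble()}.
#' @return A tibble with columns \code{contig,start,end,strand,name,...}.
#' @export
regions_tbl <- function(contig, start, end, strand = ".", name = "", ...) {
  tb <- tibble(contig = as.character(contig), start = as.integer(start),
               end = as.integer(end), strand = strand, name = name, ...)
  validate_regions(tb)
  tb
}

#' Validate a region table
#'
#' Checks 0 <= start < end, known strand codes and (optionally) that
#' intervals fit within genome contigs.
#'
#' @param regions Region tibble.
#' @param genome Optional genome to check bounds against.
#' @return \code{regions}, invisibly.
#' @export
validate_regions <- function(regions, genome = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0) {
    if (any(regions$start < 0L) || any(regions$start >= regions$end)) {
      stop("invalid region coordinates: need 0 <= start < end")
    }
    if ("strand" %in% names(regions) &&
        !all(regions$strand %in% c("+", "-", "."))) {
      stop("strand must be one of '+', '-', '.'")
    }
    if (!is.null(genome)) {
      len <- nchar(genome)[regions$contig]
      if (any(is.na(len))) stop("region contig absent from genome")
      if (any(regions$end > len)) stop("region exceeds contig length")
    }
  }
  invisible(regions)
}

#' Sort regions by (contig, start, end)
#' @param regions Region tibble.
#' @return Sorted tibble.
#' @export
sort_regions <- function(regions) {
  regions[order(regions$contig, regions$start, regions$end), , drop = FALSE]
}

# Region tibble (0-based half-open) -> GRanges (1-based closed).
regions_to_granges <- function(regions) {
  strand <- if ("strand" %in% names(regions)) {
    ifelse(regions$strand == ".", "*", regions$strand)
  } else "*"
  GenomicRanges::GRanges(
    seqnames = regions$contig,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = strand)
}

granges_to_regions <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  nm <- if (!is.null(gr$name)) as.character(gr$name) else ""
  tb <- tibble(contig = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = strand, name = nm)
  if (!is.null(gr$score)) tb$score <- as.numeric(gr$score)
  tb
}

#' Build a feature track
#'
#' A named set of (possibly overlapping) regions, e.g. DNaseI hypersensitive
#' sites or histone-mark intervals, kept sorted by (contig, start).
#'
#' @param name Track name.
#' @param regions Region tibble.
#' @return An object of class \code{feature_track}.
#' @export
feature_track <- function(name, regions) {
  validate_regions(regions)
  structure(list(name = name, regions = sort_regions(regions)),
            class = "feature_track")
}

track_regions <- function(track) {
  if (inherits(track, "feature_track")) track$regions else track
}

#' Test regions for overlap with a feature track
#'
#' A region overlaps the track iff it shares at least one base pair with at
#' least one track interval; strand is ignored.
#'
#' @param query Region tibble (any number of rows).
#' @param track A \code{feature_track} or a region tibble.
#' @return Logical vector, one element per row of \code{query}.
#' @export
overlaps_any <- function(query, track) {
  tr <- track_regions(track)
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(tr) == 0L) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(regions_to_granges(query), regions_to_granges(tr),
                       ignore.strand = TRUE)
}

#' Extract region sequences from a genome
#'
#' @param genome Named character vector of contigs.
#' @param regions Region tibble; rows with strand \code{"-"} are
#'   reverse-complemented.
#' @return Character vector of sequences, one per region.
#' @export
region_sequence <- function(genome, regions) {
  validate_regions(regions, genome)
  if (nrow(regions) == 0L) return(character(0))
  seqs <- substring(genome[regions$contig], regions$start + 1L, regions$end)
  if ("strand" %in% names(regions)) {
    neg <- regions$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  }
  unname(seqs)
}

#' Read a BED file into a region table
#'
#' BED4/BED6 via rtracklayer; coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return Region tibble (with \code{score} column when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  granges_to_regions(gr)
}

#' Write regions to a BED file
#'
#' @param regions Region tibble; optional \code{name}, \code{score},
#'   \code{strand} columns become BED columns 4-6.
#' @param path Output path.
#' @param scores Optional numeric vector overriding the score column.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(regions, path, scores = NULL) {
  validate_regions(regions)
  gr <- regions_to_granges(regions)
  if (!is.null(scores)) {
    gr$score <- scores
  } else if ("score" %in% names(regions)) {
    gr$score <- regions$score
  }
  if ("name" %in% names(regions)) gr$name <- regions$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path.
#' @return Tibble with columns \code{contig,start,end,value} (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end = BiocGenerics::end(gr),
         value = as.numeric(gr$score))
}

#' Write a bedGraph file
#'
#' Intervals must be sorted by (contig, start) and non-overlapping, as the
#' format requires.
#'
#' @param values Tibble with columns \code{contig,start,end,value}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(values, path) {
  stopifnot(all(c("contig", "start", "end", "value") %in% names(values)))
  if (nrow(values) > 1L) {
    o <- order(values$contig, values$start)
    if (!identical(o, seq_len(nrow(values)))) {
      stop("bedGraph intervals must be sorted by (contig, start)")
    }
    same <- values$contig[-1L] == values$contig[-nrow(values)]
    if (any(same & values$start[-1L] < values$end[-nrow(values)])) {
      stop("bedGraph intervals must not overlap")
    }
  }
  gr <- GenomicRanges::GRanges(
    values$contig,
    IRanges::IRanges(values$start + 1L, values$end),
    score = values$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
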