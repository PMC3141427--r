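#' @useDynLib ighloci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

# Sequences travel as named character vectors over {A,C,G,T,N}, uppercase.
# Intervals are 0-based half-open internally; GFF3 output is 1-based inclusive.

#' Normalize a nucleotide string
#'
#' Uppercases, converts U to T, and validates the alphabet. Any character
#' outside A/C/G/T/N is a hard error naming the first offending position
#' (1-based within the record).
#'
#' @param x character scalar.
#' @param id sequence id used in error messages.
#' @return normalized character scalar.
#' @export
normalize_residues <- function(x, id = "?") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("U", "T", toupper(x))
  x <- gsub("[ \t\r\n]", "", x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    stop(sprintf("sequence '%s': invalid character '%s' at position %d",
                 id, substr(x, bad, bad), bad))
  }
  x
}

#' Read a FASTA file into a named character vector
#'
#' Records are normalized (uppercase, U->T) and validated against the
#' A/C/G/T/N alphabet. Duplicate ids are a hard error; an empty file yields
#' an empty vector with a warning. Record order is preserved. Ids are taken
#' up to the first whitespace of the header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("[ \t].*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: '", dup[1L], "' in ", path)
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(i) normalize_residues(seqs[[i]], ids[[i]]), "")
  stats::setNames(out, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' N maps to N. Invalid characters are an error.
#'
#' @param x character scalar over A/C/G/T/N.
#' @return reverse complement, same length.
#' @export
revcomp <- function(x) {
  x <- normalize_residues(x)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract an interval's sequence, honoring strand
#'
#' Coordinates are 0-based half-open on the forward sequence; minus-strand
#' intervals are reverse-complemented on extraction.
#'
#' @param seq forward-strand sequence (character scalar).
#' @param start,end 0-based half-open bounds.
#' @param strand "+" or "-".
#' @return extracted (oriented) sequence.
#' @export
extract_interval <- function(seq, start, end, strand = "+") {
  n <- nchar(seq)
  if (!(start >= 0 && start < end && end <= n)) {
    stop(sprintf("interval [%d,%d) out of bounds for sequence of length %d",
                 start, end, n))
  }
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' An empty annotation table
#'
#' Canonical column layout for located features: `seq_id`, `start`, `end`
#' (0-based half-open), `strand`, `type` (V_gene_segment, D_gene_segment,
#' J_gene_segment, exon, region), `label`, `zone_id`, `score`.
#'
#' @return zero-row data.frame with the canonical columns.
#' @export
empty_annotations <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), type = character(0), label = character(0),
             zone_id = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.GFF_TYPES <- c("V_gene_segment", "D_gene_segment", "J_gene_segment",
                "exon", "region")

.as_annotations <- function(df) {
  tmpl <- empty_annotations()
  for (col in names(tmpl)) {
    if (is.null(df[[col]])) {
      df[[col]] <- rep(switch(col,
                              zone_id = NA_integer_,
                              score = NA_real_,
                              strand = "+",
                              NA_character_),
                       nrow(df))
    }
  }
  df[, union(names(tmpl), names(df)), drop = FALSE]
}

#' Write an annotation table as GFF3
#'
#' Internal 0-based half-open intervals become 1-based inclusive GFF3 columns.
#' Features are sorted by seq_id then start. Intervals out of bounds against
#' `seq_lens` (if given) are a hard error.
#'
#' @param annotations data.frame as [empty_annotations()].
#' @param path output path.
#' @param seq_lens optional named integer vector of sequence lengths.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path, seq_lens = NULL) {
  annotations <- .as_annotations(annotations)
  if (nrow(annotations) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  stopifnot(all(annotations$start >= 0), all(annotations$end > annotations$start))
  if (!is.null(seq_lens)) {
    lens <- seq_lens[annotations$seq_id]
    if (any(is.na(lens)) || any(annotations$end > lens)) {
      stop("annotation interval out of bounds for its sequence")
    }
  }
  if (!all(annotations$type %in% .GFF_TYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(unique(annotations$type), .GFF_TYPES), collapse = ", "))
  }
  o <- order(annotations$seq_id, annotations$start, annotations$end)
  annotations <- annotations[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$seq_id,
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = annotations$strand
  )
  S4Vectors::mcols(gr)$type <- annotations$type
  S4Vectors::mcols(gr)$source <- "ighloci"
  S4Vectors::mcols(gr)$ID <- sprintf("feat%05d", seq_len(nrow(annotations)))
  S4Vectors::mcols(gr)$label <- annotations$label
  S4Vectors::mcols(gr)$zone_id <- annotations$zone_id
  S4Vectors::mcols(gr)$score <- annotations$score
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into the internal annotation layout
#'
#' Inverse of [write_gff3()]: 1-based inclusive GFF3 records become 0-based
#' half-open intervals.
#'
#' @param path GFF3 path.
#' @return data.frame as [empty_annotations()].
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0L) return(empty_annotations())
  mc <- S4Vectors::mcols(gr)
  zid <- if ("zone_id" %in% names(mc)) suppressWarnings(as.integer(mc$zone_id)) else NA_integer_
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    type = as.character(mc$type),
    label = if ("label" %in% names(mc)) as.character(mc$label) else NA_character_,
    zone_id = zid,
    score = if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_,
    stringsAsFactors = FALSE
  )
}

# fast char-vector view of a sequence, for Hamming arithmetic
.raw_seq <- function(x) charToRaw(x)
.RAW_N <- charToRaw("N")

#' Hamming distance between equal-length nucleotide strings
#'
#' N never matches anything (including N), mirroring the conservative
#' treatment of assembly gaps.
#'
#' @param a,b equal-length character scalars.
#' @return integer mismatch count.
#' @export
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb | ra == .RAW_N | rb == .RAW_N)
}
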