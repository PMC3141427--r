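# Recombination signal sequence (RSS) model and scanning.
#
# An RSS is heptamer + 12- or 23-bp spacer + nonamer. The heptamer is always
# coding-proximal. Two orientations occur on a strand:
#   downstream_of_coding: coding | heptamer > spacer > nonamer   (e.g. 3' of VH)
#   upstream_of_coding:   nonamer' < spacer < heptamer' | coding (e.g. 5' of JH)
# where ' marks elements written in reverse complement on the strand scanned.

#' RSS consensus model
#'
#' Defaults: canonical vertebrate heptamer CACAGTG with at most 1 mismatch
#' (the heptamer consensus and its tolerance are a package choice, exposed
#' here, since only the nonamer consensus is fixed by convention in this
#' locus style) and nonamer TATTATTGT with at most 2 mismatches. The spacer
#' may deviate from its nominal class by `spacer_slack` (default 1 bp;
#' 0 gives the strict reading of an exact 12/23-bp spacer).
#'
#' @param spacer_class 12 or 23.
#' @param heptamer,nonamer consensus strings of lengths 7 and 9.
#' @param heptamer_max_mm,nonamer_max_mm per-element mismatch caps.
#' @param spacer_slack allowed +/- deviation of the spacer length.
#' @return an object of class `rss_model`.
#' @export
rss_model <- function(spacer_class = 23L,
                      heptamer = "CACAGTG",
                      nonamer = "TATTATTGT",
                      heptamer_max_mm = 1L,
                      nonamer_max_mm = 2L,
                      spacer_slack = 1L) {
  heptamer <- normalize_residues(heptamer, "heptamer")
  nonamer <- normalize_residues(nonamer, "nonamer")
  stopifnot(nchar(heptamer) == 7L, nchar(nonamer) == 9L,
            spacer_class %in% c(12L, 23L),
            heptamer_max_mm >= 0L, heptamer_max_mm <= 7L,
            nonamer_max_mm >= 0L, nonamer_max_mm <= 9L,
            spacer_slack >= 0L)
  structure(list(heptamer = heptamer, nonamer = nonamer,
                 spacer_class = as.integer(spacer_class),
                 heptamer_max_mm = as.integer(heptamer_max_mm),
                 nonamer_max_mm = as.integer(nonamer_max_mm),
                 spacer_slack = as.integer(spacer_slack)),
            class = "rss_model")
}

#' Exhaustive Hamming scan of a motif over a sequence
#'
#' Returns every window whose Hamming distance to `motif` is at most
#' `max_mm`. N in either string counts as a mismatch. Positions are 0-based
#' and ascending. A motif longer than the sequence yields an empty result.
#'
#' @param seq sequence (character scalar, normalized).
#' @param motif motif (character scalar).
#' @param max_mm maximum mismatches.
#' @return data.frame with columns `pos` (0-based) and `mismatches`.
#' @export
hamming_scan <- function(seq, motif, max_mm = 0L) {
  n <- nchar(seq); w <- nchar(motif)
  if (w > n || w == 0L) {
    return(data.frame(pos = integer(0), mismatches = integer(0)))
  }
  rs <- charToRaw(seq); rm <- charToRaw(motif)
  nw <- n - w + 1L
  mm <- integer(nw)
  idx0 <- seq_len(nw)
  for (j in seq_len(w)) {
    sj <- rs[idx0 + (j - 1L)]
    mm <- mm + as.integer(sj != rm[j] | sj == .RAW_N | rm[j] == .RAW_N)
  }
  keep <- which(mm <= max_mm)
  data.frame(pos = keep - 1L, mismatches = mm[keep])
}

.empty_rss_hits <- function() {
  data.frame(seq_id = character(0), strand = character(0),
             orientation = character(0),
             hept_start = integer(0), hept_end = integer(0),
             nona_start = integer(0), nona_end = integer(0),
             spacer_len = integer(0),
             hept_mm = integer(0), nona_mm = integer(0), total_mm = integer(0),
             stringsAsFactors = FALSE)
}

# scan one strandless sequence string for both RSS orientations
.scan_rss_fwd <- function(seq, model, orientation) {
  hits <- list()
  spacers <- (model$spacer_class - model$spacer_slack):(model$spacer_class + model$spacer_slack)
  spacers <- spacers[spacers >= 0L]
  if (orientation %in% c("downstream_of_coding", "both")) {
    h <- hamming_scan(seq, model$heptamer, model$heptamer_max_mm)
    n9 <- hamming_scan(seq, model$nonamer, model$nonamer_max_mm)
    if (nrow(h) && nrow(n9)) {
      npos <- stats::setNames(n9$mismatches, n9$pos)
      for (s in spacers) {
        want <- h$pos + 7L + s
        m <- match(as.character(want), names(npos))
        ok <- which(!is.na(m))
        for (k in ok) {
          hits[[length(hits) + 1L]] <- data.frame(
            orientation = "downstream_of_coding",
            hept_start = h$pos[k], hept_end = h$pos[k] + 7L,
            nona_start = want[k], nona_end = want[k] + 9L,
            spacer_len = s,
            hept_mm = h$mismatches[k], nona_mm = unname(npos[m[k]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (orientation %in% c("upstream_of_coding", "both")) {
    rc_n <- revcomp(model$nonamer)
    rc_h <- revcomp(model$heptamer)
    n9 <- hamming_scan(seq, rc_n, model$nonamer_max_mm)
    h <- hamming_scan(seq, rc_h, model$heptamer_max_mm)
    if (nrow(h) && nrow(n9)) {
      hpos <- stats::setNames(h$mismatches, h$pos)
      for (s in spacers) {
        want <- n9$pos + 9L + s
        m <- match(as.character(want), names(hpos))
        ok <- which(!is.na(m))
        for (k in ok) {
          hits[[length(hits) + 1L]] <- data.frame(
            orientation = "upstream_of_coding",
            hept_start = want[k], hept_end = want[k] + 7L,
            nona_start = n9$pos[k], nona_end = n9$pos[k] + 9L,
            spacer_len = s,
            hept_mm = unname(hpos[m[k]]), nona_mm = n9$mismatches[k],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Scan a sequence for RSS hits
#'
#' Exhaustive over positions, spacer lengths within slack, orientations and
#' requested strands. Overlapping hits are all reported; callers tie-break.
#' Minus-strand hits are found by scanning the reverse complement and carry
#' forward-sequence coordinates; their orientation is relative to the
#' minus-strand coding direction.
#'
#' @param seq sequence (character scalar).
#' @param model an [rss_model()].
#' @param strand "+", "-" or "both".
#' @param orientation "downstream_of_coding", "upstream_of_coding" or "both".
#' @param seq_id id recorded in the output.
#' @return data.frame of hits sorted by heptamer start.
#' @export
scan_rss <- function(seq, model = rss_model(), strand = "both",
                     orientation = "both", seq_id = "seq") {
  stopifnot(inherits(model, "rss_model"),
            strand %in% c("+", "-", "both"),
            orientation %in% c("downstream_of_coding", "upstream_of_coding", "both"))
  seq <- normalize_residues(seq, seq_id)
  n <- nchar(seq)
  out <- list()
  if (strand %in% c("+", "both")) {
    f <- .scan_rss_fwd(seq, model, orientation)
    if (!is.null(f)) { f$strand <- "+"; out[[length(out) + 1L]] <- f }
  }
  if (strand %in% c("-", "both") && n > 0L) {
    r <- .scan_rss_fwd(revcomp(seq), model, orientation)
    if (!is.null(r)) {
      # map [s,e) on the reverse complement to forward coordinates [n-e, n-s)
      hs <- r$hept_start; he <- r$hept_end
      ns <- r$nona_start; ne <- r$nona_end
      r$hept_start <- n - he; r$hept_end <- n - hs
      r$nona_start <- n - ne; r$nona_end <- n - ns
      r$strand <- "-"
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out)) return(.empty_rss_hits())
  res <- do.call(rbind, out)
  res$total_mm <- res$hept_mm + res$nona_mm
  res$seq_id <- seq_id
  res <- res[order(res$hept_start, res$nona_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res[, names(.empty_rss_hits())]
}
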