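# VH / D / JH gene-segment calling from germline sequence.
#
# Calling criteria:
#   VH: AG splice acceptor immediately 5' of a stop-free open reading frame
#       of plausible exon length, with a 23-spacer RSS (heptamer
#       coding-proximal) starting within a few nt of the exon 3' end.
#   D:  a short segment flanked by 12-spacer RSSs on both sides (the 12/23
#       rule places the 12s on D).
#   JH: windowed-identity homology to reference JH sequences (window 30,
#       60% match), 5' boundary immediately after the heptamer of the
#       nearest upstream 23-RSS, 3' boundary immediately before the first
#       "GTA" (the GT being the splice donor).

.STOPS <- c("TAA", "TAG", "TGA")

#' Stop-codon positions within a frame
#'
#' @param seq sequence.
#' @param frame 0, 1 or 2 (offset of the first complete codon).
#' @param from,to 0-based half-open region restricting the codons considered
#'   (codons fully inside the region only).
#' @return integer vector of 0-based stop-codon start positions.
#' @export
stop_positions <- function(seq, frame = 0L, from = 0L, to = nchar(seq)) {
  if ((from + frame) > (to - 3L)) return(integer(0))
  starts <- seq.int(from + frame, to - 3L, by = 3L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  starts[codons %in% .STOPS]
}

.is_stop_free <- function(seq, from, to, frame) {
  length(stop_positions(seq, frame, from, to)) == 0L
}

.empty_segment_calls <- function() {
  data.frame(kind = character(0), seq_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             label = character(0), evidence = numeric(0),
             orf_frame = integer(0), boundary_uncertain = logical(0),
             stringsAsFactors = FALSE)
}

# greedy overlap resolution: keep candidates in priority order, drop any
# candidate overlapping an already-kept one
.resolve_overlaps <- function(df) {
  if (nrow(df) <= 1L) return(df)
  kept <- logical(nrow(df))
  ends <- df$end; starts <- df$start
  for (k in seq_len(nrow(df))) {
    ov <- kept & starts < ends[k] & ends > starts[k]
    if (!any(ov)) kept[k] <- TRUE
  }
  df[kept, , drop = FALSE]
}

.call_vh_fwd <- function(seq, model, orf_min, orf_max, rss_gap_max) {
  hits <- scan_rss(seq, model, strand = "+",
                   orientation = "downstream_of_coding")
  if (nrow(hits) == 0L) return(NULL)
  cand <- list()
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    for (g in 0:rss_gap_max) {
      e <- h$hept_start - g
      lo <- e - orf_max; hi <- e - orf_min
      if (hi < 2L) next
      lo <- max(lo, 2L)
      ss <- lo:hi
      ag <- ss[substring(seq, ss - 1L, ss) == "AG"]  # AG at [s-2, s)
      for (s in ag) {
        fr <- NA_integer_
        for (f in 0:2) {
          if (.is_stop_free(seq, s, e, f)) { fr <- f; break }
        }
        if (is.na(fr)) next
        cand[[length(cand) + 1L]] <- data.frame(
          start = s, end = e, evidence = h$total_mm, orf_frame = fr,
          rss_gap = g, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(NULL)
  do.call(rbind, cand)
}

#' Call VH gene segments
#'
#' A VH exon is a stop-free open reading frame of length within
#' `[orf_min, orf_max]`, with the splice-acceptor dinucleotide AG
#' immediately 5' of its start and a 23-spacer RSS whose heptamer begins
#' within `[0, rss_gap_max]` nt of its 3' end. Overlapping candidates are
#' resolved by lowest total RSS mismatch count, then leftmost start, then
#' longest exon. Zero calls is a valid outcome.
#'
#' @param seq germline sequence.
#' @param model an [rss_model()] with spacer class 23.
#' @param orf_min,orf_max exon length bounds in nt.
#' @param rss_gap_max largest exon-end-to-heptamer gap in nt.
#' @param strand "+" (default: VH arrays of translocon loci lie in forward
#'   orientation), "-" or "both".
#' @param seq_id id recorded in the output.
#' @return data.frame of calls (see [.empty_segment_calls] layout).
#' @export
call_vh <- function(seq, model = rss_model(spacer_class = 23L),
                    orf_min = 240L, orf_max = 360L, rss_gap_max = 10L,
                    strand = "+", seq_id = "seq") {
  stopifnot(model$spacer_class == 23L, strand %in% c("+", "-", "both"))
  seq <- normalize_residues(seq, seq_id)
  n <- nchar(seq)
  cand <- list()
  if (strand %in% c("+", "both")) {
    f <- .call_vh_fwd(seq, model, orf_min, orf_max, rss_gap_max)
    if (!is.null(f)) { f$strand <- "+"; cand[[length(cand) + 1L]] <- f }
  }
  if (strand %in% c("-", "both")) {
    r <- .call_vh_fwd(revcomp(seq), model, orf_min, orf_max, rss_gap_max)
    if (!is.null(r)) {
      s <- r$start; e <- r$end
      r$start <- n - e; r$end <- n - s
      r$strand <- "-"
      cand[[length(cand) + 1L]] <- r
    }
  }
  if (!length(cand)) return(.empty_segment_calls())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$evidence, cand$start, -(cand$end - cand$start)), ,
               drop = FALSE]
  cand <- .resolve_overlaps(cand)
  cand <- cand[order(cand$start), , drop = FALSE]
  out <- data.frame(kind = "VH", seq_id = seq_id,
                    start = cand$start, end = cand$end, strand = cand$strand,
                    label = sprintf("VH%02d", seq_len(nrow(cand))),
                    evidence = cand$evidence, orf_frame = cand$orf_frame,
                    boundary_uncertain = FALSE, stringsAsFactors = FALSE)
  .audit_calls(seq, out, model)
  out
}

.call_d_fwd <- function(seq, model, d_min, d_max) {
  up <- scan_rss(seq, model, strand = "+", orientation = "upstream_of_coding")
  dn <- scan_rss(seq, model, strand = "+", orientation = "downstream_of_coding")
  if (nrow(up) == 0L || nrow(dn) == 0L) return(NULL)
  cand <- list()
  for (k in seq_len(nrow(up))) {
    s <- up$hept_end[k]
    ok <- which(dn$hept_start - s >= d_min & dn$hept_start - s <= d_max)
    for (j in ok) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = s, end = dn$hept_start[j],
        evidence = up$total_mm[k] + dn$total_mm[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(NULL)
  do.call(rbind, cand)
}

#' Call D gene segments
#'
#' A D segment is an interval of length within `[d_min, d_max]` flanked by
#' an upstream RSS (nonamer-spacer-heptamer reading toward the segment) and
#' a downstream RSS (heptamer-spacer-nonamer reading away), both of the
#' model's spacer class (default 12 on both sides). Both strands are
#' scanned; because the flanking-RSS arrangement is strand-symmetric, calls
#' found on both strands at the same interval are reported once, on "+".
#'
#' @param seq germline sequence.
#' @param model an [rss_model()]; default spacer class 12.
#' @param d_min,d_max segment length bounds in nt.
#' @param strand "+", "-" or "both".
#' @param seq_id id recorded in the output.
#' @return data.frame of calls.
#' @export
call_d <- function(seq, model = rss_model(spacer_class = 12L),
                   d_min = 5L, d_max = 40L, strand = "both", seq_id = "seq") {
  stopifnot(strand %in% c("+", "-", "both"))
  seq <- normalize_residues(seq, seq_id)
  n <- nchar(seq)
  cand <- list()
  if (strand %in% c("+", "both")) {
    f <- .call_d_fwd(seq, model, d_min, d_max)
    if (!is.null(f)) { f$strand <- "+"; cand[[length(cand) + 1L]] <- f }
  }
  if (strand %in% c("-", "both")) {
    r <- .call_d_fwd(revcomp(seq), model, d_min, d_max)
    if (!is.null(r)) {
      s <- r$start; e <- r$end
      r$start <- n - e; r$end <- n - s
      r$strand <- "-"
      cand[[length(cand) + 1L]] <- r
    }
  }
  if (!length(cand)) return(.empty_segment_calls())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, cand$end, cand$strand), , drop = FALSE]
  dupe <- duplicated(cand[, c("start", "end")])
  cand <- cand[!dupe, , drop = FALSE]
  out <- data.frame(kind = "D", seq_id = seq_id,
                    start = cand$start, end = cand$end, strand = cand$strand,
                    label = sprintf("D%02d", seq_len(nrow(cand))),
                    evidence = cand$evidence, orf_frame = NA_integer_,
                    boundary_uncertain = FALSE, stringsAsFactors = FALSE)
  .audit_calls(seq, out, model)
  out
}

.call_jh_fwd <- function(seq, jh_refs, model, window, min_identity,
                         rss_search, gta_max) {
  params <- dot_params(window, min_identity)
  loci <- list()
  for (rn in names(jh_refs)) {
    ref <- jh_refs[[rn]]
    if (nchar(ref) < window) next
    cells <- suppressWarnings(dot_matches(seq, ref, params))
    if (nrow(cells) == 0L) next
    runs <- merge_diagonals(cells, window)
    for (k in seq_len(nrow(runs))) {
      # extend the seed run to the full reference span along its diagonal
      # and require the whole-reference identity to clear the threshold
      g0 <- runs$a_start[k] - runs$b_start[k]
      idn <- .diag_identity_cpp(seq, ref, g0, 0L, nchar(ref))
      if (idn[2L] == 0L || idn[1L] / idn[2L] < min_identity) next
      loci[[length(loci) + 1L]] <- c(max(0L, g0),
                                     min(nchar(seq), g0 + nchar(ref)))
    }
  }
  if (!length(loci)) return(NULL)
  spans <- unique(do.call(rbind, loci))
  spans <- spans[order(spans[, 1L], spans[, 2L]), , drop = FALSE]
  # merge overlapping candidate spans across references
  merged <- list(spans[1L, ])
  for (k in seq_len(nrow(spans))[-1L]) {
    last <- merged[[length(merged)]]
    if (spans[k, 1L] <= last[2L]) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], spans[k, 2L]))
    } else merged[[length(merged) + 1L]] <- spans[k, ]
  }
  rss <- scan_rss(seq, model, strand = "+", orientation = "upstream_of_coding")
  calls <- list()
  for (sp in merged) {
    s0 <- sp[1L]; e0 <- sp[2L]
    uncertain <- FALSE
    ev <- NA_real_
    # 5' boundary: immediately after the heptamer of the nearest upstream RSS
    near <- rss[rss$hept_end >= s0 - rss_search & rss$hept_end <= s0 + 5L, ,
                drop = FALSE]
    if (nrow(near)) {
      near <- near[order(abs(near$hept_end - s0), near$total_mm), , drop = FALSE]
      start <- near$hept_end[1L]
      ev <- near$total_mm[1L]
    } else { start <- s0; uncertain <- TRUE }
    # 3' boundary: immediately before the first GTA at/after the run end
    gta <- integer(0)
    limit <- min(nchar(seq) - 3L, e0 + gta_max)
    if (e0 <= limit) {
      ps <- e0:limit
      gta <- ps[substring(seq, ps + 1L, ps + 3L) == "GTA"]
    }
    if (length(gta)) end <- gta[1L] else { end <- e0; uncertain <- TRUE }
    if (end <= start) { start <- s0; end <- e0; uncertain <- TRUE }
    calls[[length(calls) + 1L]] <- data.frame(
      start = start, end = end, evidence = ev, boundary_uncertain = uncertain,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, calls)
}

#' Call JH gene segments by homology to reference JH sequences
#'
#' Candidate loci are windowed-identity diagonal runs against any reference
#' (window 30, identity >= 0.60 by default), verified over the full
#' reference length along the diagonal. The 5' boundary is placed
#' immediately after the heptamer of the nearest upstream 23-RSS within
#' `rss_search` nt; the 3' boundary immediately before the first "GTA" at or
#' after the homology run end within `gta_max` nt. Candidates lacking either
#' anchor are emitted with `boundary_uncertain = TRUE` rather than dropped.
#'
#' @param seq germline sequence.
#' @param jh_refs named character vector of reference JH sequences.
#' @param model an [rss_model()] for the 5' RSS (default spacer class 23).
#' @param window,min_identity dot-plot parameters (defaults 30 nt, 0.60).
#' @param rss_search 5' RSS search distance in nt.
#' @param gta_max 3' GTA search distance in nt.
#' @param strand "+", "-" or "both".
#' @param seq_id id recorded in the output.
#' @return data.frame of calls.
#' @export
call_jh <- function(seq, jh_refs, model = rss_model(spacer_class = 23L),
                    window = 30L, min_identity = 0.60, rss_search = 60L,
                    gta_max = 30L, strand = "both", seq_id = "seq") {
  if (length(jh_refs) == 0L) stop("call_jh: no reference JH sequences")
  stopifnot(strand %in% c("+", "-", "both"))
  seq <- normalize_residues(seq, seq_id)
  if (is.null(names(jh_refs))) names(jh_refs) <- sprintf("JHref%d", seq_along(jh_refs))
  n <- nchar(seq)
  cand <- list()
  if (strand %in% c("+", "both")) {
    f <- .call_jh_fwd(seq, jh_refs, model, window, min_identity,
                      rss_search, gta_max)
    if (!is.null(f)) { f$strand <- "+"; cand[[length(cand) + 1L]] <- f }
  }
  if (strand %in% c("-", "both")) {
    r <- .call_jh_fwd(revcomp(seq), jh_refs, model, window, min_identity,
                      rss_search, gta_max)
    if (!is.null(r)) {
      s <- r$start; e <- r$end
      r$start <- n - e; r$end <- n - s
      r$strand <- "-"
      cand[[length(cand) + 1L]] <- r
    }
  }
  if (!length(cand)) return(.empty_segment_calls())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, cand$end, cand$strand), , drop = FALSE]
  cand <- cand[!duplicated(cand[, c("start", "end")]), , drop = FALSE]
  # one call per locus: overlapping calls (e.g. a quasi-palindromic
  # reference matching both orientations) resolve to the anchored one,
  # then fewest RSS mismatches, then leftmost
  cand <- cand[order(cand$boundary_uncertain,
                     ifelse(is.na(cand$evidence), 99, cand$evidence),
                     cand$start), , drop = FALSE]
  cand <- .resolve_overlaps(cand)
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  out <- data.frame(kind = "JH", seq_id = seq_id,
                    start = cand$start, end = cand$end, strand = cand$strand,
                    label = sprintf("JH%02d", seq_len(nrow(cand))),
                    evidence = cand$evidence, orf_frame = NA_integer_,
                    boundary_uncertain = cand$boundary_uncertain,
                    stringsAsFactors = FALSE)
  out
}

# self-audit: every emitted call's stated evidence must re-verify by direct
# string inspection; a violation is a defect, not a data problem.
.audit_calls <- function(seq, calls, model) {
  for (k in seq_len(nrow(calls))) {
    cl <- calls[k, ]
    txt <- if (cl$strand == "-") revcomp(seq) else seq
    n <- nchar(seq)
    s <- if (cl$strand == "-") n - cl$end else cl$start
    e <- if (cl$strand == "-") n - cl$start else cl$end
    if (cl$kind == "VH") {
      if (substring(txt, s - 1L, s) != "AG") {
        stop("audit: VH call without AG acceptor at ", cl$start)
      }
      if (!.is_stop_free(txt, s, e, cl$orf_frame)) {
        stop("audit: VH call with in-frame stop at ", cl$start)
      }
      down <- substring(txt, e + 1L, min(nchar(txt), e + 60L))
      h <- .scan_rss_fwd(down, model, "downstream_of_coding")
      if (is.null(h)) stop("audit: VH call without downstream 23-RSS at ", cl$start)
    } else if (cl$kind == "D") {
      up <- substring(txt, max(1L, s - 40L), s)
      dn <- substring(txt, e + 1L, min(nchar(txt), e + 40L))
      hu <- .scan_rss_fwd(up, model, "upstream_of_coding")
      hd <- .scan_rss_fwd(dn, model, "downstream_of_coding")
      ok <- !is.null(hu) && any(hu$hept_end == nchar(up)) &&
        !is.null(hd) && any(hd$hept_start == 0L)
      if (!ok) stop("audit: D call without flanking 12-RSS pair at ", cl$start)
    }
  }
  invisible(TRUE)
}
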