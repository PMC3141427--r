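# Transcript (EST) analysis: exon chaining onto the annotated locus,
# zone-of-origin voting through diagnostic nucleotides, isoform
# classification, ORF/stop analysis, protein features, and in-silico PCR.

ISOFORM_CLASSES <- c("IGM_SEC", "IGM_TM_SHORT", "IGD_TM_CHIMERIC",
                     "STERILE", "UNCLASSIFIED")

#' Build an exon catalog from annotations and the genomic sequence
#'
#' One row per exon copy: label, zone, genomic interval, and the oriented
#' (5'->3') sequence extracted from the genome.
#'
#' @param annotations exon annotation data.frame (with `zone_id` filled).
#' @param genome forward-strand genomic sequence.
#' @return data.frame with `label`, `zone_id`, `start`, `end`, `strand`, `seq`.
#' @export
exon_catalog <- function(annotations, genome) {
  ex <- if (is.null(annotations$type)) annotations else
    annotations[annotations$type == "exon", , drop = FALSE]
  data.frame(label = ex$label, zone_id = ex$zone_id,
             start = ex$start, end = ex$end, strand = ex$strand,
             seq = vapply(seq_len(nrow(ex)), function(k) {
               extract_interval(genome, ex$start[k], ex$end[k], ex$strand[k])
             }, ""),
             stringsAsFactors = FALSE)
}

# all placements of `pattern` in `subject` with at most max_mm substitutions
.approx_find <- function(pattern, subject, max_mm) {
  if (nchar(pattern) > nchar(subject)) {
    return(data.frame(start = integer(0), mm = integer(0)))
  }
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = max_mm, with.indels = FALSE)
  if (length(m) == 0L) return(data.frame(start = integer(0), mm = integer(0)))
  st <- Biostrings::start(m) - 1L
  mm <- vapply(seq_along(m), function(k) {
    hamming(as.character(m[[k]]), pattern)
  }, integer(1))
  data.frame(start = st, mm = mm)
}

#' Chain catalog exons onto a transcript
#'
#' Finds, for every exon copy, its approximate placements in the EST
#' (substitution-only, per-link identity >= `min_identity`), then selects
#' the colinear non-overlapping chain maximizing total matched bases by
#' dynamic programming. An unmatched EST prefix of >= 50 nt preceding the
#' first CH exon is tested for VH content: any stop-free open reading frame
#' of >= `vh_orf_min` nt ending within `vh_end_slack` nt of the prefix end
#' sets `has_vh`. `uses_exon0` is TRUE when the chain contains an EX0 link.
#'
#' @param est transcript sequence.
#' @param catalog data.frame from [exon_catalog()].
#' @param min_identity per-link identity threshold (default 0.90).
#' @param vh_orf_min minimum VH open-reading-frame length in nt.
#' @param vh_end_slack how close to the junction the VH ORF must end.
#' @return list with `chain` (data.frame label, zone_id, est_start, est_end,
#'   mm, identity), `has_vh`, `uses_exon0`, `prefix_len`.
#' @export
chain_exons <- function(est, catalog, min_identity = 0.90,
                        vh_orf_min = 150L, vh_end_slack = 90L) {
  est <- normalize_residues(est, "est")
  cand <- list()
  for (k in seq_len(nrow(catalog))) {
    L <- nchar(catalog$seq[k])
    hits <- .approx_find(catalog$seq[k], est, floor((1 - min_identity) * L))
    for (h in seq_len(nrow(hits))) {
      cand[[length(cand) + 1L]] <- data.frame(
        label = catalog$label[k], zone_id = catalog$zone_id[k],
        est_start = hits$start[h], est_end = hits$start[h] + L,
        mm = hits$mm[h], identity = 1 - hits$mm[h] / L,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(label = character(0), zone_id = integer(0),
                      est_start = integer(0), est_end = integer(0),
                      mm = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(cand)) {
    return(list(chain = empty, has_vh = FALSE, uses_exon0 = FALSE,
                prefix_len = nchar(est)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$est_end, cand$est_start, -cand$identity,
                     cand$zone_id), , drop = FALSE]
  # weighted interval scheduling on matched bases
  score <- (cand$est_end - cand$est_start) - cand$mm
  n <- nrow(cand)
  best <- numeric(n); takes <- vector("list", n)
  for (k in seq_len(n)) {
    prev <- which(cand$est_end[seq_len(k - 1L)] <= cand$est_start[k])
    base <- if (length(prev)) max(best[prev]) else 0
    from <- if (length(prev)) prev[which.max(best[prev])] else 0L
    best[k] <- base + score[k]
    takes[[k]] <- if (from > 0L) c(takes[[from]], k) else k
  }
  sel <- takes[[which.max(best)]]
  chain <- cand[sel, , drop = FALSE]
  chain <- chain[order(chain$est_start), , drop = FALSE]
  rownames(chain) <- NULL
  uses_exon0 <- any(chain$label == "EX0")
  first_ch <- which(chain$label != "EX0")
  prefix_end <- if (length(first_ch)) chain$est_start[first_ch[1L]] else nchar(est)
  has_vh <- FALSE
  if (prefix_end >= 50L) {
    for (f in 0:2) {
      stops <- stop_positions(est, f, 0L, prefix_end)
      bounds <- c(f, stops + 3L, prefix_end)
      starts <- bounds[-length(bounds)]
      ends <- c(stops, prefix_end)
      runs <- ends - starts
      ok <- runs >= vh_orf_min & (prefix_end - ends) <= vh_end_slack
      if (any(ok)) { has_vh <- TRUE; break }
    }
  }
  list(chain = chain, has_vh = has_vh, uses_exon0 = uses_exon0,
       prefix_len = prefix_end)
}

#' Assign a transcript to its zone of origin by diagnostic nucleotides
#'
#' For every chained exon, mismatches of the transcript segment to each
#' zone's copy of that exon are summed per zone; the zone with the fewest
#' total mismatches wins iff it beats the runner-up by at least one site
#' (a diagnostic site). Otherwise the vote is "ambiguous".
#'
#' @param est transcript sequence.
#' @param chain chain data.frame from [chain_exons()].
#' @param catalog exon catalog.
#' @return list with `zone` (zone id as integer, or the string "ambiguous"),
#'   `margin` (the diagnostic-site count), and `per_zone_mm`.
#' @export
assign_zone <- function(est, chain, catalog) {
  chain <- chain[!is.na(chain$zone_id), , drop = FALSE]
  if (nrow(chain) == 0L) {
    return(list(zone = "ambiguous", margin = 0L, per_zone_mm = integer(0)))
  }
  totals <- integer(0)
  for (k in seq_len(nrow(chain))) {
    lab <- chain$label[k]
    copies <- catalog[catalog$label == lab & !is.na(catalog$zone_id), ,
                      drop = FALSE]
    if (length(unique(copies$zone_id)) < 2L) next
    seg <- substr(est, chain$est_start[k] + 1L, chain$est_end[k])
    for (j in seq_len(nrow(copies))) {
      if (nchar(copies$seq[j]) != nchar(seg)) next
      z <- as.character(copies$zone_id[j])
      mmz <- hamming(seg, copies$seq[j])
      totals[z] <- (if (z %in% names(totals)) totals[[z]] else 0L) + mmz
    }
  }
  if (length(totals) < 2L) {
    return(list(zone = "ambiguous", margin = 0L, per_zone_mm = totals))
  }
  o <- order(totals)
  margin <- totals[o[2L]] - totals[o[1L]]
  if (margin < 1L) {
    return(list(zone = "ambiguous", margin = 0L, per_zone_mm = totals))
  }
  list(zone = as.integer(names(totals)[o[1L]]), margin = as.integer(margin),
       per_zone_mm = totals)
}

#' Per-frame stop-codon analysis of a transcript
#'
#' Stops are TAA/TAG/TGA on the forward strand. `stops_all_frames` is TRUE
#' iff each of the three frames contains at least one stop before `limit`
#' (conventionally the start of the last chained exon).
#'
#' @param est transcript sequence.
#' @param limit 0-based position bounding the region inspected.
#' @return list with `stops` (list of 3 integer vectors, frames 0..2) and
#'   `stops_all_frames`.
#' @export
orf_stop_analysis <- function(est, limit = nchar(est)) {
  est <- normalize_residues(est, "est")
  stops <- lapply(0:2, function(f) stop_positions(est, f, 0L, nchar(est)))
  before <- vapply(stops, function(s) any(s < limit), logical(1))
  list(stops = stops, stops_all_frames = all(before))
}

#' Classify a transcript's isoform
#'
#' Rules applied in order: (1) STERILE when the transcript has no VH
#' content or carries stops in all frames; (2) IGM_TM_SHORT for the chain
#' core Cmu1,Cmu2,TM1,TM2 (the short transmembrane IgM splices Cmu2 to
#' TM1); (3) IGM_SEC for Cmu1..Cmu4 (optionally + SEC_TAIL) with no TM
#' exon; (4) IGD_TM_CHIMERIC for a chain starting with Cmu1 followed by at
#' least one Cdelta exon and ending TM1,TM2 (no Cdelta5 required);
#' (5) UNCLASSIFIED otherwise. An empty chain is UNCLASSIFIED.
#'
#' @param chain chain data.frame.
#' @param has_vh,stops_all_frames flags from [chain_exons()] /
#'   [orf_stop_analysis()].
#' @return one of `ISOFORM_CLASSES`.
#' @export
classify_isoform <- function(chain, has_vh, stops_all_frames) {
  if (nrow(chain) == 0L) return("UNCLASSIFIED")
  core <- chain$label[chain$label != "EX0"]
  if (!has_vh || stops_all_frames) return("STERILE")
  if (identical(core, c("Cmu1", "Cmu2", "TM1", "TM2"))) return("IGM_TM_SHORT")
  sec <- core[core != "SEC_TAIL"]
  if (identical(sec, paste0("Cmu", 1:4)) && !any(grepl("^TM", core))) {
    return("IGM_SEC")
  }
  nlab <- length(core)
  if (nlab >= 4L && core[1L] == "Cmu1" &&
      any(grepl("^Cdelta", core)) &&
      identical(core[(nlab - 1L):nlab], c("TM1", "TM2")) &&
      all(grepl("^Cdelta", core[2:(nlab - 2L)]))) {
    return("IGD_TM_CHIMERIC")
  }
  "UNCLASSIFIED"
}

#' Classify a set of transcripts against an annotated locus
#'
#' Runs [chain_exons()], [assign_zone()], [orf_stop_analysis()] and
#' [classify_isoform()] per transcript.
#'
#' @param ests named character vector of transcripts.
#' @param catalog exon catalog from [exon_catalog()].
#' @param min_identity per-link identity threshold.
#' @return data.frame: est_id, isoform, zone, n_diagnostic_sites, has_vh,
#'   uses_exon0, stops_all_frames, chain (comma-separated labels).
#' @export
classify_transcripts <- function(ests, catalog, min_identity = 0.90) {
  rows <- lapply(names(ests), function(id) {
    est <- ests[[id]]
    ch <- chain_exons(est, catalog, min_identity)
    limit <- if (nrow(ch$chain)) ch$chain$est_start[nrow(ch$chain)] else nchar(est)
    orf <- orf_stop_analysis(est, limit)
    iso <- classify_isoform(ch$chain, ch$has_vh, orf$stops_all_frames)
    zv <- assign_zone(est, ch$chain, catalog)
    data.frame(est_id = id, isoform = iso,
               zone = as.character(zv$zone), n_diagnostic_sites = zv$margin,
               has_vh = ch$has_vh, uses_exon0 = ch$uses_exon0,
               stops_all_frames = orf$stops_all_frames,
               chain = paste(ch$chain$label, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cysteine and N-glycosylation features of a protein sequence
#'
#' Reports all cysteine positions and all N-X-S/T sequons with X != P
#' (0-based amino-acid coordinates).
#'
#' @param aa_seq amino-acid string (standard alphabet plus `*`).
#' @return list with `cys_positions` and `nglyc_sites`.
#' @export
protein_features <- function(aa_seq) {
  aa_seq <- toupper(aa_seq)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY*X]", aa_seq)) {
    stop("protein_features: invalid amino-acid residue")
  }
  ch <- strsplit(aa_seq, "")[[1L]]
  cys <- which(ch == "C") - 1L
  n <- length(ch)
  ng <- integer(0)
  if (n >= 3L) {
    i <- seq_len(n - 2L)
    hit <- ch[i] == "N" & ch[i + 1L] != "P" & ch[i + 2L] %in% c("S", "T")
    ng <- i[hit] - 1L
  }
  list(cys_positions = cys, nglyc_sites = ng)
}

#' Translate a transcript region
#'
#' Standard genetic code, forward strand.
#'
#' @param est transcript sequence.
#' @param from 0-based start of the coding region.
#' @param frame frame offset relative to `from`.
#' @return amino-acid string (stops as `*`).
#' @export
translate_region <- function(est, from = 0L, frame = 0L) {
  s <- substr(est, from + frame + 1L, nchar(est))
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  if (nchar(s) == 0L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(s),
                          if.fuzzy.codon = "solve")))
}

#' Predict PCR amplicons on a template
#'
#' Finds every product where the forward primer matches the template and
#' the reverse primer matches the reverse complement downstream (i.e. the
#' reverse complement of the reverse primer matches the forward template at
#' or after the forward primer's 3' end), each with at most `max_mm`
#' mismatches. Product length runs from the forward primer's 5' end to the
#' reverse primer's 5' end inclusive.
#'
#' @param template template sequence.
#' @param fwd_primer,rev_primer primer sequences (5'->3').
#' @param max_mm per-primer mismatch tolerance.
#' @return data.frame with `start`, `end` (0-based half-open product
#'   interval on the template) and `length`.
#' @export
predict_amplicon <- function(template, fwd_primer, rev_primer, max_mm = 0L) {
  template <- normalize_residues(template, "template")
  fwd <- normalize_residues(fwd_primer, "fwd_primer")
  rev <- normalize_residues(rev_primer, "rev_primer")
  fh <- hamming_scan(template, fwd, max_mm)
  rh <- hamming_scan(template, revcomp(rev), max_mm)
  out <- list()
  for (i in seq_len(nrow(fh))) {
    s <- fh$pos[i]
    ok <- which(rh$pos >= s + nchar(fwd))
    for (j in ok) {
      e <- rh$pos[j] + nchar(rev)
      out[[length(out) + 1L]] <- data.frame(start = s, end = e,
                                            length = e - s)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}
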