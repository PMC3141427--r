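# Reference-guided CH exon mapping, orthology naming, and zone partitioning.

#' Fixed CH exon label vocabulary
#'
#' Cmu1-Cmu4 (IgM constant domains; Cmu4 carries the secretory tail),
#' Cdelta1-Cdelta7 (IgD), TM1/TM2 (transmembrane + cytoplasmic), SEC_TAIL
#' (stand-alone secretory tail reference), EX0 (the ~100-bp non-coding exon
#' 3' of the JH cluster).
#'
#' @export
CH_LABELS <- c(paste0("Cmu", 1:4), paste0("Cdelta", 1:7),
               "TM1", "TM2", "SEC_TAIL", "EX0")

.empty_exon_annotations <- function() {
  data.frame(seq_id = character(0), label = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             identity = numeric(0), splice_ok = logical(0),
             zone_id = integer(0), stringsAsFactors = FALSE)
}

# snap a boundary to the nearest position carrying a 2-nt context within
# +/- snap_max; ties prefer the smaller shift, then the leftmost position
.snap <- function(seq, pos, context, side, snap_max) {
  n <- nchar(seq)
  cand <- (pos - snap_max):(pos + snap_max)
  if (side == "before") {          # context occupies [p-2, p)
    cand <- cand[cand >= 2L & cand <= n]
    hit <- cand[substring(seq, cand - 1L, cand) == context]
  } else {                         # context occupies [p, p+2)
    cand <- cand[cand >= 0L & cand <= n - 2L]
    hit <- cand[substring(seq, cand + 1L, cand + 2L) == context]
  }
  if (!length(hit)) return(list(pos = pos, ok = FALSE))
  hit <- hit[order(abs(hit - pos), hit)]
  list(pos = hit[1L], ok = TRUE)
}

.map_exons_one <- function(seq, ref, label, params, min_identity, snap_max,
                           orientation) {
  cells <- suppressWarnings(dot_matches(seq, ref, params,
                                        orientation = orientation))
  if (nrow(cells) == 0L) return(NULL)
  runs <- merge_diagonals(cells, params$window)
  Lr <- nchar(ref); n <- nchar(seq)
  rows <- list()
  seen <- integer(0)
  for (k in seq_len(nrow(runs))) {
    if (orientation == "forward") {
      g0 <- runs$a_start[k] - runs$b_start[k]
      idn <- .diag_identity_cpp(seq, ref, g0, 0L, Lr)
    } else {
      # reverse orientation: the reference's rc lies on the forward genome;
      # the run's b_start is the forward-b offset of its right-most ref base
      rcref <- revcomp(ref)
      b_rc_start <- Lr - (runs$b_start[k] + runs$length[k])
      g0 <- runs$a_start[k] - b_rc_start
      idn <- .diag_identity_cpp(seq, rcref, g0, 0L, Lr)
    }
    if (idn[2L] < params$window || idn[1L] / idn[2L] < min_identity) next
    if (any(abs(seen - g0) < Lr %/% 2L)) next   # same locus, lesser run
    seen <- c(seen, g0)
    s <- max(0L, g0); e <- min(n, g0 + Lr)
    if (orientation == "forward") {
      a <- .snap(seq, s, "AG", "before", snap_max)
      d <- .snap(seq, e, "GT", "after", snap_max)
    } else {
      # minus-strand exon: acceptor/donor read on the minus strand appear
      # on the forward strand as AC before the start and CT after the end
      a <- .snap(seq, s, "AC", "before", snap_max)
      d <- .snap(seq, e, "CT", "after", snap_max)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = label, start = a$pos, end = d$pos,
      strand = if (orientation == "forward") "+" else "-",
      identity = idn[1L] / idn[2L], splice_ok = a$ok && d$ok,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Map CH exons onto a germline sequence by reference homology
#'
#' For each labeled reference exon, candidate loci are seeded by
#' windowed-identity dot-plot cells (window 30, 60% match), verified by the
#' ungapped identity over the full reference length along the seed diagonal
#' (threshold `min_identity`, default 0.70), and boundary-snapped to the
#' nearest splice contexts (AG before the start, GT after the end; the
#' minus-strand equivalents for inverted copies) within `snap_max` nt.
#' Multiple copies of the same label are all reported.
#'
#' @param seq germline sequence.
#' @param refs named character vector of reference exon sequences; names are
#'   labels from [CH_LABELS] (a trailing `.tag` is allowed and stripped, so
#'   several references per label can be supplied).
#' @param min_identity full-length identity threshold.
#' @param seed_params dot-plot seeding parameters.
#' @param snap_max boundary snap radius in nt.
#' @param seq_id id recorded in the output.
#' @return data.frame of exon annotations.
#' @export
map_ch_exons <- function(seq, refs, min_identity = 0.70,
                         seed_params = dot_params(30L, 0.60),
                         snap_max = 6L, seq_id = "seq") {
  if (length(refs) == 0L) stop("map_ch_exons: no reference exons")
  seq <- normalize_residues(seq, seq_id)
  out <- list()
  for (rn in names(refs)) {
    label <- sub("\\..*$", "", rn)
    for (ori in c("forward", "reverse")) {
      m <- .map_exons_one(seq, refs[[rn]], label, seed_params, min_identity,
                          snap_max, ori)
      if (!is.null(m)) out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out)) return(.empty_exon_annotations())
  res <- do.call(rbind, out)
  # the same locus may be hit by several references of one label
  res <- res[order(res$label, res$start, -res$identity), , drop = FALSE]
  keep <- !logical(nrow(res))
  for (k in seq_len(nrow(res))[-1L]) {
    prev <- which(keep[seq_len(k - 1L)])
    prev <- prev[res$label[prev] == res$label[k] &
                   res$start[prev] < res$end[k] & res$end[prev] > res$start[k]]
    if (length(prev)) keep[k] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res$seq_id <- seq_id
  res$zone_id <- NA_integer_
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res[, names(.empty_exon_annotations())]
}

#' Name an exon by orthology to labeled references
#'
#' Global (Needleman-Wunsch) alignment against every reference with match
#' +1, mismatch -1, linear gap -2; the best-scoring label wins. The margin
#' is the score gap to the best competing label; a margin of 0 yields the
#' label "ambiguous".
#'
#' @param exon_seq nucleotide sequence of the exon.
#' @param refs named character vector (names = labels, `.tag` suffix allowed).
#' @param match,mismatch,gap scoring parameters.
#' @return list with `label` and `margin`.
#' @export
name_exon_orthology <- function(exon_seq, refs, match = 1, mismatch = -1,
                                gap = -2) {
  if (!nzchar(exon_seq)) stop("name_exon_orthology: empty exon sequence")
  labels <- sub("\\..*$", "", names(refs))
  if (length(unique(labels)) < 2L) stop("need references for >= 2 labels")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  scores <- vapply(refs, function(r) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(exon_seq), Biostrings::DNAString(r),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
  }, numeric(1))
  per_label <- tapply(scores, labels, max)
  o <- order(per_label, decreasing = TRUE)
  best <- per_label[o[1L]]; second <- per_label[o[2L]]
  margin <- as.numeric(best - second)
  if (margin == 0) return(list(label = "ambiguous", margin = 0))
  list(label = names(per_label)[o[1L]], margin = margin)
}

#' Partition annotations into zones
#'
#' Zone boundaries open at any VH call and at any gap larger than
#' `zone_gap_max` between consecutive non-VH annotations. Each maximal
#' VH-free run containing at least one CH exon becomes one zone. A zone is
#' flagged `functional = FALSE` when it carries neither a complete
#' Cmu1..Cmu4 set nor a complete configured Cdelta chain.
#'
#' @param annotations data.frame combining segment calls and exon
#'   annotations; must have `start`, `end`, `type` (or `kind`), `label`.
#' @param zone_gap_max gap threshold in nt.
#' @param cmu_core labels constituting a complete IgM set.
#' @param cdelta_core labels constituting a complete IgD chain.
#' @return list with `zones` (zone_id, start, end, n_d, n_jh, n_exons,
#'   functional) and `annotations` (input with `zone_id` filled for zone
#'   members).
#' @export
partition_zones <- function(annotations, zone_gap_max = 15000L,
                            cmu_core = paste0("Cmu", 1:4),
                            cdelta_core = paste0("Cdelta", c(1:4, 6:7))) {
  ann <- annotations
  if (is.null(ann$type)) {
    ann$type <- c(VH = "V_gene_segment", D = "D_gene_segment",
                  JH = "J_gene_segment")[ann$kind]
    ann$type[is.na(ann$type)] <- "exon"
  }
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  ann$zone_id <- NA_integer_
  is_vh <- ann$type == "V_gene_segment"
  grp <- integer(nrow(ann)); g <- 0L; prev_end <- NULL
  for (k in seq_len(nrow(ann))) {
    if (is_vh[k]) { prev_end <- NULL; grp[k] <- 0L; next }
    if (is.null(prev_end) || ann$start[k] - prev_end > zone_gap_max) g <- g + 1L
    grp[k] <- g
    prev_end <- max(prev_end %||% 0L, ann$end[k])
  }
  zones <- list()
  zid <- 0L
  for (gg in setdiff(unique(grp), 0L)) {
    idx <- which(grp == gg)
    has_ch <- any(ann$type[idx] == "exon")
    if (!has_ch) next
    zid <- zid + 1L
    ann$zone_id[idx] <- zid
    labs <- ann$label[idx][ann$type[idx] == "exon"]
    functional <- all(cmu_core %in% labs) || all(cdelta_core %in% labs)
    zones[[zid]] <- data.frame(
      zone_id = zid, start = min(ann$start[idx]), end = max(ann$end[idx]),
      n_d = sum(ann$type[idx] == "D_gene_segment"),
      n_jh = sum(ann$type[idx] == "J_gene_segment"),
      n_exons = sum(ann$type[idx] == "exon"),
      functional = functional, stringsAsFactors = FALSE)
  }
  zones <- if (length(zones)) do.call(rbind, zones) else
    data.frame(zone_id = integer(0), start = integer(0), end = integer(0),
               n_d = integer(0), n_jh = integer(0), n_exons = integer(0),
               functional = logical(0))
  list(zones = zones, annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
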