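# End-to-end orchestration: annotate a germline sequence, classify
# transcripts against it, and summarize counts per zone and isoform.

#' Annotate a germline IGH sequence
#'
#' Runs RSS-based VH/D calling, homology-based JH calling, reference-guided
#' CH exon mapping (with orthology re-naming), and zone partitioning.
#' Deterministic. A stage failure aborts with the stage name.
#'
#' @param genome named character vector of germline sequences (typically one).
#' @param refs named character vector of labeled reference exons.
#' @param jh_refs named character vector of reference JH sequences.
#' @param params optional list of per-stage parameter overrides:
#'   `vh` (orf_min, orf_max, rss_gap_max, strand), `d` (d_min, d_max),
#'   `jh` (window, min_identity, rss_search, gta_max), `exon`
#'   (min_identity, snap_max), `zones` (zone_gap_max), `rename` (logical:
#'   re-derive exon labels by orthology alignment; default TRUE).
#' @return list with `annotations` (combined, zone ids filled), `zones`,
#'   and per-stage tables `vh`, `d`, `jh`, `exons`.
#' @export
run_annotate <- function(genome, refs, jh_refs, params = list()) {
  if (length(genome) == 0L || all(!nzchar(genome))) {
    stop("seq_io stage: empty genome input")
  }
  if (is.null(names(genome))) names(genome) <- sprintf("seq%d", seq_along(genome))
  p <- function(block, name, default) {
    v <- params[[block]][[name]]
    if (is.null(v)) default else v
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage: ", conditionMessage(e), call. = FALSE)
    })
  }
  all_ann <- list(); all_zones <- list(); vh_all <- list(); d_all <- list()
  jh_all <- list(); ex_all <- list()
  zid_offset <- 0L
  for (sid in names(genome)) {
    seq <- stage("seq_io", normalize_residues(genome[[sid]], sid))
    vh <- stage("call_vh", call_vh(
      seq, orf_min = p("vh", "orf_min", 240L), orf_max = p("vh", "orf_max", 360L),
      rss_gap_max = p("vh", "rss_gap_max", 10L),
      strand = p("vh", "strand", "+"), seq_id = sid))
    d <- stage("call_d", call_d(
      seq, d_min = p("d", "d_min", 5L), d_max = p("d", "d_max", 40L),
      seq_id = sid))
    jh <- stage("call_jh", call_jh(
      seq, jh_refs, window = p("jh", "window", 30L),
      min_identity = p("jh", "min_identity", 0.60),
      rss_search = p("jh", "rss_search", 60L),
      gta_max = p("jh", "gta_max", 30L), seq_id = sid))
    ex <- stage("map_ch_exons", map_ch_exons(
      seq, refs, min_identity = p("exon", "min_identity", 0.70),
      snap_max = p("exon", "snap_max", 6L), seq_id = sid))
    if (isTRUE(p("rename", "enabled", TRUE)) && nrow(ex) &&
        length(unique(sub("\\..*$", "", names(refs)))) >= 2L) {
      ex$label <- vapply(seq_len(nrow(ex)), function(k) {
        s <- extract_interval(seq, ex$start[k], ex$end[k], ex$strand[k])
        name_exon_orthology(s, refs)$label
      }, "")
    }
    # annotation integration: an unanchored JH candidate (no RSS, no GTA)
    # inside a homology-mapped exon is dot-plot noise — a short stretch of
    # a CH exon can clear 60% identity to a JH reference by chance
    if (nrow(jh) && nrow(ex)) {
      inside <- vapply(seq_len(nrow(jh)), function(k) {
        jh$boundary_uncertain[k] &&
          any(ex$start < jh$end[k] & ex$end > jh$start[k])
      }, logical(1))
      jh <- jh[!inside, , drop = FALSE]
    }
    # a VH call rests on pattern evidence alone, so when it overlaps a
    # homology-anchored JH/exon or a dual-RSS D call (e.g. inverted JH
    # cassettes mimic forward VH RSSs) the latter wins
    if (nrow(vh)) {
      other <- rbind(d[, c("start", "end")], jh[, c("start", "end")],
                     ex[, c("start", "end")])
      clash <- vapply(seq_len(nrow(vh)), function(k) {
        any(other$start < vh$end[k] & other$end > vh$start[k])
      }, logical(1))
      vh <- vh[!clash, , drop = FALSE]
    }
    seg <- rbind(
      data.frame(seq_id = sid, start = vh$start, end = vh$end,
                 strand = vh$strand, type = "V_gene_segment",
                 label = vh$label, zone_id = NA_integer_,
                 score = vh$evidence, stringsAsFactors = FALSE),
      data.frame(seq_id = sid, start = d$start, end = d$end,
                 strand = d$strand, type = "D_gene_segment",
                 label = d$label, zone_id = NA_integer_,
                 score = d$evidence, stringsAsFactors = FALSE),
      data.frame(seq_id = sid, start = jh$start, end = jh$end,
                 strand = jh$strand, type = "J_gene_segment",
                 label = jh$label, zone_id = NA_integer_,
                 score = jh$evidence, stringsAsFactors = FALSE),
      data.frame(seq_id = sid, start = ex$start, end = ex$end,
                 strand = ex$strand, type = "exon", label = ex$label,
                 zone_id = NA_integer_, score = ex$identity,
                 stringsAsFactors = FALSE))
    pz <- stage("partition_zones", partition_zones(
      seg, zone_gap_max = p("zones", "zone_gap_max", 15000L)))
    if (nrow(pz$zones)) {
      pz$zones$zone_id <- pz$zones$zone_id + zid_offset
      pz$annotations$zone_id <- pz$annotations$zone_id + zid_offset
      pz$zones$seq_id <- sid
      zid_offset <- max(pz$zones$zone_id)
    }
    all_ann[[sid]] <- pz$annotations
    all_zones[[sid]] <- pz$zones
    vh_all[[sid]] <- vh; d_all[[sid]] <- d; jh_all[[sid]] <- jh
    ex_all[[sid]] <- ex
  }
  list(annotations = do.call(rbind, all_ann),
       zones = do.call(rbind, all_zones),
       vh = do.call(rbind, vh_all), d = do.call(rbind, d_all),
       jh = do.call(rbind, jh_all), exons = do.call(rbind, ex_all))
}

#' Classify transcripts against an annotated locus
#'
#' @param ests named character vector of transcript sequences.
#' @param annotation result of [run_annotate()].
#' @param genome the germline sequence(s) used for annotation.
#' @param min_identity per-link identity threshold.
#' @return data.frame as from [classify_transcripts()].
#' @export
run_classify <- function(ests, annotation, genome, min_identity = 0.90) {
  if (is.null(annotation$annotations) || nrow(annotation$annotations) == 0L) {
    stop("run_classify: missing or empty annotation")
  }
  if (is.null(names(genome))) names(genome) <- sprintf("seq%d", seq_along(genome))
  cats <- lapply(names(genome), function(sid) {
    ann <- annotation$annotations
    exon_catalog(ann[ann$seq_id == sid, , drop = FALSE], genome[[sid]])
  })
  catalog <- do.call(rbind, cats)
  classify_transcripts(ests, catalog, min_identity = min_identity)
}

#' Zone-by-isoform contingency table of classified transcripts
#'
#' Rows are isoform classes, columns zones plus an "ambiguous" column;
#' marginals conserve the input transcript count.
#'
#' @param transcripts data.frame from [run_classify()].
#' @return matrix of counts.
#' @export
summarize_counts <- function(transcripts) {
  zones <- transcripts$zone
  zlev <- c(sort(unique(zones[zones != "ambiguous"])), "ambiguous")
  tab <- table(factor(transcripts$isoform, levels = ISOFORM_CLASSES),
               factor(zones, levels = zlev))
  m <- as.matrix(tab)
  stopifnot(sum(m) == nrow(transcripts))
  m
}
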