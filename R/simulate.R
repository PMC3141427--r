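# Synthetic IGH locus generator with planted, machine-readable truth.
#
# The generator emulates the duplicated-zone architecture of the medaka IGH
# locus: tandem zones each carrying a D cluster, a JH cluster, an exon 0,
# Cmu1-Cmu4 (Cmu4 with integrated secretory tail), one TM1/TM2 pair and a
# configurable Cdelta exon set (no Cdelta5 by default); VH cassette arrays
# between zones; one disorganized zone; one inverted zone; inter-zone
# divergence of a few percent applied outside planted motifs.

.NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.rand_seq <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.rand_orf <- function(n_codons) {
  paste(sample(.NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

# 48-nt segment with no stop codon in any of the three frames
.rand_allframe_orf <- function(n, gc = 0.45) {
  for (k in 1:500) {
    s <- .rand_seq(n, gc)
    if (all(vapply(0:2, function(f) length(stop_positions(s, f)) == 0L,
                   logical(1)))) return(s)
  }
  stop("could not generate an all-frame stop-free segment")
}

# a sequence part: seq + protection mask + coding spans + features, all in
# part-local 0-based coordinates. mode "frame0": substitutions must not
# create a stop in the span's own frame; "allframes": in any frame.
.part <- function(seq, protect = NULL, spans = NULL, feats = NULL) {
  n <- nchar(seq)
  list(seq = seq,
       protect = protect %||% logical(n),
       spans = spans %||% data.frame(start = integer(0), end = integer(0),
                                     mode = character(0)),
       feats = feats %||% data.frame(start = integer(0), end = integer(0),
                                     strand = character(0),
                                     type = character(0), label = character(0),
                                     stringsAsFactors = FALSE))
}

.p_pad <- function(range, gc) {
  n <- sample(range[1L]:range[2L], 1L)
  .part(.rand_seq(n, gc))
}

.protect_span <- function(n, intervals) {
  p <- logical(n)
  for (iv in intervals) if (iv[2L] > iv[1L]) p[(iv[1L] + 1L):iv[2L]] <- TRUE
  p
}

.p_d_cassette <- function(dseq, label, model, gc) {
  rcn <- revcomp(model$nonamer); rch <- revcomp(model$heptamer)
  sp1 <- .rand_seq(model$spacer_class, gc)
  sp2 <- .rand_seq(model$spacer_class, gc)
  seq <- paste0(rcn, sp1, rch, dseq, model$heptamer, sp2, model$nonamer)
  s <- 9L + model$spacer_class + 7L           # segment start
  e <- s + nchar(dseq)
  protect <- .protect_span(nchar(seq), list(
    c(0L, 9L), c(9L + model$spacer_class, s),
    c(e, e + 7L), c(e + 7L + model$spacer_class, e + 16L + model$spacer_class)))
  feats <- data.frame(start = s, end = e, strand = "+",
                      type = "D_gene_segment", label = label,
                      stringsAsFactors = FALSE)
  .part(seq, protect, feats = feats)
}

.p_jh_cassette <- function(jseq, label, model, gc) {
  rcn <- revcomp(model$nonamer); rch <- revcomp(model$heptamer)
  sp <- .rand_seq(model$spacer_class, gc)
  seq <- paste0(rcn, sp, rch, jseq, "GTA")
  s <- 9L + model$spacer_class + 7L
  e <- s + nchar(jseq)
  protect <- .protect_span(nchar(seq), list(
    c(0L, 9L), c(9L + model$spacer_class, s), c(e, e + 3L)))
  spans <- data.frame(start = s, end = e, mode = "allframes",
                      stringsAsFactors = FALSE)
  feats <- data.frame(start = s, end = e, strand = "+",
                      type = "J_gene_segment", label = label,
                      stringsAsFactors = FALSE)
  .part(seq, protect, spans, feats)
}

.p_exon <- function(exseq, label, mode = "frame0") {
  seq <- paste0("AG", exseq, "GT")
  n <- nchar(seq)
  protect <- .protect_span(n, list(c(0L, 2L), c(n - 2L, n)))
  spans <- if (identical(mode, "none")) NULL else
    data.frame(start = 2L, end = n - 2L, mode = mode, stringsAsFactors = FALSE)
  feats <- data.frame(start = 2L, end = n - 2L, strand = "+",
                      type = "exon", label = label, stringsAsFactors = FALSE)
  .part(seq, protect, spans, feats)
}

# exon 0: 100 bp, a planted stop in each reading frame (offsets 9, 13, 17)
.make_exon0 <- function(gc) {
  s <- .rand_seq(100L, gc)
  for (off in c(9L, 13L, 17L)) {
    substr(s, off + 1L, off + 3L) <- "TAA"
  }
  s
}

.p_exon0 <- function(ex0seq) {
  p <- .p_exon(ex0seq, "EX0", mode = "none")
  # keep the planted stop triplets fixed under divergence
  for (off in c(9L, 13L, 17L)) {
    p$protect[(2L + off + 1L):(2L + off + 3L)] <- TRUE
  }
  p
}

.VH_STOP_WALL <- "TTAATTAATTAA"   # a stop in every reading frame

.p_vh_cassette <- function(orfseq, label, model, gc) {
  sp <- .rand_seq(model$spacer_class, gc)
  seq <- paste0(.VH_STOP_WALL, "AG", orfseq, model$heptamer, sp, model$nonamer)
  s <- nchar(.VH_STOP_WALL) + 2L
  e <- s + nchar(orfseq)
  protect <- .protect_span(nchar(seq), list(
    c(0L, s), c(e, e + 7L),
    c(e + 7L + model$spacer_class, e + 16L + model$spacer_class)))
  spans <- data.frame(start = s, end = e, mode = "frame0",
                      stringsAsFactors = FALSE)
  feats <- data.frame(start = s, end = e, strand = "+",
                      type = "V_gene_segment", label = label,
                      stringsAsFactors = FALSE)
  .part(seq, protect, spans, feats)
}

.cat_parts <- function(parts) {
  seqs <- vapply(parts, `[[`, "", "seq")
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  feats <- list(); spans <- list()
  for (k in seq_along(parts)) {
    f <- parts[[k]]$feats
    if (nrow(f)) { f$start <- f$start + offs[k]; f$end <- f$end + offs[k]
      feats[[length(feats) + 1L]] <- f }
    s <- parts[[k]]$spans
    if (nrow(s)) { s$start <- s$start + offs[k]; s$end <- s$end + offs[k]
      spans[[length(spans) + 1L]] <- s }
  }
  list(seq = paste(seqs, collapse = ""),
       protect = unlist(lapply(parts, `[[`, "protect")),
       spans = if (length(spans)) do.call(rbind, spans) else
         data.frame(start = integer(0), end = integer(0), mode = character(0)),
       feats = if (length(feats)) do.call(rbind, feats) else
         .part("")$feats)
}

# i.i.d. substitution at `rate` outside protected positions; substitutions
# inside coding spans never create a stop codon in the span's guarded frames
.mutate_seq <- function(block, rate) {
  if (rate <= 0) return(block$seq)
  seq <- block$seq
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate & !block$protect)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  spans <- block$spans
  for (pos in hit) {      # pos is 1-based here
    p0 <- pos - 1L
    alts <- setdiff(c("A", "C", "G", "T"), ch[pos])
    sp <- spans[spans$start <= p0 & p0 < spans$end, , drop = FALSE]
    if (nrow(sp)) {
      frames <- if (sp$mode[1L] == "allframes") 0:2 else 0L
      keep <- vapply(alts, function(b) {
        old <- ch[pos]; ch[pos] <<- b
        ok <- TRUE
        for (f in frames) {
          cs <- sp$start[1L] + f +
            3L * ((p0 - sp$start[1L] - f) %/% 3L)
          if (cs < sp$start[1L] || cs + 3L > sp$end[1L]) next
          if (paste(ch[(cs + 1L):(cs + 3L)], collapse = "") %in%
              c("TAA", "TAG", "TGA")) { ok <- FALSE; break }
        }
        ch[pos] <<- old
        ok
      }, logical(1))
      alts <- alts[keep]
    }
    if (length(alts)) ch[pos] <- sample(alts, 1L)
  }
  paste(ch, collapse = "")
}

# mutate only the protected (motif) positions, at motif_rate
.mutate_motifs <- function(seq, protect, motif_rate) {
  if (motif_rate <= 0) return(seq)
  hit <- which(stats::runif(nchar(seq)) < motif_rate & protect)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  for (pos in hit) ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defaults reproduce the five-zone architecture of the medaka IGH locus:
#' zones 1, 2 and 4 fully organized, zone 3 disorganized (a minority of CH
#' exons, no D/JH clusters), zone 5 fully organized but inverted; seven D
#' and seven JH segments per organized zone; exon 0 in zones 1-3 only; ten
#' VH cassettes between consecutive zones (and 5' of zone 1); 2% expected
#' pairwise inter-zone divergence applied outside planted motifs.
#'
#' @param n_zones number of zones.
#' @param n_d,n_jh D/JH segments per organized zone.
#' @param cmu_labels IgM exon labels planted per zone (Cmu4 carries the
#'   secretory tail; one TM1/TM2 pair per zone serves both isotypes).
#' @param cdelta_labels IgD exon labels planted per zone (no Cdelta5).
#' @param exon0_zones zone indices carrying exon 0.
#' @param disorganized_zones,inverted_zones zone indices.
#' @param n_vh_between_zones VH cassettes per inter-zone array.
#' @param zone_divergence expected pairwise per-base divergence between two
#'   zone copies (each copy draws substitutions at half this rate from a
#'   common master).
#' @param motif_mutation_rate substitution rate applied to the protected
#'   motif positions (RSS elements, splice contexts, GTA, stop triplets).
#' @param background_gc GC content of background/intergenic sequence.
#' @param intergenic_len 2-vector range of pad lengths between cassettes.
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_zones = 5L, n_d = 7L, n_jh = 7L,
                       cmu_labels = c(paste0("Cmu", 1:4), "TM1", "TM2"),
                       cdelta_labels = paste0("Cdelta", c(1:4, 6:7)),
                       exon0_zones = 1:3,
                       disorganized_zones = 3L,
                       inverted_zones = 5L,
                       n_vh_between_zones = 10L,
                       zone_divergence = 0.02,
                       motif_mutation_rate = 0,
                       background_gc = 0.45,
                       intergenic_len = c(30L, 90L),
                       seed = 1L) {
  stopifnot(n_zones >= 1L, n_d >= 0L, n_jh >= 0L,
            zone_divergence >= 0, zone_divergence <= 1,
            motif_mutation_rate >= 0, motif_mutation_rate <= 1,
            background_gc > 0, background_gc < 1,
            length(intergenic_len) == 2L,
            intergenic_len[1L] <= intergenic_len[2L],
            !is.null(seed))
  if (intergenic_len[1L] < 10L) {
    stop("infeasible config: intergenic_len too small for cassette spacing")
  }
  structure(list(n_zones = as.integer(n_zones), n_d = as.integer(n_d),
                 n_jh = as.integer(n_jh),
                 cmu_labels = cmu_labels, cdelta_labels = cdelta_labels,
                 exon0_zones = as.integer(exon0_zones),
                 disorganized_zones = as.integer(disorganized_zones),
                 inverted_zones = as.integer(inverted_zones),
                 n_vh_between_zones = as.integer(n_vh_between_zones),
                 zone_divergence = zone_divergence,
                 motif_mutation_rate = motif_mutation_rate,
                 background_gc = background_gc,
                 intergenic_len = as.integer(intergenic_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.EXON_CODONS <- c(Cmu1 = 100L, Cmu2 = 100L, Cmu3 = 100L, Cmu4 = 120L,
                  Cdelta1 = 100L, Cdelta2 = 100L, Cdelta3 = 100L,
                  Cdelta4 = 100L, Cdelta5 = 100L, Cdelta6 = 100L,
                  Cdelta7 = 100L, TM1 = 50L, TM2 = 40L)

#' Simulate a germline IGH locus with planted truth
#'
#' Deterministic given `config$seed`. Zone copies are drawn from a common
#' master zone with per-base substitution outside protected motif positions
#' (RSS elements, splice AG/GT contexts, the JH-terminal GTA, exon-0 stop
#' triplets), codon-aware inside exon reading frames so no planted exon
#' acquires a stop. Inverted zones are reverse-complemented in place;
#' disorganized zones keep a random minority of CH exons and no D/JH.
#'
#' @param config a [sim_config()].
#' @return an `igh_truth` list: `genome` (named character), `features`
#'   (annotation data.frame with zone ids), `zones` (per-zone truth),
#'   `refs` (master exon sequences, incl. EX0), `jh_refs` (master JH
#'   sequences), `vh_orfs`, `config`.
#' @export
simulate_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$background_gc
  ig <- config$intergenic_len
  m23 <- rss_model(23L); m12 <- rss_model(12L)

  exon_labels <- unique(c(config$cmu_labels, config$cdelta_labels))
  refs <- vapply(exon_labels, function(lab) {
    .rand_orf(.EXON_CODONS[[lab]])
  }, "")
  ex0 <- .make_exon0(gc)
  refs <- c(refs, EX0 = ex0)
  jh_refs <- stats::setNames(
    vapply(seq_len(max(config$n_jh, 1L)), function(k)
      .rand_allframe_orf(48L, gc), ""),
    sprintf("JH%d", seq_len(max(config$n_jh, 1L))))
  d_refs <- stats::setNames(
    vapply(seq_len(max(config$n_d, 1L)), function(k) .rand_seq(16L, gc), ""),
    sprintf("D%d", seq_len(max(config$n_d, 1L))))

  # master zone: D cluster, JH cluster, exon 0, Cmu exons + TM pair, Cdelta
  mk_master <- function() {
    parts <- list(.p_pad(ig, gc))
    for (k in seq_len(config$n_d)) {
      parts <- c(parts, list(.p_d_cassette(d_refs[[k]], names(d_refs)[k],
                                           m12, gc), .p_pad(ig, gc)))
    }
    for (k in seq_len(config$n_jh)) {
      parts <- c(parts, list(.p_jh_cassette(jh_refs[[k]], names(jh_refs)[k],
                                            m23, gc), .p_pad(ig, gc)))
    }
    parts <- c(parts, list(.p_exon0(ex0), .p_pad(ig, gc)))
    for (lab in config$cmu_labels) {
      parts <- c(parts, list(.p_exon(refs[[lab]], lab), .p_pad(ig, gc)))
    }
    for (lab in config$cdelta_labels) {
      parts <- c(parts, list(.p_exon(refs[[lab]], lab), .p_pad(ig, gc)))
    }
    parts
  }
  master_parts <- mk_master()

  blocks <- list(); feats <- list(); zones <- list()
  offset <- 0L
  vh_id <- 0L
  push_seq <- function(seq) {
    blocks[[length(blocks) + 1L]] <<- seq
    offset <<- offset + nchar(seq)
  }
  push_feats <- function(f, zone_id = NA_integer_) {
    if (nrow(f)) {
      f$zone_id <- zone_id
      feats[[length(feats) + 1L]] <<- f
    }
  }
  add_vh_array <- function() {
    for (k in seq_len(config$n_vh_between_zones)) {
      vh_id <<- vh_id + 1L
      p <- .p_vh_cassette(.rand_orf(98L) %+% substr(.rand_allframe_orf(6L, gc), 1L, 2L),
                          sprintf("VH%02d", vh_id), m23, gc)
      f <- p$feats; f$start <- f$start + offset; f$end <- f$end + offset
      push_feats(f)
      push_seq(p$seq)
      pad <- .p_pad(ig, gc); push_seq(pad$seq)
    }
  }

  for (z in seq_len(config$n_zones)) {
    add_vh_array()
    zone_parts <- master_parts
    disorganized <- z %in% config$disorganized_zones
    inverted <- z %in% config$inverted_zones
    if (!(z %in% config$exon0_zones)) {
      is_ex0 <- vapply(zone_parts, function(p) {
        nrow(p$feats) > 0L && p$feats$label[1L] == "EX0"
      }, logical(1))
      zone_parts <- zone_parts[!is_ex0]
    }
    if (disorganized) {
      keep_exon <- function(p) nrow(p$feats) && p$feats$type[1L] == "exon"
      exon_idx <- which(vapply(zone_parts, keep_exon, logical(1)))
      n_keep <- max(1L, length(exon_idx) %/% 3L)
      kept <- sort(sample(exon_idx, n_keep))
      ex0_idx <- exon_idx[vapply(zone_parts[exon_idx], function(p) {
        p$feats$label[1L] == "EX0"
      }, logical(1))]
      kept <- sort(unique(c(kept, ex0_idx)))   # exon 0 survives disorganization
      zone_parts <- zone_parts[sort(unique(c(1L, kept)))]
      zone_parts <- append(zone_parts, list(.p_pad(ig, gc)))
    }
    blk <- .cat_parts(zone_parts)
    zseq <- .mutate_seq(blk, config$zone_divergence / 2)
    zseq <- .mutate_motifs(zseq, blk$protect, config$motif_mutation_rate)
    zf <- blk$feats
    L <- nchar(zseq)
    if (inverted) {
      zseq <- revcomp(zseq)
      if (nrow(zf)) {
        s <- zf$start; e <- zf$end
        zf$start <- L - e; zf$end <- L - s
        zf$strand <- ifelse(zf$strand == "+", "-", "+")
        zf <- zf[order(zf$start), , drop = FALSE]
      }
    }
    zf$start <- zf$start + offset; zf$end <- zf$end + offset
    push_feats(zf, zone_id = z)
    labs <- zf$label[zf$type == "exon"]
    functional <- all(paste0("Cmu", 1:4) %in% labs) ||
      all(config$cdelta_labels %in% labs)
    zones[[z]] <- data.frame(
      zone_id = z, start = offset, end = offset + L,
      functional = functional, has_exon0 = "EX0" %in% labs,
      inverted = inverted, disorganized = disorganized,
      stringsAsFactors = FALSE)
    push_seq(zseq)
    pad <- .p_pad(ig, gc); push_seq(pad$seq)
  }

  genome <- paste(unlist(blocks), collapse = "")
  features <- do.call(rbind, feats)
  features$seq_id <- "locus"
  features$score <- NA_real_
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  zones <- do.call(rbind, zones)
  structure(list(genome = c(locus = genome),
                 features = features[, c("seq_id", "start", "end", "strand",
                                         "type", "label", "zone_id", "score")],
                 zones = zones, refs = refs, jh_refs = jh_refs,
                 config = config),
            class = "igh_truth")
}

`%+%` <- function(a, b) paste0(a, b)

# oriented sequence of a planted feature
.truth_seq <- function(truth, row) {
  extract_interval(truth$genome[[1L]], row$start, row$end, row$strand)
}

.truth_exon_seq <- function(truth, zone, label) {
  f <- truth$features
  row <- f[f$type == "exon" & f$label == label & f$zone_id %in% zone, ,
           drop = FALSE]
  if (nrow(row) == 0L) stop("no planted exon ", label, " in zone ", zone)
  .truth_seq(truth, row[1L, ])
}

#' Verify a truth set's planted motifs by direct string inspection
#'
#' Checks (at motif mutation rate 0) that every planted D/JH segment is
#' flanked by its exact RSS elements, every JH ends at GTA, exon 0 is
#' 100 bp with a stop in each frame, and every exon has its splice
#' contexts. Errors on violation.
#'
#' @param truth an `igh_truth`.
#' @return TRUE, invisibly.
#' @export
verify_truth <- function(truth) {
  stopifnot(inherits(truth, "igh_truth"))
  if (truth$config$motif_mutation_rate > 0) return(invisible(TRUE))
  g <- truth$genome[[1L]]
  n <- nchar(g)
  m23 <- rss_model(23L); m12 <- rss_model(12L)
  f <- truth$features
  for (k in seq_len(nrow(f))) {
    row <- f[k, ]
    txt <- if (row$strand == "-") revcomp(g) else g
    s <- if (row$strand == "-") n - row$end else row$start
    e <- if (row$strand == "-") n - row$start else row$end
    at <- function(a, b) substring(txt, a + 1L, b)
    if (row$type == "D_gene_segment") {
      stopifnot(at(s - 7L, s) == revcomp(m12$heptamer),
                at(s - 16L - m12$spacer_class, s - 7L - m12$spacer_class) ==
                  revcomp(m12$nonamer),
                at(e, e + 7L) == m12$heptamer,
                at(e + 7L + m12$spacer_class, e + 16L + m12$spacer_class) ==
                  m12$nonamer)
    } else if (row$type == "J_gene_segment") {
      stopifnot(at(s - 7L, s) == revcomp(m23$heptamer),
                at(s - 16L - m23$spacer_class, s - 7L - m23$spacer_class) ==
                  revcomp(m23$nonamer),
                at(e, e + 3L) == "GTA")
    } else if (row$type == "V_gene_segment") {
      stopifnot(at(s - 2L, s) == "AG",
                at(e, e + 7L) == m23$heptamer,
                .is_stop_free(txt, s, e, 0L))
    } else if (row$type == "exon") {
      stopifnot(at(s - 2L, s) == "AG", at(e, e + 2L) == "GT" ||
                  row$label == "EX0")
      if (row$label == "EX0") {
        stopifnot(e - s == 100L)
        seq0 <- at(s, e)
        for (fr in 0:2) stopifnot(length(stop_positions(seq0, fr)) > 0L)
      }
    }
  }
  invisible(TRUE)
}

#' Simulate transcripts from a planted locus
#'
#' Each transcript draws an isoform class from `mix` and a source zone
#' uniformly among functional zones. Isoforms with VH perform V(D)J joining
#' (random V cassette, zone D and JH; 0-5 nt trimming and 0-8 random
#' non-templated additions per junction, resampled until the rearranged
#' prefix is in-frame and stop-free, emulating productive rearrangement),
#' then splice exons per class: IGM_SEC Cmu1..Cmu4; IGM_TM_SHORT Cmu1,
#' Cmu2, TM1, TM2; IGD_TM_CHIMERIC Cmu1 + the zone's Cdelta chain + TM1,
#' TM2; STERILE either exon 0 + Cmu1..Cmu4 (zones with exon 0) or a VH-less
#' Cmu chain. I.i.d. substitution errors are applied at `error_rate`.
#'
#' @param truth an `igh_truth` from [simulate_locus()].
#' @param mix named isoform-proportion vector summing to 1.
#' @param n number of transcripts.
#' @param error_rate per-base substitution error rate.
#' @param seed RNG seed.
#' @return list with `ests` (named character) and `labels` (data.frame:
#'   est_id, isoform, zone_id, uses_exon0, v_label, d_label, j_label,
#'   prefix_len).
#' @export
simulate_transcripts <- function(truth,
                                 mix = c(IGM_SEC = 0.45, IGM_TM_SHORT = 0.25,
                                         IGD_TM_CHIMERIC = 0.15,
                                         STERILE = 0.15),
                                 n = 500L, error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "igh_truth"),
            abs(sum(mix) - 1) < 1e-8, n >= 1L)
  set.seed(seed)
  fz <- truth$zones[truth$zones$functional, , drop = FALSE]
  if (nrow(fz) == 0L) stop("simulate_transcripts: no functional zones")
  f <- truth$features
  vh_rows <- f[f$type == "V_gene_segment", , drop = FALSE]
  zone_rows <- function(z, type) {
    f[f$zone_id %in% z & f$type == type, , drop = FALSE]
  }
  build_prefix <- function(z) {
    ds <- zone_rows(z, "D_gene_segment"); js <- zone_rows(z, "J_gene_segment")
    if (nrow(ds) == 0L || nrow(js) == 0L || nrow(vh_rows) == 0L) return(NULL)
    for (try in 1:300) {
      vr <- vh_rows[sample(nrow(vh_rows), 1L), ]
      dr <- ds[sample(nrow(ds), 1L), ]
      jr <- js[sample(nrow(js), 1L), ]
      v <- .truth_seq(truth, vr); d <- .truth_seq(truth, dr)
      j <- .truth_seq(truth, jr)
      t1 <- sample(0:5, 1L); t2 <- sample(0:5, 1L); t3 <- sample(0:5, 1L)
      t4 <- sample(0:5, 1L)
      n1 <- sample(0:8, 1L); n2 <- sample(0:8, 1L)
      v2 <- substr(v, 1L, nchar(v) - t1)
      d2 <- substr(d, 1L + t2, nchar(d) - t3)
      j2 <- substr(j, 1L + t4, nchar(j))
      pre <- paste0(v2, .rand_seq(n1, 0.5), d2, .rand_seq(n2, 0.5), j2)
      if (nchar(pre) %% 3L == 0L &&
          length(stop_positions(pre, 0L)) == 0L) {
        return(list(seq = pre, v = vr$label, d = dr$label, j = jr$label))
      }
    }
    stop("could not assemble an in-frame V(D)J prefix")
  }
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  ests <- character(n); rows <- vector("list", n)
  for (k in seq_len(n)) {
    z <- fz$zone_id[sample(nrow(fz), 1L)]
    cls <- classes[k]
    chain <- switch(cls,
      IGM_SEC = paste0("Cmu", 1:4),
      IGM_TM_SHORT = c("Cmu1", "Cmu2", "TM1", "TM2"),
      IGD_TM_CHIMERIC = c("Cmu1", truth$config$cdelta_labels, "TM1", "TM2"),
      STERILE = paste0("Cmu", 1:4))
    use_ex0 <- FALSE
    if (cls == "STERILE") {
      if (truth$zones$has_exon0[truth$zones$zone_id == z]) {
        chain <- c("EX0", chain); use_ex0 <- TRUE
      }
      prefix <- list(seq = "", v = NA_character_, d = NA_character_,
                     j = NA_character_)
    } else {
      prefix <- build_prefix(z)
      if (is.null(prefix)) stop("zone ", z, " lacks D/JH for rearrangement")
    }
    body <- paste(vapply(chain, function(lab) .truth_exon_seq(truth, z, lab),
                         ""), collapse = "")
    est <- paste0(prefix$seq, body)
    if (error_rate > 0) {
      hit <- which(stats::runif(nchar(est)) < error_rate)
      if (length(hit)) {
        ch <- strsplit(est, "")[[1L]]
        for (pos in hit) ch[pos] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   ch[pos]), 1L)
        est <- paste(ch, collapse = "")
      }
    }
    ests[k] <- est
    rows[[k]] <- data.frame(
      est_id = sprintf("est%04d", k), isoform = cls, zone_id = z,
      uses_exon0 = use_ex0, v_label = prefix$v, d_label = prefix$d,
      j_label = prefix$j, prefix_len = nchar(prefix$seq),
      stringsAsFactors = FALSE)
  }
  labels <- do.call(rbind, rows)
  list(ests = stats::setNames(ests, labels$est_id), labels = labels)
}
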