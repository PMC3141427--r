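make_exon_ref <- function(n_codons = 100L) {
  nonstop <- setdiff(as.vector(outer(as.vector(outer(
    c("A","C","G","T"), c("A","C","G","T"), paste0)),
    c("A","C","G","T"), paste0)), c("TAA", "TAG", "TGA"))
  paste(sample(nonstop, n_codons, replace = TRUE), collapse = "")
}

mutate_frac <- function(seq, frac) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), round(frac * length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

test_that("a planted 95%-identity exon copy maps with snapped boundaries", {
  set.seed(30)
  ref <- make_exon_ref()
  copy <- mutate_frac(ref, 0.05)
  seq <- paste0(rand_dna(80), "AG", copy, "GT", rand_dna(80))
  ann <- map_ch_exons(seq, c(Cmu1 = ref))
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$label, "Cmu1")
  expect_identical(ann$start, 82L)
  expect_identical(ann$end, 82L + 300L)
  expect_true(ann$splice_ok)
  expect_gte(ann$identity, 0.94)
})

test_that("two planted copies are both reported; absent references are not", {
  set.seed(31)
  ref <- make_exon_ref()
  other <- make_exon_ref()
  seq <- paste0(rand_dna(60), "AG", ref, "GT", rand_dna(120),
                "AG", mutate_frac(ref, 0.02), "GT", rand_dna(60))
  ann <- map_ch_exons(seq, c(Cmu2 = ref, Cdelta1 = other))
  expect_identical(nrow(ann), 2L)
  expect_identical(unique(ann$label), "Cmu2")
  expect_identical(length(unique(ann$start)), 2L)
})

test_that("an inverted exon copy maps on the minus strand", {
  set.seed(32)
  ref <- make_exon_ref()
  cassette <- paste0("AG", mutate_frac(ref, 0.03), "GT")
  seq <- paste0(rand_dna(70), oracle_revcomp(cassette), rand_dna(70))
  ann <- map_ch_exons(seq, c(TM1 = ref, Cmu1 = make_exon_ref()))
  ann <- ann[ann$label == "TM1", ]
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$strand, "-")
  expect_identical(ann$start, 72L)
  expect_identical(ann$end, 72L + 300L)
  expect_true(ann$splice_ok)
})

test_that("orthology naming: identity wins, equidistance is ambiguous", {
  set.seed(33)
  refs <- c(Cdelta6 = make_exon_ref(), Cmu1 = make_exon_ref(),
            TM1 = make_exon_ref(50L))
  res <- name_exon_orthology(refs[["Cdelta6"]], refs)
  expect_identical(res$label, "Cdelta6")
  expect_gt(res$margin, 0)
  # an exon equidistant from two references: same mismatch count to both
  base <- make_exon_ref()
  a <- base; substr(a, 1, 1) <- setdiff(c("A","C","G","T"), substr(a, 1, 1))[1]
  b <- base; substr(b, 4, 4) <- setdiff(c("A","C","G","T"), substr(b, 4, 4))[1]
  res2 <- name_exon_orthology(base, c(Cmu1 = a, Cmu2 = b))
  expect_identical(res2$label, "ambiguous")
  expect_identical(res2$margin, 0)
})

test_that("orthology naming survives 5% divergence (100 draws, >=99%)", {
  set.seed(34)
  refs <- c(Cmu1 = make_exon_ref(), Cmu2 = make_exon_ref(),
            Cdelta1 = make_exon_ref(), TM1 = make_exon_ref(50L))
  ok <- 0L
  for (k in 1:100) {
    lab <- sample(names(refs), 1)
    q <- mutate_frac(refs[[lab]], 0.05)
    if (name_exon_orthology(q, refs)$label == lab) ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})

test_that("naming is invariant to the order of the reference list", {
  set.seed(35)
  refs <- c(Cmu1 = make_exon_ref(), Cmu3 = make_exon_ref(),
            Cdelta2 = make_exon_ref())
  q <- mutate_frac(refs[["Cmu3"]], 0.04)
  r1 <- name_exon_orthology(q, refs)
  r2 <- name_exon_orthology(q, rev(refs))
  expect_identical(r1$label, r2$label)
  expect_identical(r1$margin, r2$margin)
})

test_that("zone partitioning separates on VH calls and flags defects", {
  ann <- rbind(
    data.frame(seq_id = "s", start = c(100L, 300L, 600L), end = c(140L, 500L, 900L),
               strand = "+", type = c("D_gene_segment", "exon", "exon"),
               label = c("D1", "Cmu1", "Cmu2"), zone_id = NA_integer_, score = NA_real_),
    data.frame(seq_id = "s", start = 2000L, end = 2300L, strand = "+",
               type = "V_gene_segment", label = "VH01", zone_id = NA_integer_,
               score = NA_real_),
    data.frame(seq_id = "s", start = c(4000L, 4400L, 4800L, 5200L, 5600L, 6000L),
               end = c(4300L, 4700L, 5100L, 5500L, 5900L, 6300L), strand = "+",
               type = "exon", label = c(paste0("Cmu", 1:4), "TM1", "TM2"),
               zone_id = NA_integer_, score = NA_real_))
  pz <- partition_zones(ann)
  expect_identical(nrow(pz$zones), 2L)
  expect_identical(pz$zones$functional, c(FALSE, TRUE))
  expect_identical(pz$zones$n_d, c(1L, 0L))
  # every CH exon belongs to exactly one zone
  ex <- pz$annotations[pz$annotations$type == "exon", ]
  expect_false(any(is.na(ex$zone_id)))
})

test_that("large gaps open zone boundaries; a lone zone stands alone", {
  ann <- data.frame(seq_id = "s", start = c(0L, 100L, 20100L),
                    end = c(50L, 400L, 20400L), strand = "+",
                    type = "exon", label = c("Cmu1", "Cmu2", "Cmu1"),
                    zone_id = NA_integer_, score = NA_real_)
  pz <- partition_zones(ann, zone_gap_max = 15000L)
  expect_identical(nrow(pz$zones), 2L)
  one <- partition_zones(ann[1:2, ])
  expect_identical(nrow(one$zones), 1L)
  # a group without any CH exon is not a zone
  seg <- data.frame(seq_id = "s", start = 0L, end = 30L, strand = "+",
                    type = "D_gene_segment", label = "D1",
                    zone_id = NA_integer_, score = NA_real_)
  expect_identical(nrow(partition_zones(seg)$zones), 0L)
})
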