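test_that("an error-free secreted IgM transcript chains at identity 1", {
  tr <- fixture_truth()
  tx <- simulate_transcripts(tr, mix = c(IGM_SEC = 1), n = 1, seed = 3)
  catalog <- exon_catalog(tr$features, tr$genome[[1]])
  ch <- chain_exons(tx$ests[[1]], catalog)
  expect_identical(ch$chain$label, paste0("Cmu", 1:4))
  expect_true(all(ch$chain$identity == 1))
  expect_true(ch$has_vh)
  expect_false(ch$uses_exon0)
})

test_that("an exon-0 transcript is flagged uses_exon0 without VH", {
  tr <- fixture_truth()
  set.seed(4)
  z <- 1L
  f <- tr$features
  g <- tr$genome[[1]]
  ex0 <- f[f$label == "EX0" & f$zone_id %in% z, ]
  cmu <- f[f$label %in% paste0("Cmu", 1:4) & f$zone_id %in% z, ]
  est <- paste0(
    extract_interval(g, ex0$start, ex0$end, ex0$strand),
    paste(vapply(order(cmu$start), function(k) {
      extract_interval(g, cmu$start[k], cmu$end[k], cmu$strand[k])
    }, ""), collapse = ""))
  catalog <- exon_catalog(f, g)
  ch <- chain_exons(est, catalog)
  expect_true(ch$uses_exon0)
  expect_false(ch$has_vh)
  orf <- orf_stop_analysis(est, limit = ch$chain$est_start[nrow(ch$chain)])
  expect_true(orf$stops_all_frames)
})

test_that("a random EST yields an empty chain and UNCLASSIFIED", {
  set.seed(5)
  tr <- fixture_truth()
  catalog <- exon_catalog(tr$features, tr$genome[[1]])
  ch <- chain_exons(rand_dna(1200), catalog)
  expect_identical(nrow(ch$chain), 0L)
  expect_identical(classify_isoform(ch$chain, ch$has_vh, FALSE), "UNCLASSIFIED")
})

test_that("isoform rules reproduce the four observed splice patterns", {
  mk <- function(labels) {
    data.frame(label = labels, zone_id = 1L,
               est_start = seq(0, by = 300, length.out = length(labels)),
               est_end = seq(300, by = 300, length.out = length(labels)),
               mm = 0L, identity = 1)
  }
  # secreted IgM: four Cmu domains (+ secretory tail), no TM exon
  expect_identical(classify_isoform(mk(paste0("Cmu", 1:4)), TRUE, FALSE),
                   "IGM_SEC")
  # short transmembrane IgM: only Cmu1-Cmu2 spliced to TM1-TM2
  expect_identical(classify_isoform(mk(c("Cmu1", "Cmu2", "TM1", "TM2")),
                                    TRUE, FALSE), "IGM_TM_SHORT")
  # chimeric transmembrane IgD: Cmu1 + Cdelta chain without Cdelta5 + TMs
  expect_identical(classify_isoform(
    mk(c("Cmu1", paste0("Cdelta", c(1:4, 6, 7)), "TM1", "TM2")), TRUE, FALSE),
    "IGD_TM_CHIMERIC")
  # exon-0 transcript without VH: sterile
  expect_identical(classify_isoform(mk(c("EX0", paste0("Cmu", 1:4))),
                                    FALSE, TRUE), "STERILE")
  # stops in all frames dominate even with VH present
  expect_identical(classify_isoform(mk(paste0("Cmu", 1:4)), TRUE, TRUE),
                   "STERILE")
  # an unrecognized pattern stays unclassified
  expect_identical(classify_isoform(mk(c("Cmu2", "TM1")), TRUE, FALSE),
                   "UNCLASSIFIED")
})

test_that("per-frame stop analysis matches hand enumeration", {
  res <- orf_stop_analysis("TAATAGTGA")
  expect_identical(res$stops[[1]], c(0L, 3L, 6L))
  expect_identical(res$stops[[2]], integer(0))
  expect_identical(res$stops[[3]], integer(0))
  expect_false(res$stops_all_frames)
  res2 <- orf_stop_analysis("TTAATTAATTAA")
  expect_identical(lapply(res2$stops, length), list(1L, 1L, 1L))
  expect_true(res2$stops_all_frames)
})

test_that("zone votes use diagnostic sites and degrade to ambiguous", {
  set.seed(6)
  base <- rand_dna(300)
  v1 <- base
  v2 <- base; substr(v2, 10, 10) <- ifelse(substr(v2, 10, 10) == "A", "C", "A")
  catalog <- data.frame(label = "Cmu1", zone_id = c(1L, 2L),
                        start = c(0L, 400L), end = c(300L, 700L),
                        strand = "+", seq = c(v1, v2))
  chain <- data.frame(label = "Cmu1", zone_id = 1L, est_start = 0L,
                      est_end = 300L, mm = 0L, identity = 1)
  vote <- assign_zone(v1, chain, catalog)
  expect_identical(vote$zone, 1L)
  expect_gte(vote$margin, 1L)
  # planted-identical copies cannot be told apart
  catalog$seq[2] <- v1
  vote2 <- assign_zone(v1, chain, catalog)
  expect_identical(vote2$zone, "ambiguous")
  # the winner never has more mismatches than the runner-up
  expect_true(all(diff(sort(vote$per_zone_mm)) >= 0))
})

test_that("protein features find cysteines and N-glycosylation sequons", {
  expect_identical(protein_features("NAS")$nglyc_sites, 0L)
  expect_identical(protein_features("NPS")$nglyc_sites, integer(0))
  pf <- protein_features("CNCT")
  expect_identical(pf$cys_positions, c(0L, 2L))
  expect_identical(pf$nglyc_sites, 1L)
  expect_error(protein_features("CJC"), "invalid")
})

test_that("amplicon prediction matches construction and the oracle", {
  set.seed(7)
  fwd <- "CATTGACTTTCTCATGGACTCAGGGC"   # Cmu1-sense RT-PCR primer
  rev <- rand_dna(24)
  template <- paste0(rand_dna(50), fwd, rand_dna(100), oracle_revcomp(rev),
                     rand_dna(50))
  prod <- predict_amplicon(template, fwd, rev)
  expect_identical(nrow(prod), 1L)
  expect_identical(prod$length, nchar(fwd) + 100L + nchar(rev))
  expect_identical(nrow(predict_amplicon(rand_dna(500), fwd, rev)), 0L)
  # exhaustive-oracle agreement with mismatches and multiple products
  for (k in 1:3) {
    t2 <- rand_dna(800)
    f2 <- substr(t2, 101, 118)
    r2 <- oracle_revcomp(substr(t2, 501, 518))
    got <- predict_amplicon(t2, f2, r2, max_mm = 2)
    want <- oracle_amplicon(t2, f2, r2, max_mm = 2)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("translation of a chained coding region is standard-code", {
  expect_identical(translate_region("ATGAAATAG"), "MK*")
  expect_identical(translate_region("GATGAAA", from = 1L), "MK")
})
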