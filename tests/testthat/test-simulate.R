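test_that("the default locus echoes its configuration into truth", {
  tr <- fixture_truth()
  cfg <- tr$config
  expect_identical(nrow(tr$zones), cfg$n_zones)
  f <- tr$features
  for (z in tr$zones$zone_id) {
    organized <- !tr$zones$disorganized[z]
    if (organized) {
      expect_identical(sum(f$type == "D_gene_segment" & f$zone_id %in% z),
                       cfg$n_d)
      expect_identical(sum(f$type == "J_gene_segment" & f$zone_id %in% z),
                       cfg$n_jh)
    } else {
      expect_identical(sum(f$type %in% c("D_gene_segment", "J_gene_segment") &
                             f$zone_id %in% z), 0L)
      expect_lt(sum(f$type == "exon" & f$zone_id %in% z),
                length(cfg$cmu_labels) + length(cfg$cdelta_labels))
    }
  }
  expect_identical(sum(f$type == "V_gene_segment"),
                   cfg$n_vh_between_zones * cfg$n_zones)
  # exon 0 where configured, inverted zone on the minus strand
  expect_identical(tr$zones$has_exon0, tr$zones$zone_id %in% cfg$exon0_zones)
  inv <- f$zone_id %in% cfg$inverted_zones & f$type == "exon"
  expect_true(all(f$strand[inv] == "-"))
  verify_truth(tr)
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_locus(sim_config(seed = 123))
  b <- simulate_locus(sim_config(seed = 123))
  expect_identical(a$genome, b$genome)
  expect_identical(a$features, b$features)
  c1 <- simulate_transcripts(a, n = 20, seed = 9)
  c2 <- simulate_transcripts(b, n = 20, seed = 9)
  expect_identical(c1$ests, c2$ests)
  expect_false(identical(
    a$genome, simulate_locus(sim_config(seed = 124))$genome))
})

test_that("pairwise zone divergence over exon positions lands near 2%", {
  tr <- fixture_truth()
  f <- tr$features
  g <- tr$genome[[1]]
  zones <- tr$zones$zone_id[!tr$zones$disorganized]
  ids <- numeric(0)
  for (lab in c(paste0("Cmu", 1:4), "Cdelta1")) {
    copies <- vapply(zones, function(z) {
      row <- f[f$type == "exon" & f$label == lab & f$zone_id %in% z, ]
      extract_interval(g, row$start[1], row$end[1], row$strand[1])
    }, "")
    for (a in seq_along(copies)) for (b in seq_along(copies)) {
      if (a < b) {
        ids <- c(ids, 1 - oracle_hamming(copies[a], copies[b]) /
                   nchar(copies[a]))
      }
    }
  }
  expect_gte(mean(ids), 0.97)
  expect_lte(mean(ids), 0.99)
})

test_that("planted exons never acquire stop codons under divergence", {
  tr <- fixture_truth()
  f <- tr$features
  g <- tr$genome[[1]]
  ex <- f[f$type == "exon" & f$label != "EX0", ]
  for (k in seq_len(nrow(ex))) {
    s <- extract_interval(g, ex$start[k], ex$end[k], ex$strand[k])
    expect_length(stop_positions(s, 0L), 0L)
  }
})

test_that("an error-free transcript is the exact concatenation of its exons", {
  tr <- fixture_truth()
  tx <- simulate_transcripts(tr, mix = c(IGM_TM_SHORT = 1), n = 1, seed = 21)
  f <- tr$features
  g <- tr$genome[[1]]
  z <- tx$labels$zone_id[1]
  body <- paste(vapply(c("Cmu1", "Cmu2", "TM1", "TM2"), function(lab) {
    row <- f[f$type == "exon" & f$label == lab & f$zone_id %in% z, ]
    extract_interval(g, row$start[1], row$end[1], row$strand[1])
  }, ""), collapse = "")
  est <- tx$ests[[1]]
  expect_identical(substr(est, nchar(est) - nchar(body) + 1, nchar(est)), body)
  expect_identical(nchar(est) - nchar(body), tx$labels$prefix_len[1])
  # the rearranged prefix is in-frame and stop-free (productive)
  expect_identical(tx$labels$prefix_len[1] %% 3L, 0L)
  expect_length(stop_positions(substr(est, 1, tx$labels$prefix_len[1]), 0L), 0L)
})

test_that("the sterile fraction concentrates around its mix proportion", {
  tx <- fixture_transcripts()
  n <- nrow(tx$labels)
  sterile <- sum(tx$labels$isoform == "STERILE")
  ci <- qbinom(c(0.025, 0.975), n, 0.15)
  expect_gte(sterile, ci[1])
  expect_lte(sterile, ci[2])
})

test_that("infeasible configurations fail before generation", {
  expect_error(sim_config(intergenic_len = c(2L, 5L)), "infeasible")
  expect_error(simulate_transcripts(
    structure(list(zones = data.frame(functional = FALSE),
                   config = sim_config()), class = "igh_truth"),
    n = 1), "no functional zones")
})
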