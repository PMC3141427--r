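test_that("hamming_scan matches hand-derived and brute-force results", {
  expect_identical(hamming_scan("TATTATTGT", "TATTATTGT", 0),
                   data.frame(pos = 0L, mismatches = 0L))
  # brute force over the 4 windows of TATTACTGTAAA leaves only pos 0 (1 mm)
  expect_identical(hamming_scan("TATTACTGTAAA", "TATTATTGT", 2),
                   data.frame(pos = 0L, mismatches = 1L))
  # N counts as a mismatch even against N
  expect_identical(nrow(hamming_scan("NNNNNNNNN", "TATTATTGT", 2)), 0L)
  expect_identical(nrow(hamming_scan("ACG", "ACGT", 0)), 0L)
  set.seed(1)
  for (k in 1:10) {
    s <- rand_dna(150)
    m <- rand_dna(6)
    mm <- sample(0:3, 1)
    got <- hamming_scan(s, m, mm)
    want <- oracle_scan_motif(s, m, mm)
    expect_equal(got$pos, want$pos)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("a planted canonical 23-RSS yields exactly one clean hit", {
  set.seed(2)
  spacer <- rand_dna(23)
  seq <- paste0("CACAGTG", spacer, "TATTATTGT")
  hits <- scan_rss(seq, rss_model(23), strand = "+",
                   orientation = "downstream_of_coding")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$hept_mm, 0L)
  expect_identical(hits$nona_mm, 0L)
  expect_identical(hits$spacer_len, 23L)
  expect_identical(hits$hept_start, 0L)
  expect_identical(hits$nona_start, 30L)
})

test_that("the nonamer mismatch cap is enforced", {
  set.seed(3)
  spacer <- rand_dna(23)
  nona <- "TATTATTGT"
  substr(nona, 1, 3) <- "GCG"   # 3 substitutions
  seq <- paste0("CACAGTG", spacer, nona)
  hits <- scan_rss(seq, rss_model(23), strand = "+",
                   orientation = "downstream_of_coding")
  expect_identical(nrow(hits), 0L)
})

test_that("scan_rss equals the exhaustive double-loop oracle on random DNA", {
  set.seed(4)
  for (k in 1:3) {
    # mismatch caps loosened so random sequence produces hits to compare
    s <- rand_dna(2500)
    model <- rss_model(ifelse(k %% 2 == 0, 12L, 23L),
                       heptamer_max_mm = 2L, nonamer_max_mm = 3L)
    got <- scan_rss(s, model, strand = "both")
    want <- oracle_scan_rss(s, hmm = 2L, nmm = 3L,
                            sclass = model$spacer_class, slack = 1L)
    expect_identical(nrow(got), nrow(want))
    og <- got[order(got$hept_start, got$nona_start, got$strand, got$orientation), ]
    expect_equal(og$hept_start, want$hept_start)
    expect_equal(og$nona_start, want$nona_start)
    expect_equal(og$spacer_len, want$spacer_len)
    expect_equal(og$orientation, want$orientation)
    expect_equal(og$strand, want$strand)
  }
})

test_that("raising mismatch caps or spacer slack never removes a hit", {
  set.seed(5)
  s <- rand_dna(4000)
  key <- function(h) paste(h$strand, h$orientation, h$hept_start, h$nona_start)
  base <- scan_rss(s, rss_model(23, heptamer_max_mm = 1, nonamer_max_mm = 2,
                                spacer_slack = 0))
  for (args in list(list(heptamer_max_mm = 2), list(nonamer_max_mm = 4),
                    list(spacer_slack = 2))) {
    model <- do.call(rss_model, c(list(spacer_class = 23), args))
    wider <- scan_rss(s, model)
    expect_true(all(key(base) %in% key(wider)))
  }
})

test_that("minus-strand scanning maps a planted RSS to forward coordinates", {
  set.seed(6)
  pad1 <- rand_dna(11); pad2 <- rand_dna(17)
  fwd <- paste0("CACAGTG", rand_dna(23), "TATTATTGT")
  seq <- paste0(pad1, oracle_revcomp(fwd), pad2)
  hits <- scan_rss(seq, rss_model(23), strand = "-",
                   orientation = "downstream_of_coding")
  expect_identical(nrow(hits), 1L)
  # the heptamer occupies the last 7 forward bases of the embedded rc block
  expect_identical(hits$hept_start, 11L + 39L - 7L)
  expect_identical(hits$hept_end, 11L + 39L)
  expect_identical(hits$nona_start, 11L)
})

test_that("random-sequence hit counts sit within 3 sigma of the closed form", {
  set.seed(9)
  n <- 1500000L
  s <- rand_dna(n)
  hits <- scan_rss(s, rss_model(23), strand = "+",
                   orientation = "downstream_of_coding")
  p_h <- sum(choose(7, 0:1) * 3^(0:1)) / 4^7
  p_n <- sum(choose(9, 0:2) * 3^(0:2)) / 4^9
  # each (position, spacer) pair is one Bernoulli(p_h * p_n) trial
  expected <- sum(n - 16L - (22:24) + 1L) * p_h * p_n
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 1)
})
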