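test_that("self comparison fills the main diagonal at identity 1", {
  set.seed(10)
  a <- rand_dna(80)
  cells <- dot_matches(a, a, dot_params(30, 0.85))
  diag <- cells[cells$i == cells$j, ]
  expect_identical(nrow(diag), 80L - 29L)
  expect_true(all(diag$identity == 1))
})

test_that("three substitutions in one window keep it at 27/30 = 0.90", {
  set.seed(11)
  a <- rand_dna(100)
  b <- a
  for (p in c(41L, 50L, 62L)) {
    old <- substr(b, p, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  cells <- dot_matches(a, b, dot_params(30, 0.85))
  cell <- cells[cells$i == 40L & cells$j == 40L, ]
  expect_identical(nrow(cell), 1L)
  expect_equal(cell$identity, 27 / 30)
})

test_that("dot_matches equals the exhaustive double-loop oracle", {
  set.seed(12)
  for (k in 1:4) {
    a <- rand_dna(200)
    # half-related pair: embed a shared fragment so matches exist
    b <- paste0(rand_dna(60), substr(a, 41, 160), rand_dna(40))
    got <- dot_matches(a, b, dot_params(20, 0.8))
    want <- oracle_dot(a, b, 20, 0.8)
    og <- got[order(got$i, got$j), ]
    ow <- want[order(want$i, want$j), ]
    expect_equal(og$i, ow$i)
    expect_equal(og$j, ow$j)
    expect_equal(og$identity * 20, ow$matches)
  }
})

test_that("lowering the identity threshold never removes a cell", {
  set.seed(13)
  a <- rand_dna(300); b <- paste0(substr(a, 50, 250), rand_dna(50))
  hi <- dot_matches(a, b, dot_params(30, 0.85))
  lo <- dot_matches(a, b, dot_params(30, 0.60))
  expect_true(all(paste(hi$i, hi$j) %in% paste(lo$i, lo$j)))
})

test_that("diagonal merging equals the union-find oracle", {
  set.seed(14)
  for (gap in c(0L, 2L)) {
    a <- rand_dna(250)
    b <- paste0(rand_dna(30), substr(a, 21, 120), rand_dna(20),
                substr(a, 151, 230), rand_dna(20))
    cells <- dot_matches(a, b, dot_params(25, 0.8))
    got <- merge_diagonals(cells, 25L, max_gap = gap)
    want <- oracle_merge(cells, 25L, max_gap = gap)
    expect_identical(nrow(got), nrow(want))
    og <- got[order(got$a_start, got$b_start), ]
    expect_equal(og$a_start, want$a_start)
    expect_equal(og$b_start, want$b_start)
    expect_equal(og$length, want$length)
    expect_equal(og$n_cells, want$n_cells)
    expect_identical(sum(got$n_cells), nrow(cells))
  }
})

test_that("contiguous and split diagonals merge as specified", {
  w <- 10L
  cells <- data.frame(i = c(0:19, 40:45), j = c(5:24, 45:50),
                      identity = 1, orientation = "forward")
  runs <- merge_diagonals(cells, w, max_gap = 0L)
  expect_identical(nrow(runs), 2L)
  expect_identical(runs$length[1], 19L + w)
  cells2 <- data.frame(i = c(0, 1, 10), j = c(0, 1, 10), identity = 1,
                       orientation = "forward")
  expect_identical(nrow(merge_diagonals(cells2, w, max_gap = 0L)), 2L)
  expect_identical(nrow(merge_diagonals(cells2, w, max_gap = 10L)), 1L)
})

test_that("duplication detection finds a 2%-mutated copy and skips self", {
  set.seed(15)
  z <- rand_dna(2000)
  ch <- strsplit(z, "")[[1]]
  mut <- which(runif(2000) < 0.02)
  for (p in mut) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  zcopy <- paste(ch, collapse = "")
  runs <- detect_duplications(z, zcopy)
  expect_gt(run_coverage(runs, a_len = 2000L), 0.9)
  # self comparison of a random sequence: nothing beyond the main diagonal
  expect_identical(nrow(detect_duplications(z, z)), 0L)
})

test_that("unrelated 5-kb sequences yield no long duplication runs", {
  set.seed(16)
  for (k in 1:3) {
    runs <- detect_duplications(rand_dna(5000), rand_dna(5000))
    expect_identical(sum(runs$length >= 60L), 0L)
  }
})

test_that("inverted duplications are reported in reverse orientation", {
  set.seed(17)
  core <- rand_dna(400)
  a <- paste0(rand_dna(100), core, rand_dna(100))
  b <- paste0(rand_dna(50), oracle_revcomp(core), rand_dna(50))
  runs <- detect_duplications(a, b)
  rev <- runs[runs$orientation == "reverse", ]
  expect_gt(nrow(rev), 0L)
  expect_gte(max(rev$length), 400L)
  # the longest reverse run covers the planted rc block (boundary windows
  # with a majority of in-core positions may extend it a few nt)
  top <- rev[which.max(rev$length), ]
  expect_lte(top$a_start, 100L)
  expect_gte(top$a_start + top$length, 500L)
  expect_lte(top$b_start, 50L)
})
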