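# Shared desk-scale fixtures, built once per test run. The default locus is
# the five-zone configuration; annotation and the 500-transcript
# classification are the expensive steps, so they are cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    .fixture_env$truth <- simulate_locus(sim_config(seed = 7))
  }
  .fixture_env$truth
}

fixture_annotation <- function() {
  if (is.null(.fixture_env$ann)) {
    tr <- fixture_truth()
    .fixture_env$ann <- run_annotate(tr$genome, tr$refs, tr$jh_refs)
  }
  .fixture_env$ann
}

fixture_transcripts <- function() {
  if (is.null(.fixture_env$tx)) {
    .fixture_env$tx <- simulate_transcripts(fixture_truth(), n = 500L,
                                            error_rate = 0, seed = 11)
  }
  .fixture_env$tx
}

fixture_classified <- function() {
  if (is.null(.fixture_env$cls)) {
    .fixture_env$cls <- run_classify(fixture_transcripts()$ests,
                                     fixture_annotation(),
                                     fixture_truth()$genome)
  }
  .fixture_env$cls
}

# canonical planted constructs used across segment tests
planted_vh_construct <- function(orf_codons = 98L, pad = 60L, seed = 5L) {
  set.seed(seed)
  nonstop <- setdiff(as.vector(outer(as.vector(outer(
    c("A","C","G","T"), c("A","C","G","T"), paste0)),
    c("A","C","G","T"), paste0)), c("TAA", "TAG", "TGA"))
  orf <- paste0(paste(sample(nonstop, orf_codons, replace = TRUE),
                      collapse = ""), "CA")
  spacer <- rand_dna(23)
  left <- rand_dna(pad)
  seq <- paste0(left, "TTAATTAATTAA", "AG", orf, "CACAGTG", spacer,
                "TATTATTGT", rand_dna(pad))
  start <- pad + 12L + 2L
  list(seq = seq, start = start, end = start + nchar(orf), orf = orf)
}

planted_d_construct <- function(d_len = 16L, pad = 40L, seed = 6L) {
  set.seed(seed)
  d <- rand_dna(d_len)
  seq <- paste0(rand_dna(pad),
                oracle_revcomp("TATTATTGT"), rand_dna(12), oracle_revcomp("CACAGTG"),
                d,
                "CACAGTG", rand_dna(12), "TATTATTGT", rand_dna(pad))
  start <- pad + 9L + 12L + 7L
  list(seq = seq, start = start, end = start + d_len, d = d)
}

planted_jh_construct <- function(jh_ref, pad = 60L, seed = 8L) {
  set.seed(seed)
  seq <- paste0(rand_dna(pad),
                oracle_revcomp("TATTATTGT"), rand_dna(23), oracle_revcomp("CACAGTG"),
                jh_ref, "GTA", rand_dna(pad))
  start <- pad + 9L + 23L + 7L
  list(seq = seq, start = start, end = start + nchar(jh_ref))
}
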