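#!/usr/bin/env Rscript
# Build the default five-zone synthetic IGH locus (the study conditions:
# 7 D + 7 JH per organized zone, disorganized zone 3, inverted zone 5,
# exon 0 in zones 1-3, ~2% inter-zone divergence) plus 500 transcripts at
# the observed isoform mix, and write everything under results/.

suppressPackageStartupMessages(library(ighloci))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 7)
truth <- simulate_locus(cfg)
verify_truth(truth)
tx <- simulate_transcripts(truth, n = 500L, error_rate = 0, seed = 11)

write_fasta(truth$genome, "results/genome.fa")
write_fasta(truth$refs, "results/ch_refs.fa")
write_fasta(truth$jh_refs, "results/jh_refs.fa")
write_gff3(truth$features, "results/truth.gff3",
           seq_lens = vapply(truth$genome, nchar, integer(1)))
write_fasta(tx$ests, "results/ests.fa")
write.table(tx$labels, "results/est_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$zones, "results/truth_zones.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("locus: %d nt; %d planted features; %d zones (%d functional)\n",
            nchar(truth$genome[[1]]), nrow(truth$features),
            nrow(truth$zones), sum(truth$zones$functional)))
cat(sprintf("transcripts: %d; mix: %s\n", length(tx$ests),
            paste(names(table(tx$labels$isoform)),
                  table(tx$labels$isoform), collapse = ", ")))
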