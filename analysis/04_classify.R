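#!/usr/bin/env Rscript
# Classify the simulated EST set against the annotated locus: isoform
# calling, zone-of-origin voting through diagnostic nucleotides, and the
# zone x isoform count table. Also demonstrates in-silico RT-PCR across
# the chimeric IgD span (sense primer in Cmu1, antisense in Cdelta6).

suppressPackageStartupMessages(library(ighloci))

genome <- read_fasta("results/genome.fa")
refs <- read_fasta("results/ch_refs.fa")
jh_refs <- read_fasta("results/jh_refs.fa")
ests <- read_fasta("results/ests.fa")
labels <- read.delim("results/est_labels.tsv")

ann <- run_annotate(genome, refs, jh_refs)
res <- run_classify(ests, ann, genome)
write.table(res, "results/transcripts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

stopifnot(identical(res$est_id, labels$est_id))
cat(sprintf("isoform accuracy: %.1f%% (n=%d)\n",
            100 * mean(res$isoform == labels$isoform), nrow(res)))
nonamb <- res$zone != "ambiguous"
cat(sprintf("zone assignment: %.1f%% correct, %.1f%% ambiguous\n",
            100 * mean((res$zone == as.character(labels$zone_id))[nonamb]),
            100 * mean(!nonamb)))
cat(sprintf("sterile fraction: %.1f%% (simulated 15%%)\n",
            100 * mean(res$isoform == "STERILE")))

tab <- summarize_counts(res)
write.table(cbind(isoform = rownames(tab), as.data.frame.matrix(tab)),
            "results/zone_isoform_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab)

# in-silico RT-PCR on a chimeric IgD transcript
igd_id <- labels$est_id[labels$isoform == "IGD_TM_CHIMERIC"][1]
est <- ests[[igd_id]]
fwd <- substr(refs[["Cmu1"]], 21, 46)
rev <- revcomp(substr(refs[["Cdelta6"]], 255, 280))
amp <- predict_amplicon(est, fwd, rev, max_mm = 3)
cat(sprintf("Cmu1-sense x Cdelta6-antisense amplicon on %s: %s bp\n",
            igd_id, if (nrow(amp)) max(amp$length) else "no product"))

# protein features of a secreted IgM transcript (read in its V frame)
sec_id <- res$est_id[res$isoform == "IGM_SEC"][1]
aa <- translate_region(ests[[sec_id]], from = 0L)
pf <- protein_features(aa)
cat(sprintf("%s constant+variable region: %d cysteines, %d N-glycosylation sequons\n",
            sec_id, length(pf$cys_positions), length(pf$nglyc_sites)))
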