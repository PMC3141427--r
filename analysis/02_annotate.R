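#!/usr/bin/env Rscript
# Annotate the simulated germline locus from the FASTA/reference files
# written by 01_simulate.R, compare against planted truth, and write the
# annotation (GFF3), the zone table and a recovery summary.

suppressPackageStartupMessages(library(ighloci))

genome <- read_fasta("results/genome.fa")
refs <- read_fasta("results/ch_refs.fa")
jh_refs <- read_fasta("results/jh_refs.fa")
truth_feats <- read_gff3("results/truth.gff3")

ann <- run_annotate(genome, refs, jh_refs)
write_gff3(ann$annotations, "results/locus.gff3",
           seq_lens = vapply(genome, nchar, integer(1)))
write.table(ann$zones, "results/zones.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

key <- function(df) paste(df$start, df$end)
rows <- lapply(c("V_gene_segment", "D_gene_segment", "J_gene_segment",
                 "exon"), function(kind) {
  tr <- truth_feats[truth_feats$type == kind, ]
  cl <- ann$annotations[ann$annotations$type == kind, ]
  data.frame(kind = kind, planted = nrow(tr), called = nrow(cl),
             recovered = sum(key(tr) %in% key(cl)),
             false_calls = sum(!(key(cl) %in% key(tr))))
})
recovery <- do.call(rbind, rows)
write.table(recovery, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("zones detected:", nrow(ann$zones), "\n")
print(recovery, row.names = FALSE)
cat(sprintf("sensitivity %.1f%%, precision %.1f%%\n",
            100 * sum(recovery$recovered) / sum(recovery$planted),
            100 * (1 - sum(recovery$false_calls) / sum(recovery$called))))
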