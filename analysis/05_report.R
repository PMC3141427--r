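#!/usr/bin/env Rscript
# Aggregate the stage outputs into one summary table.

recovery <- read.delim("results/recovery.tsv")
zones <- read.delim("results/zones.tsv")
tx <- read.delim("results/transcripts.tsv")
labels <- read.delim("results/est_labels.tsv")
runs <- read.delim("results/duplication_runs.tsv")

nonamb <- tx$zone != "ambiguous"
summary <- data.frame(
  quantity = c("zones_detected", "functional_zones",
               "segments_planted", "segments_recovered", "false_segment_calls",
               "isoform_accuracy_pct", "zone_assignment_accuracy_pct",
               "ambiguous_zone_votes_pct", "sterile_fraction_pct",
               "longest_duplication_run_nt"),
  value = c(nrow(zones), sum(zones$functional),
            sum(recovery$planted), sum(recovery$recovered),
            sum(recovery$false_calls),
            round(100 * mean(tx$isoform == labels$isoform), 2),
            round(100 * mean((tx$zone == as.character(labels$zone_id))[nonamb]), 2),
            round(100 * mean(!nonamb), 2),
            round(100 * mean(tx$isoform == "STERILE"), 2),
            max(runs$length)))
write.table(summary, "results/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summary, row.names = FALSE)
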