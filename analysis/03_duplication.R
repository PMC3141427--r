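#!/usr/bin/env Rscript
# Zone-versus-zone duplication dot plot (window 30, 85% identity): the
# tandem zones should light up as off-diagonal runs covering most of each
# zone, the signature of recent segmental duplication.

suppressPackageStartupMessages(library(ighloci))

genome <- read_fasta("results/genome.fa")[[1]]
zones <- read.delim("results/truth_zones.tsv")
org <- zones[!zones$disorganized, ]

z1 <- extract_interval(genome, org$start[1], org$end[1])
z2 <- extract_interval(genome, org$start[2], org$end[2])
runs <- detect_duplications(z1, z2)
write.table(runs, "results/duplication_runs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cov <- run_coverage(runs, a_len = nchar(z1))
cat(sprintf("zone %d vs zone %d: %d runs, longest %d nt, coverage %.1f%%\n",
            org$zone_id[1], org$zone_id[2], nrow(runs), max(runs$length),
            100 * cov))

# dot-plot rendering of the match cells
cells <- dot_matches(z1, z2, dot_params(30, 0.85))
png("results/dotplot_zone_pair.png", width = 700, height = 700)
plot(cells$i, cells$j, pch = ".", cex = 2,
     xlab = sprintf("zone %d position (nt)", org$zone_id[1]),
     ylab = sprintf("zone %d position (nt)", org$zone_id[2]),
     main = "Windowed-identity dot plot (window 30, 85% identity)")
invisible(dev.off())

# the inverted zone shows up in reverse orientation
inv <- zones[zones$inverted, ]
if (nrow(inv)) {
  zi <- extract_interval(genome, inv$start[1], inv$end[1])
  rinv <- detect_duplications(z1, zi)
  cat(sprintf("zone %d vs inverted zone %d: %d reverse runs (%.1f%% coverage)\n",
              org$zone_id[1], inv$zone_id[1],
              sum(rinv$orientation == "reverse"),
              100 * run_coverage(rinv[rinv$orientation == "reverse", ],
                                 a_len = nchar(z1))))
}
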