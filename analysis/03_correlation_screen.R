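#!/usr/bin/env Rscript
# Stage 3: regulator-expression vs PSI correlation screen on the tumour
# cohort.
#
# Applies the cohort filters (drop the 5% of samples with fewest detected
# exons, keep exons detected in >= 25% of the remaining samples), then runs
# the Spearman screen with BH correction and an adjusted-p < 0.01 call.

library(splicescape)

if (!file.exists("results/data/tumour_counts.tsv"))
  stop("run analysis/01_simulate.R first")
dir.create("results/correlation", showWarnings = FALSE)

counts <- read_event_table("results/data/tumour_counts.tsv")
md <- read_metadata("results/data/tumour_metadata.tsv")

det <- call_expressed(counts)
flt <- filter_cohort(det)
message(sprintf("filters: %d/%d samples kept, %d/%d exons kept",
                length(flt$samples), ncol(det),
                length(flt$events), nrow(det)))

pm <- psi_matrix(subset_events(counts, events = flt$events,
                               samples = flt$samples))
screen <- correlate_exons(pm, md)
write.table(screen, "results/correlation/correlation_screen.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- generate_cohort(synthetic_config(n_samples_per_group = 100L,
                                          planted_diff = list(fraction = 0,
                                                              delta = 0.4),
                                          seed = 2L))$truth
planted <- truth$corr_event_ids
n_sig <- sum(screen$significant)
n_hit <- sum(screen$significant & screen$event_id %in% planted)
message(sprintf("significant exons (adj p < 0.01): %d", n_sig))
message(sprintf("planted-exon recovery: %d/%d (%.1f%%); null false positives: %d",
                n_hit, length(planted), 100 * n_hit / length(planted),
                n_sig - n_hit))
message("Done: results/correlation/")
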