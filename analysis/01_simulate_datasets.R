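#!/usr/bin/env Rscript
# Generate the three synthetic datasets the downstream analyses consume:
# the suspension-differentiation lipidome time course, the siELOVL1/siSLC27A1
# knockdown time course, and the 258-target siRNA screen. Ground truth is
# written next to each dataset so later steps can score themselves.

suppressPackageStartupMessages(library(lipidisc))
seed <- 1L
out <- "results/datasets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

susp <- simulate_suspension(seed = seed)
write_lipidomics_table(susp$dataset, file.path(out, "suspension.tsv"))
write.table(susp$truth, file.path(out, "suspension_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("suspension: %d samples x %d species, %d planted species\n",
            nrow(susp$dataset$abundance), ncol(susp$dataset$abundance),
            nrow(susp$truth)))

kd <- simulate_knockdown(seed = seed)
for (tp in names(kd$datasets))
  write_lipidomics_table(kd$datasets[[tp]], file.path(out, sprintf("knockdown_%sh.tsv", tp)))
write.table(kd$truth, file.path(out, "knockdown_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("knockdown: 3 timepoints x %d samples, %d planted species\n",
            nrow(kd$datasets[[1]]$abundance), nrow(kd$truth)))

scr <- simulate_screen(seed = seed)
write.table(scr$wells, file.path(out, "screen_wells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(scr$truth, file.path(out, "screen_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("screen: %d wells over %d plates, %d planted hits\n",
            nrow(scr$wells), length(unique(scr$wells$plate)), nrow(scr$truth)))
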