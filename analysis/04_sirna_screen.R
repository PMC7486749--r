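#!/usr/bin/env Rscript
# siRNA screen scoring: per-condition modified Z-scores pooled into one
# dataset, per-plate fold changes against nontargeting controls, replicate
# concordance QC, and volcano-style hit calling (p < 0.05, FC < 0.6 or
# FC > 2.5), scored against the planted truth.

suppressPackageStartupMessages(library(lipidisc))
din <- "results/datasets"
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wells <- read.delim(file.path(din, "screen_wells.tsv"))
truth <- read.delim(file.path(din, "screen_truth.tsv"))

wells <- pool_conditions(wells)
wells <- plate_fold_change(wells)
qc <- replicate_correlation(wells)
cat("replicate-vs-mean Pearson r:", paste(sprintf("%.3f", qc), collapse = ", "), "\n")

calls <- call_hits(wells)
write.table(calls, file.path(out, "hit_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hits <- calls[!is.na(calls$call) & calls$call != "none", ]
cat(sprintf("\n%d hits called of %d targets:\n", nrow(hits), nrow(calls)))
print(hits[order(hits$call, -abs(hits$mean_z)),
           c("target", "fold_change", "p_value", "call")], row.names = FALSE)

want <- ifelse(truth$direction == "up", "inducer", "inhibitor")
ok <- calls$call[match(truth$gene, calls$target)] == want
cat(sprintf("\nplanted hits recovered: %d/%d; false positives: %d\n",
            sum(ok, na.rm = TRUE), nrow(truth),
            length(setdiff(hits$target, truth$gene))))
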