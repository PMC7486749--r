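#!/usr/bin/env Rscript
# Suspension-differentiation lipidome analysis: mol% normalization, class
# composition, Z-score clustering, PCA, sPLS-DA under the four-class model
# (adherent / commitment / differentiated / inhibited) and extraction of the
# discriminant lipid set, scored against the planted truth.

suppressPackageStartupMessages(library(lipidisc))
din <- "results/datasets"
out <- "results/suspension"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- read_lipidomics_table(file.path(din, "suspension.tsv"), layout = "long",
                            design = file.path(din, "suspension_design.tsv"))
ds$design <- assign_suspension_classes(ds$design)
truth <- read.delim(file.path(din, "suspension_truth.tsv"))

mp <- normalize_molpct(ds)
write.table(mp, file.path(out, "molpct.tsv"), sep = "\t", quote = FALSE, col.names = NA)

comp <- class_composition(mp)
grp <- with(ds$design, paste(timepoint, treatment, sep = "h_"))
write.table(class_composition_summary(comp, grp),
            file.path(out, "class_composition_by_group.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("class composition (mean mol% at 0h vs 24h control):\n")
print(round(cbind(`0h` = rowMeans(comp[, grp == "0h_control"]),
                  `24h` = rowMeans(comp[, grp == "24h_control"])), 2))

zs <- suppressWarnings(zscore_by_species(mp))
hc <- hierarchical_cluster(zs, axis = "samples")
cat("\nsample clustering leaf order (complete linkage on Z-scores):\n")
cat(paste(hc$labels, collapse = ", "), "\n")

nz <- remove_near_zero_variance(mp)
pc <- pca(nz$matrix, ncomp = 3, scale = TRUE)
write.table(pc$scores, file.path(out, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)
cat(sprintf("\nPCA explained variance: %s\n",
            paste(sprintf("%.1f%%", 100 * pc$explained), collapse = ", ")))

set <- suspension_discriminants(ds)
write_discriminant_set(set, file.path(out, "discriminants.tsv"))
planted <- truth$annotation[truth$role %in% c("commitment", "differentiated")]
cat(sprintf("\ndiscriminant set: %d species; sensitivity %.2f; false positives %d\n",
            length(set$species), mean(planted %in% set$species),
            length(setdiff(set$species, planted))))
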