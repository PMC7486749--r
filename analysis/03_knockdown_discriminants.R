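#!/usr/bin/env Rscript
# Knockdown time-course analysis: per-timepoint sPLS-DA at 48 h and 72 h,
# discriminant species for siELOVL1 (components 1-2) and siSLC27A1
# (component 2), maximum fold-change report with the Accumulated sentinel,
# and intersection with the suspension discriminant set.

suppressPackageStartupMessages(library(lipidisc))
din <- "results/datasets"
out <- "results/knockdown"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_tp <- function(tp) read_lipidomics_table(
  file.path(din, sprintf("knockdown_%dh.tsv", tp)), layout = "long",
  design = file.path(din, sprintf("knockdown_%dh_design.tsv", tp)))
ds48 <- read_tp(48); ds72 <- read_tp(72)
truth <- read.delim(file.path(din, "knockdown_truth.tsv"))

sets <- list()
for (tg in c("siELOVL1", "siSLC27A1")) {
  set <- knockdown_discriminants(ds48, ds72, target = tg)
  sets[[tg]] <- set
  write_discriminant_set(set, file.path(out, sprintf("%s_discriminants.tsv", tg)))
  roles <- if (tg == "siELOVL1") c("siELOVL1", "siELOVL1_accumulated") else tg
  planted <- truth$annotation[truth$role %in% roles]
  cat(sprintf("%s: %d discriminant species; sensitivity %.2f; false positives %d\n",
              tg, length(set$species), mean(planted %in% set$species),
              length(setdiff(set$species, planted))))
  tab <- max_fold_change_table(set, ds48, ds72, target = tg)
  write.table(tab, file.path(out, sprintf("%s_max_fold_change.tsv", tg)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  acc <- tab$label[grepl("Accumulated", tab$label)]
  cat(sprintf("  max fold change range %.2g-%.2g; %d species report '%s'\n",
              min(tab$max_fold_change[is.finite(tab$max_fold_change)]),
              max(tab$max_fold_change[is.finite(tab$max_fold_change)]),
              length(acc), if (length(acc)) acc[1] else "Accumulated"))
}

# intersection with the suspension set (step 02 must have run)
susp_path <- "results/suspension/discriminants.tsv"
if (file.exists(susp_path)) {
  susp_tab <- read.delim(susp_path)
  susp_set <- lipidisc:::.new_discriminant_set(within(susp_tab, {
    fold_change <- suppressWarnings(as.numeric(fold_change))
    fold_change[is.na(fold_change)] <- Inf
  }))
  for (tg in names(sets)) {
    inter <- intersect_sets(susp_set, sets[[tg]])
    write_discriminant_set(inter, file.path(out, sprintf("intersection_%s.tsv", tg)))
    cat(sprintf("suspension ∩ %s: %d candidate bioactive species\n",
                tg, length(inter$species)))
  }
}
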