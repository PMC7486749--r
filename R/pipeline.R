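# End-to-end pipeline driver: wires the modules into one reproducible run
# over simulated (or user-supplied) datasets and writes every stage artifact
# plus a machine-readable summary.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Seed for the simulated inputs.
#' @param ncomp,keepX sPLS-DA parameters (defaults 3 and 250).
#' @param loading_threshold Discriminant loading cutoff (default 0.01).
#' @param fc_low,fc_high,alpha,z_constant Screen thresholds.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(out_dir = tempfile("lipidisc_run_"), seed = 1L,
                            ncomp = 3L, keepX = 250L, loading_threshold = 0.01,
                            fc_low = 0.6, fc_high = 2.5, alpha = 0.05,
                            z_constant = 0.6745) {
  stopifnot(ncomp >= 1, keepX >= 1, loading_threshold > 0,
            fc_low > 0, fc_high > 0, alpha > 0)
  list(out_dir = out_dir, seed = as.integer(seed), ncomp = ncomp, keepX = keepX,
       loading_threshold = loading_threshold, fc_low = fc_low,
       fc_high = fc_high, alpha = alpha, z_constant = z_constant)
}

#' Run the full analysis pipeline on simulated datasets
#'
#' Simulates the suspension time course, the knockdown time course and the
#' siRNA screen from `config$seed`, then runs every stage: mol%
#' normalization, class composition, Z-scoring, clustering, PCA, sPLS-DA,
#' discriminant extraction, cross-experiment intersection and screen
#' scoring. All tables are written as TSV under `config$out_dir` together
#' with a `summary.json` holding the set sizes and hit list; the summary is
#' fully determined by the configuration.
#'
#' @param config A [pipeline_config()].
#' @return The summary, invisibly (a list, also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir

  # --- suspension experiment -------------------------------------------------
  susp <- simulate_suspension(seed = config$seed)
  ds <- susp$dataset
  ds$design <- assign_suspension_classes(ds$design)
  mp <- normalize_molpct(ds)
  utils::write.table(mp, file.path(od, "suspension_molpct.tsv"), sep = "\t", quote = FALSE, col.names = NA)
  comp <- class_composition(mp)
  utils::write.table(comp, file.path(od, "suspension_class_composition.tsv"), sep = "\t", quote = FALSE, col.names = NA)
  zs <- suppressWarnings(zscore_by_species(mp))
  hc <- hierarchical_cluster(zs, axis = "samples")
  utils::write.table(data.frame(merge1 = hc$hclust$merge[, 1], merge2 = hc$hclust$merge[, 2],
                                height = hc$hclust$height),
                     file.path(od, "suspension_linkage.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  nz <- remove_near_zero_variance(mp)
  pc <- pca(nz$matrix, ncomp = min(3L, nrow(mp) - 1L), scale = TRUE)
  utils::write.table(pc$scores, file.path(od, "suspension_pca_scores.tsv"), sep = "\t", quote = FALSE, col.names = NA)
  susp_set <- suspension_discriminants(ds, ncomp = config$ncomp, keepX = config$keepX,
                                       loading_threshold = config$loading_threshold)
  write_discriminant_set(susp_set, file.path(od, "suspension_discriminants.tsv"))

  # --- knockdown experiment --------------------------------------------------
  kd <- simulate_knockdown(seed = config$seed)
  kd_sets <- list()
  for (tg in c("siELOVL1", "siSLC27A1")) {
    set <- knockdown_discriminants(kd$datasets[["48"]], kd$datasets[["72"]], target = tg,
                                   ncomp = config$ncomp, keepX = config$keepX,
                                   loading_threshold = config$loading_threshold)
    kd_sets[[tg]] <- set
    write_discriminant_set(set, file.path(od, sprintf("knockdown_%s_discriminants.tsv", tg)))
    fc_tab <- max_fold_change_table(set, kd$datasets[["48"]], kd$datasets[["72"]], target = tg)
    utils::write.table(fc_tab, file.path(od, sprintf("knockdown_%s_max_fold_change.tsv", tg)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  inter <- lapply(kd_sets, function(s) intersect_sets(susp_set, s))
  for (tg in names(inter))
    write_discriminant_set(inter[[tg]], file.path(od, sprintf("intersection_suspension_%s.tsv", tg)))

  # --- siRNA screen ----------------------------------------------------------
  scr <- simulate_screen(seed = config$seed)
  wells <- pool_conditions(scr$wells, constant = config$z_constant)
  wells <- plate_fold_change(wells)
  calls <- call_hits(wells, fc_low = config$fc_low, fc_high = config$fc_high,
                     alpha = config$alpha, constant = config$z_constant)
  utils::write.table(calls, file.path(od, "screen_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  qc <- replicate_correlation(wells)

  summary <- list(
    config = config[setdiff(names(config), "out_dir")],
    suspension = list(n_discriminants = length(susp_set$species)),
    knockdown = list(siELOVL1 = length(kd_sets$siELOVL1$species),
                     siSLC27A1 = length(kd_sets$siSLC27A1$species)),
    intersections = list(siELOVL1 = length(inter$siELOVL1$species),
                         siSLC27A1 = length(inter$siSLC27A1$species)),
    screen = list(hits = calls$target[!is.na(calls$call) & calls$call != "none"],
                  calls = calls$call[!is.na(calls$call) & calls$call != "none"],
                  replicate_correlation = unname(round(qc, 6))))
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
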