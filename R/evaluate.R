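# Recovery evaluation against generator ground truth: the quantitative
# checks behind the synthetic-data validation of every pipeline stage.

#' Suspension discriminant recovery over seeds
#'
#' For each seed, simulates a suspension time course, extracts the
#' discriminant set and scores it against the planted truth: sensitivity is
#' the fraction of commitment/differentiation-planted species recovered,
#' false positives are flagged species that were not planted with either
#' role (suspension-response species count as false positives: they are not
#' differentiation-enriched).
#'
#' @param seeds Integer vector of seeds.
#' @param profile,planted,n_rep Generator settings (see
#'   [simulate_suspension()]).
#' @param ... Passed to [suspension_discriminants()].
#' @return Data frame `seed`, `n_truth`, `recovered`, `sensitivity`,
#'   `false_positives`, `set_size`.
#' @export
evaluate_suspension_recovery <- function(seeds,
                                         profile = default_lipidome_profile(),
                                         planted = suspension_truth_spec(),
                                         n_rep = 2L, ...) {
  out <- lapply(seeds, function(s) {
    sim <- simulate_suspension(profile, planted, n_rep = n_rep, seed = s)
    set <- suspension_discriminants(sim$dataset, ...)
    truth <- sim$truth$annotation[sim$truth$role %in% c("commitment", "differentiated")]
    rec <- sum(truth %in% set$species)
    data.frame(seed = s, n_truth = length(truth), recovered = rec,
               sensitivity = if (length(truth)) rec / length(truth) else NA_real_,
               false_positives = length(setdiff(set$species, truth)),
               set_size = length(set$species))
  })
  do.call(rbind, out)
}

#' Knockdown discriminant recovery over seeds
#'
#' As [evaluate_suspension_recovery()], for the knockdown time course. Truth
#' for each target includes its accumulated (control-undetectable) species.
#'
#' @param seeds Integer vector of seeds.
#' @param profile,planted,n_rep Generator settings (see
#'   [simulate_knockdown()]).
#' @param ... Passed to [knockdown_discriminants()].
#' @return Data frame with one row per seed x target.
#' @export
evaluate_knockdown_recovery <- function(seeds,
                                        profile = default_lipidome_profile(),
                                        planted = knockdown_truth_spec(),
                                        n_rep = 3L, ...) {
  out <- lapply(seeds, function(s) {
    sim <- simulate_knockdown(profile, planted, n_rep = n_rep, seed = s)
    do.call(rbind, lapply(c("siELOVL1", "siSLC27A1"), function(tg) {
      set <- knockdown_discriminants(sim$datasets[["48"]], sim$datasets[["72"]],
                                     target = tg, ...)
      roles <- if (tg == "siELOVL1") c("siELOVL1", "siELOVL1_accumulated") else tg
      truth <- sim$truth$annotation[sim$truth$role %in% roles]
      rec <- sum(truth %in% set$species)
      data.frame(seed = s, target = tg, n_truth = length(truth), recovered = rec,
                 sensitivity = if (length(truth)) rec / length(truth) else NA_real_,
                 false_positives = length(setdiff(set$species, truth)),
                 set_size = length(set$species), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Screen hit recovery over seeds
#'
#' For each seed, simulates a screen, calls hits and scores them against the
#' planted truth: a planted hit counts as recovered when it is called in the
#' planted direction; any other called target is a false positive.
#'
#' @param seeds Integer vector of seeds.
#' @param n_targets,planted_hits,n_rep,... Generator settings (see
#'   [simulate_screen()]).
#' @param fc_low,fc_high,alpha Hit-calling thresholds (see [call_hits()]).
#' @return Data frame `seed`, `n_planted`, `recovered`, `false_positives`.
#' @export
evaluate_screen_recovery <- function(seeds, n_targets = 258L,
                                     planted_hits = screen_truth_spec(),
                                     n_rep = 4L, fc_low = 0.6, fc_high = 2.5,
                                     alpha = 0.05, ...) {
  out <- lapply(seeds, function(s) {
    sim <- simulate_screen(n_targets = n_targets, planted_hits = planted_hits,
                           n_rep = n_rep, seed = s, ...)
    calls <- call_hits(sim$wells, fc_low = fc_low, fc_high = fc_high, alpha = alpha)
    want <- ifelse(sim$truth$direction == "up", "inducer", "inhibitor")
    called <- calls$target[!is.na(calls$call) & calls$call != "none"]
    rec <- sum(calls$call[match(sim$truth$gene, calls$target)] == want, na.rm = TRUE)
    data.frame(seed = s, n_planted = nrow(sim$truth), recovered = rec,
               false_positives = length(setdiff(called, sim$truth$gene)))
  })
  do.call(rbind, out)
}

#' Type-I error of the screen test on null targets
#'
#' Simulates a screen with no planted hits, no target heterogeneity and no
#' plate offsets, and returns the fraction of targets with p below alpha.
#'
#' @param seed Integer seed.
#' @param n_targets Number of null targets (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param n_rep Replicates (default 4).
#' @return List with `rate` (fraction significant) and `n` (targets tested).
#' @export
evaluate_screen_type1 <- function(seed, n_targets = 1000L, alpha = 0.05,
                                  n_rep = 4L) {
  sim <- simulate_screen(n_targets = n_targets,
                         planted_hits = screen_truth_spec(0L, 1, 0L, 1),
                         n_rep = n_rep, seed = seed,
                         target_effect_sd = 0, plate_offset_sd = 0)
  calls <- call_hits(sim$wells)
  p <- calls$p_value[!is.na(calls$p_value)]
  list(rate = mean(p < alpha), n = length(p))
}
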