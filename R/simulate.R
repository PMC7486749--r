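# Synthetic lipidomes, time-course designs and screens with known truth.
#
# The generators emulate the design shapes of the study this pipeline
# supports: a 0/4/8/12/24 h suspension time course in duplicate with a PKC
# inhibitor arm, a {siScramble, siELOVL1, siSLC27A1} x {24, 48, 72 h}
# knockdown time course in triplicate, and a 96-well siRNA screen of 258
# targets in quadruplicate under two culture conditions. Abundances are
# class-structured lognormals; designated species receive multiplicative
# enrichment in designated sample groups; replicate noise is multiplicative
# lognormal. Each generator is deterministic given its seed.

.set_sim_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Default lipidome profile
#'
#' Class-level baseline composition loosely mimicking a cultured-cell
#' lipidome (phosphatidylcholine-dominant with minor sphingolipid classes);
#' only the statistical structure matters for testing, no fidelity to any
#' particular measured lipidome is claimed.
#'
#' @param n_species Total number of species to spread over the classes.
#' @param species_sdlog Lognormal SD of species base abundances within a
#'   class (default 1: abundances span roughly two orders of magnitude).
#' @param noise_sdlog Multiplicative replicate noise SD on the log scale
#'   (default 0.15, i.e. ~15% CV).
#' @return List with `class_shares`, `class_counts`, `species_sdlog`,
#'   `noise_sdlog`.
#' @export
default_lipidome_profile <- function(n_species = 300L, species_sdlog = 1,
                                     noise_sdlog = 0.15) {
  shares <- c(PC = 0.28, `PC O-` = 0.04, PE = 0.10, `PE O-` = 0.04,
              PS = 0.06, PI = 0.05, PG = 0.02, PA = 0.02,
              LPC = 0.01, LPE = 0.01, SM = 0.08, Cer = 0.04, HexCer = 0.02,
              DAG = 0.04, TAG = 0.06, CE = 0.02, Chol = 0.10, CL = 0.01)
  shares <- shares / sum(shares)
  counts <- pmax(round(shares * n_species), 1L)
  counts["Chol"] <- 1L
  # largest classes absorb the rounding remainder
  diff <- n_species - sum(counts)
  counts["PC"] <- counts["PC"] + diff
  list(class_shares = shares, class_counts = counts,
       species_sdlog = species_sdlog, noise_sdlog = noise_sdlog)
}

# enumerate a plausible random chain for a class; glycerophospholipid chains
# span 14-24 carbons with up to 4 unsaturations, sphingolipid fatty acids
# 14-24 carbons with up to 2
.random_chain <- function(kind = c("glycero", "fa_sphingo")) {
  kind <- match.arg(kind)
  if (kind == "glycero")
    chain_descriptor(sample(14:24, 1L), sample(0:4, 1L), 0L)
  else
    chain_descriptor(sample(14:24, 1L), sample(0:2, 1L), 0L)
}

#' Random valid lipid species annotations
#'
#' Generates unique species per class following the annotation grammar;
#' every annotation round-trips through [parse_species_annotation()].
#'
#' @param profile A [default_lipidome_profile()].
#' @param seed Integer seed (optional; when NULL the current RNG stream is
#'   used, so callers can embed this in a larger seeded simulation).
#' @return Character vector of canonical annotations, named by class.
#' @export
random_species <- function(profile = default_lipidome_profile(), seed = NULL) {
  if (!is.null(seed)) .set_sim_seed(seed)
  reg <- .lipid_registry
  out <- character(0)
  for (cls in names(profile$class_counts)) {
    n <- profile$class_counts[[cls]]
    if (n == 0L) next
    info <- reg[[cls]]
    seen <- character(0)
    tries <- 0L
    while (length(seen) < n && tries < 1000L * n) {
      tries <- tries + 1L
      ann <- if (info$n_chains == 0L) {
        cls
      } else if (info$category == "sphingolipid") {
        fa <- .random_chain("fa_sphingo")
        tot <- chain_descriptor(18L + fa[1L], 1L + fa[2L], 2L)
        paste0(cls, " - ", .format_chain(tot))
      } else {
        chains <- lapply(seq_len(info$n_chains), function(i) .random_chain("glycero"))
        ord <- order(vapply(chains, `[[`, 0L, 1L), vapply(chains, `[[`, 0L, 2L))
        paste0(cls, " - ", paste(vapply(chains[ord], .format_chain, ""), collapse = ";"))
      }
      if (!ann %in% seen) seen <- c(seen, ann)
    }
    if (length(seen) < n)
      stop(sprintf("could not generate %d unique %s species", n, cls))
    out <- c(out, stats::setNames(seen, rep(cls, length(seen))))
  }
  out
}

#' Planted-effect specification for the suspension generator
#'
#' Three planted signatures: a broad suspension response (species shifted in
#' every suspended sample, the dominant source of variance, mirroring the
#' adherent-vs-suspended separation such experiments show on the first
#' component), a commitment signature (untreated 4/8 h only) and a
#' differentiation signature (untreated 12/24 h only). The PKC-inhibited arm
#' receives the suspension response but neither differentiation effect.
#'
#' @param n_suspension,effect_suspension Count and multiplier of
#'   suspension-response species (defaults 40, 2.5).
#' @param n_commitment,effect_commitment Commitment-enriched species
#'   (defaults 20, 3).
#' @param n_differentiated,effect_differentiated Differentiation-enriched
#'   species (defaults 20, 3).
#' @return List, the `planted` argument of [simulate_suspension()].
#' @export
suspension_truth_spec <- function(n_suspension = 40L, effect_suspension = 2.5,
                                  n_commitment = 20L, effect_commitment = 3,
                                  n_differentiated = 20L, effect_differentiated = 3) {
  list(n_suspension = n_suspension, effect_suspension = effect_suspension,
       n_commitment = n_commitment, effect_commitment = effect_commitment,
       n_differentiated = n_differentiated, effect_differentiated = effect_differentiated)
}

#' Simulate a suspension-differentiation lipidomics time course
#'
#' Design: timepoints 0/4/8/12/24 h x {control, PKCi} x `n_rep` replicates.
#' Per-sample totals vary by +/-30%; species amounts are
#' `total x base_share x planted_effect x lognormal noise`.
#'
#' @param profile A [default_lipidome_profile()].
#' @param planted A [suspension_truth_spec()].
#' @param n_rep Replicates per design cell (default 2).
#' @param seed Integer seed.
#' @return List with `dataset` (a [lipidomics_dataset()]) and `truth`
#'   (data frame `annotation`, `role`, `multiplier`; plus the seed as an
#'   attribute).
#' @export
simulate_suspension <- function(profile = default_lipidome_profile(),
                                planted = suspension_truth_spec(),
                                n_rep = 2L, seed = 1L) {
  .set_sim_seed(seed)
  species <- random_species(profile)
  p <- length(species)
  base_share <- .base_shares(species, profile)

  design <- expand.grid(timepoint = c(0, 4, 8, 12, 24),
                        treatment = c("control", "PKCi"),
                        replicate = seq_len(n_rep),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("susp_%gh_%s_r%d", design$timepoint,
                              design$treatment, design$replicate)
  design$experiment <- "suspension"
  design <- design[, c("sample_id", "experiment", "timepoint", "treatment", "replicate")]

  n_tot <- planted$n_suspension + planted$n_commitment + planted$n_differentiated
  if (n_tot > p) stop("more planted species than species in the lipidome")
  picks <- sample.int(p, n_tot)
  idx_susp <- picks[seq_len(planted$n_suspension)]
  idx_comm <- picks[planted$n_suspension + seq_len(planted$n_commitment)]
  idx_diff <- picks[planted$n_suspension + planted$n_commitment +
                      seq_len(planted$n_differentiated)]

  n <- nrow(design)
  eff <- matrix(1, n, p)
  in_susp <- design$timepoint > 0
  in_comm <- design$treatment == "control" & design$timepoint %in% c(4, 8)
  in_diff <- design$treatment == "control" & design$timepoint %in% c(12, 24)
  eff[in_susp, idx_susp] <- planted$effect_suspension
  eff[in_comm, idx_comm] <- planted$effect_commitment
  eff[in_diff, idx_diff] <- planted$effect_differentiated

  totals <- 1000 * stats::runif(n, 0.7, 1.3)
  noise <- matrix(exp(stats::rnorm(n * p, 0, profile$noise_sdlog)), n, p)
  ab <- totals * t(t(eff * noise) * base_share)
  colnames(ab) <- unname(species)

  truth <- data.frame(
    annotation = unname(species[c(idx_susp, idx_comm, idx_diff)]),
    role = rep(c("suspension_response", "commitment", "differentiated"),
               c(length(idx_susp), length(idx_comm), length(idx_diff))),
    multiplier = rep(c(planted$effect_suspension, planted$effect_commitment,
                       planted$effect_differentiated),
                     c(length(idx_susp), length(idx_comm), length(idx_diff))),
    stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  list(dataset = lipidomics_dataset(ab, design), truth = truth)
}

.base_shares <- function(species, profile) {
  cls <- names(species)
  share <- profile$class_shares[cls] / table(cls)[cls]
  w <- exp(stats::rnorm(length(species), 0, profile$species_sdlog))
  s <- as.numeric(share) * w
  s / sum(s)
}

#' Planted-effect specification for the knockdown generator
#'
#' @param n_elovl1,effect_elovl1 Species enriched under siELOVL1 at 48/72 h
#'   (defaults 20, 3).
#' @param n_slc27a1,effect_slc27a1 Species enriched under siSLC27A1 at
#'   48/72 h (defaults 15, 3).
#' @param n_accumulated Species undetectable in the control but present
#'   under siELOVL1 at 48/72 h, exercising the Accumulated sentinel
#'   (default 3).
#' @param n_drift,drift_multipliers Species drifting over time in every
#'   treatment (defaults 30 and 1/1.6/2.5 at 24/48/72 h), emulating the
#'   dominant time effect such cultures show.
#' @param timepoints_effect Timepoints (h) at which knockdown enrichment
#'   applies (default c(48, 72)).
#' @return List, the `planted` argument of [simulate_knockdown()].
#' @export
knockdown_truth_spec <- function(n_elovl1 = 20L, effect_elovl1 = 3,
                                 n_slc27a1 = 15L, effect_slc27a1 = 3,
                                 n_accumulated = 3L,
                                 n_drift = 30L, drift_multipliers = c(1, 1.6, 2.5),
                                 timepoints_effect = c(48, 72)) {
  list(n_elovl1 = n_elovl1, effect_elovl1 = effect_elovl1,
       n_slc27a1 = n_slc27a1, effect_slc27a1 = effect_slc27a1,
       n_accumulated = n_accumulated, n_drift = n_drift,
       drift_multipliers = drift_multipliers,
       timepoints_effect = timepoints_effect)
}

#' Simulate a knockdown lipidomics time course
#'
#' Design: {siScramble, siELOVL1, siSLC27A1} x {24, 48, 72 h} x `n_rep`
#' replicates, returned as one dataset per timepoint (the discriminant
#' analysis fits each timepoint separately).
#'
#' @param profile A [default_lipidome_profile()].
#' @param planted A [knockdown_truth_spec()].
#' @param n_rep Replicates per treatment x timepoint (default 3).
#' @param seed Integer seed.
#' @return List with `datasets` (named list `"24"`, `"48"`, `"72"` of
#'   [lipidomics_dataset()]s) and `truth` (data frame `annotation`, `role`,
#'   `multiplier`, `timepoints`).
#' @export
simulate_knockdown <- function(profile = default_lipidome_profile(),
                               planted = knockdown_truth_spec(),
                               n_rep = 3L, seed = 1L) {
  .set_sim_seed(seed)
  species <- random_species(profile)
  p <- length(species)
  base_share <- .base_shares(species, profile)
  treatments <- c("siScramble", "siELOVL1", "siSLC27A1")
  timepoints <- c(24, 48, 72)

  n_tot <- planted$n_elovl1 + planted$n_slc27a1 + planted$n_accumulated + planted$n_drift
  if (n_tot > p) stop("more planted species than species in the lipidome")
  picks <- sample.int(p, n_tot)
  idx_el <- picks[seq_len(planted$n_elovl1)]
  idx_sl <- picks[planted$n_elovl1 + seq_len(planted$n_slc27a1)]
  idx_ac <- picks[planted$n_elovl1 + planted$n_slc27a1 + seq_len(planted$n_accumulated)]
  idx_dr <- picks[planted$n_elovl1 + planted$n_slc27a1 + planted$n_accumulated +
                    seq_len(planted$n_drift)]

  datasets <- list()
  for (ti in seq_along(timepoints)) {
    tp <- timepoints[ti]
    design <- expand.grid(treatment = treatments, replicate = seq_len(n_rep),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design$timepoint <- tp
    design$sample_id <- sprintf("kd_%gh_%s_r%d", tp, design$treatment, design$replicate)
    design$experiment <- "knockdown"
    design <- design[, c("sample_id", "experiment", "timepoint", "treatment", "replicate")]
    n <- nrow(design)
    eff <- matrix(1, n, p)
    eff[, idx_dr] <- planted$drift_multipliers[ti]
    if (tp %in% planted$timepoints_effect) {
      eff[design$treatment == "siELOVL1", idx_el] <- planted$effect_elovl1
      eff[design$treatment == "siSLC27A1", idx_sl] <- planted$effect_slc27a1
    }
    # accumulated species: absent everywhere except siELOVL1 at effect timepoints
    eff[, idx_ac] <- 0
    if (tp %in% planted$timepoints_effect)
      eff[design$treatment == "siELOVL1", idx_ac] <- planted$effect_elovl1
    totals <- 1000 * stats::runif(n, 0.7, 1.3)
    noise <- matrix(exp(stats::rnorm(n * p, 0, profile$noise_sdlog)), n, p)
    ab <- totals * t(t(eff * noise) * base_share)
    colnames(ab) <- unname(species)
    datasets[[as.character(tp)]] <- lipidomics_dataset(ab, design)
  }

  truth <- data.frame(
    annotation = unname(species[c(idx_el, idx_ac, idx_sl, idx_dr)]),
    role = rep(c("siELOVL1", "siELOVL1_accumulated", "siSLC27A1", "time_drift"),
               c(length(idx_el), length(idx_ac), length(idx_sl), length(idx_dr))),
    multiplier = c(rep(planted$effect_elovl1, length(idx_el) + length(idx_ac)),
                   rep(planted$effect_slc27a1, length(idx_sl)),
                   rep(max(planted$drift_multipliers), length(idx_dr))),
    timepoints = c(rep(paste(planted$timepoints_effect, collapse = ","),
                       length(idx_el) + length(idx_ac) + length(idx_sl)),
                   rep(paste(timepoints, collapse = ","), length(idx_dr))),
    stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  list(datasets = datasets, truth = truth)
}

#' Planted-hit specification for the screen generator
#'
#' @param n_down,effect_down Differentiation-inhibiting hits (defaults 4 at
#'   0.4x).
#' @param n_up,effect_up Differentiation-inducing hits (defaults 6 at 3.5x).
#' @return List, the `planted_hits` argument of [simulate_screen()].
#' @export
screen_truth_spec <- function(n_down = 4L, effect_down = 0.4,
                              n_up = 6L, effect_up = 3.5) {
  list(n_down = n_down, effect_down = effect_down,
       n_up = n_up, effect_up = effect_up)
}

#' Simulate a 96-well siRNA screen
#'
#' Targets are spread over plates of at most 86 test wells plus two
#' nontargeting, two no-siRNA and two positive-control wells each; the
#' layout is replicated per replicate and per culture condition. Readouts
#' are `baseline(condition) x plate offset x target effect x lognormal
#' noise`, clipped to the unit interval. Besides the planted hits, every
#' target carries a small lognormal true effect (`target_effect_sd`),
#' emulating the biological heterogeneity that makes replicate-vs-mean
#' correlations high (~0.8) in real screens; set it to 0 for a pure null.
#'
#' @param n_targets Number of test siRNAs (default 258).
#' @param planted_hits A [screen_truth_spec()]; use
#'   `screen_truth_spec(0, 1, 0, 1)` for none.
#' @param n_rep Replicates (default 4).
#' @param seed Integer seed.
#' @param baseline Named baseline differentiating fractions per condition
#'   (default growth 0.10, serum 0.30).
#' @param noise_sd Well-level lognormal noise SD (default 0.15).
#' @param target_effect_sd Target-level lognormal effect SD (default 0.15).
#' @param plate_offset_sd Plate-level lognormal offset SD (default 0.05).
#' @param positive_effect Multiplier of involucrin-siRNA positive-control
#'   wells (default 0.2; these wells are transfection QC only).
#' @return List with `wells` (screen table, see [validate_screen()]) and
#'   `truth` (data frame `gene`, `direction`, `multiplier`).
#' @export
simulate_screen <- function(n_targets = 258L,
                            planted_hits = screen_truth_spec(),
                            n_rep = 4L, seed = 1L,
                            baseline = c(growth = 0.10, serum = 0.30),
                            noise_sd = 0.15, target_effect_sd = 0.15,
                            plate_offset_sd = 0.05, positive_effect = 0.2) {
  .set_sim_seed(seed)
  per_plate <- 86L
  genes <- sprintf("GENE%04d", seq_len(n_targets))
  n_hit <- planted_hits$n_down + planted_hits$n_up
  hit_idx <- if (n_hit > 0) sample.int(n_targets, n_hit) else integer(0)
  mult <- rep(1, n_targets)
  dir <- rep("none", n_targets)
  if (planted_hits$n_down > 0) {
    i <- hit_idx[seq_len(planted_hits$n_down)]
    mult[i] <- planted_hits$effect_down; dir[i] <- "down"
  }
  if (planted_hits$n_up > 0) {
    i <- hit_idx[planted_hits$n_down + seq_len(planted_hits$n_up)]
    mult[i] <- planted_hits$effect_up; dir[i] <- "up"
  }
  target_eff <- mult * exp(stats::rnorm(n_targets, 0, target_effect_sd))

  chunks <- split(seq_len(n_targets), ceiling(seq_len(n_targets) / per_plate))
  rows <- list()
  for (cond in names(baseline)) {
    for (rep_i in seq_len(n_rep)) {
      for (ci in seq_along(chunks)) {
        plate <- sprintf("P%02d_%s_r%d", ci, cond, rep_i)
        offset <- exp(stats::rnorm(1L, 0, plate_offset_sd))
        tg <- chunks[[ci]]
        wells <- data.frame(
          plate = plate,
          target = c(genes[tg], rep("NT", 2L), rep("noRNA", 2L), rep("siINV", 2L)),
          role = c(rep("test", length(tg)), rep("nontargeting", 2L),
                   rep("no_siRNA", 2L), rep("positive_control", 2L)),
          eff = c(target_eff[tg], rep(1, 4L), rep(positive_effect, 2L)),
          stringsAsFactors = FALSE)
        nw <- nrow(wells)
        wells$well <- sprintf("%s%02d", LETTERS[(seq_len(nw) - 1L) %/% 12L + 1L],
                              (seq_len(nw) - 1L) %% 12L + 1L)
        wells$condition <- cond
        wells$replicate <- rep_i
        wells$readout <- pmin(1, pmax(0, baseline[[cond]] * offset * wells$eff *
                                        exp(stats::rnorm(nw, 0, noise_sd))))
        wells$eff <- NULL
        rows[[length(rows) + 1L]] <- wells
      }
    }
  }
  wells <- do.call(rbind, rows)
  wells <- wells[, c("plate", "well", "target", "role", "condition", "replicate", "readout")]
  truth <- data.frame(gene = genes[hit_idx],
                      direction = dir[hit_idx],
                      multiplier = mult[hit_idx], stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  list(wells = wells, truth = truth)
}
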