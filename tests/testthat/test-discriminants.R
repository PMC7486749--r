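test_that("suspension class model labels every design cell", {
  d <- expand.grid(timepoint = c(0, 4, 8, 12, 24),
                   treatment = c("control", "PKCi"), stringsAsFactors = FALSE)
  lab <- assign_suspension_classes(d)$class_label
  expect_equal(lab[d$timepoint == 0], rep("adherent", 2))
  expect_equal(lab[d$timepoint == 8 & d$treatment == "control"], "commitment")
  expect_equal(lab[d$timepoint == 24 & d$treatment == "control"], "differentiated")
  expect_equal(lab[d$timepoint == 12 & d$treatment == "PKCi"], "inhibited")
  expect_error(assign_suspension_classes(data.frame(timepoint = 6, treatment = "control")),
               "unknown")
})

test_that("median enrichment requires strict superiority over every class", {
  mp <- rbind(3, 3.2, 1, 1.1, 0.9, 1.2, 1, 1)  # one species, 8 samples
  mp <- cbind(mp, c(2, 2, 2, 2, 2, 2, 2, 2))   # all-equal medians
  colnames(mp) <- c("up", "flat")
  labels <- rep(c("differentiated", "adherent", "commitment", "inhibited"), each = 2)
  enr <- enriched_by_class_median(mp, labels, "differentiated")
  expect_true(enr[["up"]])
  expect_false(enr[["flat"]])
  expect_error(enriched_by_class_median(mp, labels, "nosuch"), "no samples")

  # brute-force oracle on a 12 x 20 fixture
  set.seed(21)
  m <- matrix(rexp(12 * 20), 12, 20, dimnames = list(NULL, paste0("l", 1:20)))
  labs <- rep(c("a", "b", "c"), each = 4)
  got <- enriched_by_class_median(m, labs, "b")
  want <- apply(m, 2, function(col) {
    meds <- tapply(col, labs, median)
    all(meds["b"] > meds[c("a", "c")])
  })
  expect_equal(unname(got), unname(want))
})

test_that("mean enrichment computes fold changes with the Accumulated sentinel", {
  mp <- cbind(up = c(2, 2, 1, 1), acc = c(0.5, 0.7, 0, 0), flat = c(1, 1, 1, 1),
              none = c(0, 0, 0, 0))
  e <- enriched_by_mean(mp, 1:2, 3:4)
  expect_equal(e$fold_change[e$species == "up"], 2)
  expect_true(e$enriched[e$species == "up"])
  expect_equal(e$fold_change[e$species == "acc"], Inf)
  expect_true(e$enriched[e$species == "acc"])
  expect_equal(e$fold_change[e$species == "flat"], 1)
  expect_false(e$enriched[e$species == "flat"])
  expect_true(is.nan(e$fold_change[e$species == "none"]))
  expect_false(e$enriched[e$species == "none"])
  expect_error(enriched_by_mean(mp, integer(0), 3:4), "non-empty")
})

test_that("suspension discriminant extraction obeys threshold monotonicity and orientation independence", {
  sim <- simulate_suspension(profile = default_lipidome_profile(n_species = 120),
                             planted = suspension_truth_spec(15, 2.5, 8, 3, 8, 3),
                             seed = 31)
  set_lo <- suppressWarnings(suspension_discriminants(sim$dataset, keepX = 100))
  set_hi <- suppressWarnings(suspension_discriminants(sim$dataset, keepX = 100,
                                                      loading_threshold = 0.2))
  expect_true(all(set_hi$species %in% set_lo$species))
  set_inf <- suppressWarnings(suspension_discriminants(sim$dataset, keepX = 100,
                                                       loading_threshold = Inf))
  expect_length(set_inf$species, 0L)
  # planted differentiation species dominate the set
  truth <- sim$truth$annotation[sim$truth$role %in% c("commitment", "differentiated")]
  expect_gt(mean(truth %in% set_lo$species), 0.8)
})

test_that("knockdown extraction unions timepoints and reports qualifying timepoint", {
  planted <- knockdown_truth_spec(n_elovl1 = 8, n_slc27a1 = 5, n_accumulated = 2,
                                  n_drift = 10, timepoints_effect = 72)
  sim <- simulate_knockdown(profile = default_lipidome_profile(n_species = 120),
                            planted = planted, seed = 32)
  set <- suppressWarnings(knockdown_discriminants(sim$datasets[["48"]], sim$datasets[["72"]],
                                                  target = "siELOVL1", keepX = 100))
  truth <- sim$truth$annotation[sim$truth$role == "siELOVL1"]
  found <- intersect(truth, set$species)
  expect_gt(length(found), 0)
  # effects planted only at 72 h must be recorded at 72 h
  recs <- set$records[set$records$species %in% found, ]
  expect_true(all(vapply(found, function(sp) 72 %in% recs$timepoint[recs$species == sp],
                         logical(1))))
  # missing treatment group errors
  ds_bad <- sim$datasets[["48"]]
  keep <- ds_bad$design$treatment != "siELOVL1"
  ds_bad$abundance <- ds_bad$abundance[keep, ]
  ds_bad$design <- ds_bad$design[keep, ]
  expect_error(knockdown_discriminants(ds_bad, sim$datasets[["72"]], target = "siELOVL1"),
               "missing treatment")
})

test_that("max fold change table applies the max rule and the Accumulated literal", {
  planted <- knockdown_truth_spec(n_elovl1 = 8, n_slc27a1 = 5, n_accumulated = 3,
                                  n_drift = 10)
  sim <- simulate_knockdown(profile = default_lipidome_profile(n_species = 120),
                            planted = planted, seed = 33)
  set <- suppressWarnings(knockdown_discriminants(sim$datasets[["48"]], sim$datasets[["72"]],
                                                  target = "siELOVL1", keepX = 100))
  tab <- max_fold_change_table(set, sim$datasets[["48"]], sim$datasets[["72"]],
                               target = "siELOVL1")
  acc_truth <- sim$truth$annotation[sim$truth$role == "siELOVL1_accumulated"]
  acc_rows <- tab[tab$species %in% acc_truth, ]
  expect_gt(nrow(acc_rows), 0)
  expect_true(all(is.infinite(acc_rows$max_fold_change)))
  expect_true(all(grepl("^Accumulated \\(48 and 72 h\\)$", acc_rows$label)))
  num <- tab[is.finite(tab$max_fold_change), ]
  expect_true(all(num$timepoint %in% c(48, 72)))
  # max rule recomputed by hand for one species
  sp <- num$species[1]
  fc48 <- enriched_by_mean(normalize_molpct(sim$datasets[["48"]]),
                           sim$datasets[["48"]]$design$treatment == "siELOVL1",
                           sim$datasets[["48"]]$design$treatment == "siScramble")
  fc72 <- enriched_by_mean(normalize_molpct(sim$datasets[["72"]]),
                           sim$datasets[["72"]]$design$treatment == "siELOVL1",
                           sim$datasets[["72"]]$design$treatment == "siScramble")
  expect_equal(num$max_fold_change[1],
               max(fc48$fold_change[fc48$species == sp],
                   fc72$fold_change[fc72$species == sp]))
})

test_that("set intersection is commutative, idempotent and bounded by its inputs", {
  recs <- function(sp, src) data.frame(species = sp, source = src, component = 1L,
                                       loading = 0.1, enriched_in = "x",
                                       timepoint = NA_real_, fold_change = 2,
                                       stringsAsFactors = FALSE)
  a <- lipidisc:::.new_discriminant_set(recs(c("Cer - 34:1:2", "Chol", "PC - 16:0:0;18:1:0"), "s1"))
  b <- lipidisc:::.new_discriminant_set(recs(c("Chol", "PC - 16:0:0;18:1:0", "SM - 34:1:2"), "s2"))
  ab <- intersect_sets(a, b)
  expect_setequal(ab$species, c("Chol", "PC - 16:0:0;18:1:0"))
  expect_equal(intersect_sets(b, a)$species, ab$species)
  expect_true(all(ab$species %in% a$species) && all(ab$species %in% b$species))
  expect_equal(intersect_sets(a, a)$species, a$species)
  disjoint <- lipidisc:::.new_discriminant_set(recs("TAG - 16:0:0;18:1:0;18:1:0", "s3"))
  expect_length(intersect_sets(a, disjoint)$species, 0L)
  # subset case
  sub <- lipidisc:::.new_discriminant_set(recs("Chol", "s4"))
  expect_equal(intersect_sets(sub, a)$species, sub$species)
})

test_that("discriminant TSV writer prints the Accumulated literal", {
  recs <- data.frame(species = c("a", "b"), source = "siELOVL1", component = 1L,
                     loading = c(0.2, 0.3), enriched_in = "siELOVL1",
                     timepoint = c(48, 72), fold_change = c(2.5, Inf),
                     stringsAsFactors = FALSE)
  set <- lipidisc:::.new_discriminant_set(recs)
  path <- file.path(tempdir(), "set.tsv")
  write_discriminant_set(set, path)
  out <- read.delim(path, stringsAsFactors = FALSE)
  expect_true("Accumulated" %in% out$fold_change)
})
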