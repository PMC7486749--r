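test_that("long-format reader builds the dataset and sums duplicates", {
  path <- write_long_fixture()
  ds <- read_lipidomics_table(path, layout = "long")
  expect_s3_class(ds, "lipidomics_dataset")
  expect_equal(dim(ds$abundance), c(2L, 3L))
  expect_equal(unname(ds$abundance["s1", "Cer - 34:1:2"]), 2)

  # duplicate rows are summed with a warning
  df <- data.frame(sample = "s1", lipid = c("Chol", "Chol"), pmol = c(1, 2))
  p2 <- file.path(tempdir(), "dup.tsv")
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ds2 <- read_lipidomics_table(p2, layout = "long"), "summed")
  expect_equal(unname(ds2$abundance[1, 1]), 3)

  # missing mandatory column
  p3 <- file.path(tempdir(), "bad.tsv")
  write.table(data.frame(sample = "s1", lipid = "Chol"), p3, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_lipidomics_table(p3, layout = "long"), "missing")
})

test_that("wide reader requires a matching design sidecar", {
  wide <- data.frame(lipid = c("Chol", "Cer - 34:1:2"), s1 = c(1, 2), s2 = c(3, 4))
  p <- file.path(tempdir(), "wide.tsv")
  write.table(wide, p, sep = "\t", quote = FALSE, row.names = FALSE)
  design <- data.frame(sample = c("s1", "s2"), experiment = "x",
                       timepoint = 0, treatment = "control", replicate = 1:2)
  ds <- read_lipidomics_table(p, layout = "wide", design = design)
  expect_equal(dim(ds$abundance), c(2L, 2L))
  expect_error(read_lipidomics_table(p, layout = "wide", design = design[1, ]),
               "absent from design")
})

test_that("round trip through the writer preserves the abundance matrix", {
  sim <- simulate_suspension(profile = default_lipidome_profile(n_species = 60),
                             planted = suspension_truth_spec(6, 2.5, 4, 3, 4, 3),
                             seed = 3)
  path <- file.path(tempdir(), "rt.tsv")
  paths <- write_lipidomics_table(sim$dataset, path)
  expect_silent(ds2 <- read_lipidomics_table(path, layout = "long", design = paths[2]))
  common <- colnames(sim$dataset$abundance)
  expect_equal(ds2$abundance[rownames(sim$dataset$abundance), common],
               sim$dataset$abundance, tolerance = 1e-8)
})

test_that("mol% normalization conserves 100 per sample and is scale invariant", {
  m <- rbind(s1 = c(2, 3, 5), s2 = c(1, 0, 3))
  colnames(m) <- c("a", "b", "c")
  mp <- normalize_molpct(m)
  expect_equal(unname(mp["s1", ]), c(20, 30, 50))
  expect_equal(unname(rowSums(mp)), c(100, 100), tolerance = 1e-9)
  # scale invariance
  m2 <- m; m2["s1", ] <- m2["s1", ] * 17.3
  expect_equal(normalize_molpct(m2)["s1", ], mp["s1", ], tolerance = 1e-12)
  # single species
  expect_equal(unname(normalize_molpct(matrix(5, 1, 1))[1, 1]), 100)
  # all-zero sample errors with its name
  m3 <- m; m3["s2", ] <- 0
  expect_error(normalize_molpct(m3), "s2")
})

test_that("class composition sums species mol% within classes to 100", {
  m <- rbind(s1 = c(30, 30, 40), s2 = c(10, 50, 40))
  colnames(m) <- c("Cer - 34:1:2", "Cer - 36:1:2", "PC - 16:0:0;18:1:0")
  comp <- class_composition(m)
  expect_equal(unname(comp["Cer", ]), c(60, 60))
  expect_equal(unname(comp["PC", ]), c(40, 40))
  expect_equal(unname(colSums(comp)), c(100, 100), tolerance = 1e-9)

  # group means/SDs recomputed by hand on a 4-sample fixture
  m4 <- rbind(a1 = c(60, 40), a2 = c(50, 50), b1 = c(20, 80), b2 = c(40, 60))
  colnames(m4) <- c("Cer - 34:1:2", "PC - 16:0:0;18:1:0")
  smry <- class_composition_summary(class_composition(m4), c("g1", "g1", "g2", "g2"))
  cer_g1 <- smry[smry$class == "Cer" & smry$group == "g1", ]
  expect_equal(cer_g1$mean, 55)
  expect_equal(cer_g1$sd, sd(c(60, 50)))
})

test_that("Z-scoring standardizes columns and handles constants per policy", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_warning(z <- zscore_by_species(m), "constant")
  expect_equal(colnames(z), c("a", "c"))
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_by_species(m, on_constant = "error"), "constant")
  expect_error(zscore_by_species(m[1, , drop = FALSE]), "at least 2")
})

test_that("near-zero-variance rule matches the reference filter", {
  set.seed(1)
  m <- cbind(const = rep(3, 40),
             almost = c(rep(1, 39), 2),
             spread = rnorm(40),
             steps = rep(1:8, each = 5))
  res <- remove_near_zero_variance(m)
  expect_setequal(res$removed, c("const", "almost"))
  expect_equal(colnames(res$matrix), c("spread", "steps"))

  # boundary: 19-of-20 equal gives freqRatio exactly 95/5 and 10% unique,
  # which the strict rule retains
  b <- cbind(x = c(rep(1, 19), 2), y = rnorm(20))
  expect_equal(remove_near_zero_variance(b)$removed, character(0))

  skip_if_not_installed("mixOmics")
  mo <- mixOmics::nearZeroVar(m)
  expect_setequal(colnames(m)[mo$Position], res$removed)

  # variance mode
  expect_equal(remove_near_zero_variance(m, rule = "variance")$removed, "const")
})

test_that("complete-linkage clustering reproduces closed forms and is order invariant", {
  pts <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("p0", "p1", "p10"), NULL))
  hc <- hierarchical_cluster(pts, axis = "samples")
  expect_equal(sort(hc$hclust$height), c(1, 10))

  dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 5))
  hcd <- hierarchical_cluster(dup)
  expect_equal(min(hcd$hclust$height), 0)

  set.seed(9)
  m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  h1 <- hierarchical_cluster(m)
  perm <- sample(8)
  h2 <- hierarchical_cluster(m[perm, ])
  expect_equal(sort(h1$hclust$height), sort(h2$hclust$height), tolerance = 1e-12)
  # deterministic leaf order: same label sequence regardless of input order
  expect_equal(h1$labels, h2$labels)
  expect_error(hierarchical_cluster(m * NA), "NaN/NA")
})

test_that("pca agrees with an SVD oracle and reconstructs the scaled matrix", {
  set.seed(11)
  m <- matrix(rnorm(5 * 8), 5, 8)
  res <- pca(m, ncomp = 4, scale = TRUE)
  xs <- scale(m)
  sv <- svd(xs)
  expl_oracle <- sv$d^2 / sum(sv$d^2)
  expect_equal(res$explained, expl_oracle[1:4], tolerance = 1e-10)
  for (k in 1:4)
    expect_equal(abs(sum(res$loadings[, k] * sv$v[, k])), 1, tolerance = 1e-8)
  # scores orthogonal
  g <- crossprod(res$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # full reconstruction
  recon <- res$scores %*% t(res$loadings)
  expect_lt(norm(recon - xs, "F") / norm(xs, "F"), 1e-8)
  # 2 samples -> one component carrying all variance
  m2 <- matrix(rnorm(2 * 6), 2, 6)
  expect_equal(pca(m2, ncomp = 1, scale = FALSE)$explained, 1, tolerance = 1e-12)
  expect_error(pca(m, ncomp = 10), "ncomp")
})
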