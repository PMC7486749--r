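test_that("dummy encoding is one-hot with lexicographic classes", {
  d <- dummy_encode(c("b", "a", "b"))
  expect_equal(d$classes, c("a", "b"))
  expect_equal(unname(d$dummy), rbind(c(0, 1), c(1, 0), c(0, 1)))
  expect_equal(unname(rowSums(d$dummy)), c(1, 1, 1))
  d4 <- dummy_encode(rep(c("adherent", "commitment", "differentiated", "inhibited"), 3))
  expect_equal(ncol(d4$dummy), 4L)
  expect_error(dummy_encode(rep("a", 5)), "at least 2")
})

test_that("dense two-class limit matches the cross-covariance oracle", {
  fx <- make_two_class_matrix(n_per_class = 3, p = 10, strong = 2, seed = 5)
  fit <- fit_splsda(fx$X, fx$labels, ncomp = 2, keepX = 10)
  X0 <- scale(fx$X)
  y <- scale(dummy_encode(fx$labels)$dummy, scale = FALSE)[, 1]
  oracle <- drop(crossprod(X0, y))
  oracle <- oracle / sqrt(sum(oracle^2))
  cosine <- abs(sum(fit$weights[, 1] * oracle))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("dense-limit weights align with the leading singular vector on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("s", 1:8), paste0("v", 1:12)))
    labels <- rep(c("A", "B"), each = 4)
    fit <- fit_splsda(X, labels, ncomp = 1, keepX = 12)
    M <- crossprod(scale(dummy_encode(labels)$dummy, scale = FALSE), scale(X))
    v1 <- svd(M)$v[, 1]
    expect_gt(abs(sum(fit$weights[, 1] * v1)), 1 - 1e-8)
  }
})

test_that("keepX = 1 selects the species with maximal |covariance| with the contrast", {
  for (seed in 1:10) {
    fx <- make_two_class_matrix(n_per_class = 3, p = 10, strong = 1,
                                effect = 3, seed = seed)
    fit <- fit_splsda(fx$X, fx$labels, ncomp = 1, keepX = 1)
    nz <- which(fit$weights[, 1] != 0)
    expect_length(nz, 1L)
    # brute-force oracle over scaled columns
    X0 <- scale(fx$X)
    y <- scale(dummy_encode(fx$labels)$dummy, scale = FALSE)[, 1]
    expect_equal(unname(nz), unname(which.max(abs(drop(crossprod(X0, y))))))
  }
})

test_that("sparsity contract: nonzero count equals min(keepX, p) per component", {
  fx <- make_two_class_matrix(n_per_class = 4, p = 20, strong = 3, seed = 2)
  fit <- fit_splsda(fx$X, fx$labels, ncomp = 2, keepX = c(5, 7))
  expect_equal(colSums(fit$weights != 0), c(comp1 = 5, comp2 = 7))
  expect_warning(fit2 <- fit_splsda(fx$X, fx$labels, ncomp = 1, keepX = 250),
                 "clamped")
  expect_equal(sum(fit2$weights != 0), 20)
  expect_error(fit_splsda(fx$X[1:2, ], fx$labels[1:2], ncomp = 1, keepX = 2),
               "at least 3")
})

test_that("deflation leaves residual X orthogonal to every extracted score", {
  fx <- make_two_class_matrix(n_per_class = 5, p = 15, strong = 3, seed = 8)
  labels <- rep(c("A", "B", "C", "D", "E"), each = 2)
  fit <- fit_splsda(fx$X, labels, ncomp = 3, keepX = 10)
  X0 <- scale(fx$X)
  Xres <- X0 - fit$scores %*% t(fit$loadings)
  expect_lt(max(abs(crossprod(fit$scores, Xres))), 1e-8)
  # scores mutually orthogonal in regression mode
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("fit is equivariant under sample permutation", {
  fx <- make_two_class_matrix(n_per_class = 4, p = 12, strong = 2, seed = 3)
  fit <- fit_splsda(fx$X, fx$labels, ncomp = 2, keepX = 6)
  perm <- sample(nrow(fx$X))
  fit2 <- fit_splsda(fx$X[perm, ], fx$labels[perm], ncomp = 2, keepX = 6)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-9)
  expect_equal(fit2$scores, fit$scores[perm, ], tolerance = 1e-9)
})

test_that("component orientation flips all blocks together and is idempotent", {
  fx <- make_two_class_matrix(n_per_class = 4, p = 12, strong = 2, seed = 4)
  fit <- fit_splsda(fx$X, fx$labels, ncomp = 1, keepX = 12)
  o1 <- orient_component(fit, 1, "B")
  expect_gte(mean(o1$scores[o1$labels == "B", 1]), 0)
  o2 <- orient_component(o1, 1, "B")
  expect_identical(o1$weights, o2$weights)
  # flipping consistency: weights and scores flip in tandem
  if (mean(fit$scores[fit$labels == "B", 1]) < 0) {
    expect_equal(o1$weights[, 1], -fit$weights[, 1])
    expect_equal(o1$scores[, 1], -fit$scores[, 1])
  }
  expect_error(orient_component(fit, 3, "B"), "out of range")
  expect_error(orient_component(fit, 1, "Z"), "not in model")
})

test_that("component loadings report the sparse vector and top-k listing", {
  fx <- make_two_class_matrix(n_per_class = 4, p = 20, strong = 2, seed = 6)
  fit <- fit_splsda(fx$X, fx$labels, ncomp = 1, keepX = 5)
  cl <- component_loadings(fit, 1, top = 3)
  expect_length(cl$loading, 20L)
  expect_equal(sum(cl$loading != 0), 5L)
  expect_equal(nrow(cl$top), 3L)
  expect_true(all(diff(abs(cl$top$loading)) <= 0))
  expect_error(component_loadings(fit, 2), "out of range")
})

test_that("agreement with the reference sPLS-DA on dense and strongly sparse fits", {
  skip_if_not_installed("mixOmics")
  fx <- make_two_class_matrix(n_per_class = 4, p = 12, strong = 3,
                              effect = 4, seed = 10)
  # dense limit: classical PLS-DA weights match up to sign
  fit <- fit_splsda(fx$X, fx$labels, ncomp = 1, keepX = 12)
  mo <- mixOmics::splsda(fx$X, factor(fx$labels), ncomp = 1, keepX = 12)
  cosine <- abs(sum(fit$weights[, 1] * mo$loadings$X[, 1]))
  expect_gt(cosine, 1 - 1e-6)
  # strong sparse toy: identical selection set
  fit3 <- fit_splsda(fx$X, fx$labels, ncomp = 1, keepX = 3)
  mo3 <- mixOmics::splsda(fx$X, factor(fx$labels), ncomp = 1, keepX = 3)
  expect_setequal(names(which(fit3$weights[, 1] != 0)),
                  rownames(mo3$loadings$X)[mo3$loadings$X[, 1] != 0])
})

test_that("planted four-class structure separates in score space", {
  skip_if_not_installed("cluster")
  sil <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed)
    n_class <- 4; n_rep <- 3; p <- 120
    labels <- rep(paste0("cl", 1:n_class), each = n_rep)
    X <- matrix(rnorm(n_class * n_rep * p), n_class * n_rep, p)
    # 10 species per class shifted by effect size 2
    for (k in 1:n_class) {
      cols <- (k - 1) * 10 + 1:10
      X[labels == paste0("cl", k), cols] <- X[labels == paste0("cl", k), cols] + 2
    }
    fit <- fit_splsda(X, labels, ncomp = 3, keepX = 40)
    d <- dist(fit$scores)
    sil[seed] <- mean(cluster::silhouette(as.integer(factor(labels)), d)[, 3])
  }
  expect_gt(mean(sil > 0.5), 0.9)
})
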