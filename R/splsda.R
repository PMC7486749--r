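# Sparse partial least squares discriminant analysis (sPLS-DA).
#
# NIPALS-style power iteration on the X/Y cross-covariance with per-component
# hard-threshold variable selection (keepX) and regression-mode deflation of
# both blocks on the X-score. Selection is pure: surviving weights keep their
# magnitude (no soft-threshold shrinkage); the selection set, not the weight
# magnitude, drives the downstream loading-threshold rules.

#' One-hot class design for discriminant analysis
#'
#' @param labels Vector of class labels, at least two distinct values,
#'   every class non-empty.
#' @return List with `labels`, `classes` (lexicographic) and `dummy`
#'   (samples x classes indicator matrix; each row sums to 1).
#' @export
dummy_encode <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 distinct class labels")
  dummy <- outer(labels, classes, `==`) + 0
  dimnames(dummy) <- list(names(labels), classes)
  list(labels = labels, classes = classes, dummy = dummy)
}

# keepX hard threshold with deterministic tie-break: keep the `keep` entries
# with largest |u|, preferring the smaller original index on exact ties.
.hard_threshold <- function(u, keep) {
  p <- length(u)
  if (keep >= p) return(u)
  ord <- order(-abs(u), seq_len(p))
  u[ord[(keep + 1L):p]] <- 0
  u
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Per component: (i) columns of X are centered and unit-scaled (first
#' component only; deflated blocks are reused thereafter) and the dummy Y is
#' centered; (ii) power iteration on the cross-covariance: `u` proportional
#' to `t(X) (Y v)`, hard-thresholded to its `keepX` largest absolute entries
#' and renormalized, then `v` proportional to `t(Y) (X u)`, renormalized;
#' (iii) score `t = X u`; (iv) X and Y are both deflated by regression on
#' `t`. The Y-weight is initialized from the first left singular vector of
#' `t(Y) X`, so the fit is deterministic and seed-free.
#'
#' @param X Samples x species numeric matrix (near-zero-variance columns
#'   should be removed first; constant columns are an error when
#'   `scale = TRUE`).
#' @param labels Class label per sample (or a [dummy_encode()] result).
#' @param ncomp Number of components.
#' @param keepX Integer vector (recycled to `ncomp`) of variables kept per
#'   component; clamped to `ncol(X)` with a warning.
#' @param scale Unit-variance scale X columns (default TRUE).
#' @param max_iter,tol Convergence controls for the power iteration
#'   (relative change in `u`).
#' @return Object of class `splsda_fit`: weights `u` (p x ncomp, sparse),
#'   regression loadings, scores (n x ncomp), `y_weights`, centering/scaling
#'   state, classes, and per-component `iterations`/`deltas`.
#' @export
fit_splsda <- function(X, labels, ncomp = 3L, keepX = 250L, scale = TRUE,
                       max_iter = 500L, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 samples")
  if (ncomp < 1L) stop("ncomp must be >= 1")
  design <- if (is.list(labels) && !is.null(labels$dummy)) labels else dummy_encode(labels)
  if (nrow(design$dummy) != n) stop("labels do not match rows of X")
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1L)) stop("keepX entries must be >= 1")
  if (any(keepX > p)) {
    warning(sprintf("keepX clamped from %d to %d species", max(keepX), p))
    keepX <- pmin(keepX, p)
  }

  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2L, stats::sd) else rep(1, p)
  if (any(x_scale <= 0))
    stop("constant columns in X; remove near-zero-variance species first")
  Xc <- scale(X, center = x_center, scale = x_scale)
  Y <- scale(design$dummy, center = TRUE, scale = FALSE)

  u_mat <- matrix(0, p, ncomp, dimnames = list(colnames(X), paste0("comp", seq_len(ncomp))))
  c_mat <- matrix(0, p, ncomp, dimnames = dimnames(u_mat))
  t_mat <- matrix(0, n, ncomp, dimnames = list(rownames(X), colnames(u_mat)))
  v_mat <- matrix(0, ncol(Y), ncomp, dimnames = list(design$classes, colnames(u_mat)))
  iters <- integer(ncomp); deltas <- numeric(ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(Y, Xc)                       # q x p cross-covariance
    v <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    u <- rep(0, p)
    for (it in seq_len(max_iter)) {
      u_old <- u
      u <- drop(crossprod(Xc, Y %*% v))
      u <- .hard_threshold(u, keepX[h])
      nu <- sqrt(sum(u^2))
      if (nu == 0) stop(sprintf("component %d collapsed to a zero weight vector", h))
      u <- u / nu
      v <- drop(crossprod(Y, Xc %*% u))
      v <- v / sqrt(sum(v^2))
      delta <- sqrt(sum((u - u_old)^2)) / max(sqrt(sum(u_old^2)), 1)
      if (delta < tol) break
    }
    if (delta >= tol)
      warning(sprintf("component %d did not converge in %d iterations (delta %.2e)",
                      h, max_iter, delta))
    iters[h] <- it; deltas[h] <- delta
    tt <- drop(Xc %*% u)
    tsq <- sum(tt^2)
    cvec <- drop(crossprod(Xc, tt)) / tsq
    dvec <- drop(crossprod(Y, tt)) / tsq
    Xc <- Xc - tcrossprod(tt, cvec)             # regression-mode deflation
    Y <- Y - tcrossprod(tt, dvec)
    u_mat[, h] <- u; c_mat[, h] <- cvec; t_mat[, h] <- tt; v_mat[, h] <- v
  }

  structure(list(ncomp = ncomp, keepX = keepX, weights = u_mat,
                 loadings = c_mat, scores = t_mat, y_weights = v_mat,
                 x_center = x_center, x_scale = x_scale, scale = scale,
                 classes = design$classes, labels = design$labels,
                 iterations = iters, deltas = deltas),
            class = "splsda_fit")
}

#' @export
print.splsda_fit <- function(x, ...) {
  cat(sprintf("<splsda_fit> %d samples, %d species, ncomp = %d, keepX = %s\n",
              nrow(x$scores), nrow(x$weights), x$ncomp,
              paste(x$keepX, collapse = ",")))
  invisible(x)
}

#' Fix the sign of a component against a reference class
#'
#' The sign of any PLS component is arbitrary; this flips weights, loadings,
#' scores and Y-weights together so that the mean score of the reference
#' class on the component is non-negative (a mean of exactly 0 is left
#' unchanged). Applying it twice is a no-op.
#'
#' @param model An `splsda_fit`.
#' @param comp Component index.
#' @param reference_class Class whose mean score must be >= 0.
#' @return The model with the component possibly sign-flipped.
#' @export
orient_component <- function(model, comp, reference_class) {
  if (comp < 1L || comp > model$ncomp) stop("comp out of range")
  if (!reference_class %in% model$classes)
    stop(sprintf("class '%s' not in model", reference_class))
  m <- mean(model$scores[model$labels == reference_class, comp])
  if (m < 0) {
    model$weights[, comp] <- -model$weights[, comp]
    model$loadings[, comp] <- -model$loadings[, comp]
    model$scores[, comp] <- -model$scores[, comp]
    model$y_weights[, comp] <- -model$y_weights[, comp]
  }
  model
}

#' Per-species loadings of a component
#'
#' Returns the sparse weight vector on the original species index (zeros for
#' unselected species) together with the top-k species by absolute loading,
#' the listing behind "most discriminant species" bar plots.
#'
#' @param model An `splsda_fit`.
#' @param comp Component index (error when out of range).
#' @param top Number of top species to list (default 50).
#' @return List with `loading` (named numeric, all species) and `top`
#'   (data frame `species`, `loading`, sorted by |loading| descending).
#' @export
component_loadings <- function(model, comp, top = 50L) {
  if (comp < 1L || comp > model$ncomp)
    stop(sprintf("comp %d out of range (model has %d)", comp, model$ncomp))
  w <- model$weights[, comp]
  nz <- which(w != 0)
  ord <- nz[order(-abs(w[nz]), nz)]
  k <- min(top, length(ord))
  list(loading = w,
       top = data.frame(species = names(w)[ord[seq_len(k)]],
                        loading = unname(w[ord[seq_len(k)]]),
                        stringsAsFactors = FALSE))
}
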