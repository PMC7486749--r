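# Lipidomics dataset container, normalization and matrix-level operations.

#' Construct a lipidomics dataset
#'
#' @param abundance Numeric samples x species matrix of pmol amounts
#'   (non-negative; rownames are sample ids, colnames are annotations).
#' @param design Data frame with one row per sample: `sample_id`,
#'   `experiment`, `timepoint`, `treatment`, `replicate` and optionally
#'   `class_label`.
#' @param species Optional list of parsed `lipid_species` matching the
#'   columns; parsed from the colnames when omitted.
#' @return Object of class `lipidomics_dataset`.
#' @export
lipidomics_dataset <- function(abundance, design, species = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundance matrix has negative entries")
  if (nrow(design) != nrow(abundance))
    stop("design rows do not match abundance rows")
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design")
  rownames(abundance) <- design$sample_id
  if (is.null(species)) species <- parse_species_annotation(colnames(abundance))
  if (inherits(species, "lipid_species")) species <- list(species)
  if (length(species) != ncol(abundance))
    stop("species list does not match abundance columns")
  structure(list(abundance = abundance, design = design, species = species),
            class = "lipidomics_dataset")
}

#' @export
print.lipidomics_dataset <- function(x, ...) {
  cat(sprintf("<lipidomics_dataset> %d samples x %d species (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(unique(x$design$experiment), collapse = ", ")))
  invisible(x)
}

#' Read a lipidomics abundance table
#'
#' Long layout: columns `sample`, `lipid`, optional `class`, `pmol`.
#' Duplicate (sample, lipid) rows are summed with a warning; missing pairs
#' are zeros (shotgun lipidomics reports only detected species). Wide layout:
#' species rows x sample columns with a `lipid` first column, plus a design
#' sidecar TSV (`sample`, `experiment`, `timepoint`, `treatment`,
#' `replicate`).
#'
#' @param path Delimited text file (TSV or CSV, sniffed from the extension).
#' @param layout `"long"` or `"wide"`.
#' @param design Data frame or sidecar path with the sample design; optional
#'   for long layout (a minimal design is derived from the sample ids).
#' @return A [lipidomics_dataset()].
#' @export
read_lipidomics_table <- function(path, layout = c("long", "wide"), design = NULL) {
  layout <- match.arg(layout)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (is.character(design)) {
    design <- utils::read.table(design, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  if (layout == "long") {
    need <- c("sample", "lipid", "pmol")
    if (!all(need %in% names(tab)))
      stop(sprintf("long layout needs columns %s; missing: %s",
                   paste(need, collapse = ", "),
                   paste(setdiff(need, names(tab)), collapse = ", ")))
    bad <- which(is.na(suppressWarnings(as.numeric(tab$pmol))))
    if (length(bad))
      stop(sprintf("non-numeric pmol at row(s) %s", paste(utils::head(bad, 5), collapse = ", ")))
    parsed <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      parsed[[i]] <- tryCatch(parse_species_annotation(tab$lipid[i]),
                              error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE))
    }
    key <- format_species(parsed)
    samples <- unique(tab$sample)
    lipids <- unique(key)
    mat <- matrix(0, length(samples), length(lipids),
                  dimnames = list(samples, lipids))
    if (anyDuplicated(paste(tab$sample, key)))
      warning("duplicate (sample, lipid) rows summed")
    for (i in seq_len(nrow(tab)))
      mat[tab$sample[i], key[i]] <- mat[tab$sample[i], key[i]] + as.numeric(tab$pmol[i])
    if (is.null(design))
      design <- data.frame(sample_id = samples, experiment = "unknown",
                           timepoint = NA_real_, treatment = NA_character_,
                           replicate = NA_integer_, stringsAsFactors = FALSE)
    else design <- .match_design(design, samples)
    species <- parse_species_annotation(lipids)
    if (inherits(species, "lipid_species")) species <- list(species)
  } else {
    if (is.null(design)) stop("wide layout requires a design sidecar")
    if (!"lipid" %in% names(tab)) stop("wide layout needs a 'lipid' column")
    samples <- setdiff(names(tab), "lipid")
    design <- .match_design(design, samples)
    mat <- t(as.matrix(tab[, samples, drop = FALSE]))
    mat[is.na(mat)] <- 0
    colnames(mat) <- tab$lipid
    species <- parse_species_annotation(tab$lipid)
    colnames(mat) <- format_species(species)
    rownames(mat) <- samples
  }
  lipidomics_dataset(mat, design, species)
}

.match_design <- function(design, samples) {
  if ("sample" %in% names(design) && !"sample_id" %in% names(design))
    names(design)[names(design) == "sample"] <- "sample_id"
  missing <- setdiff(samples, design$sample_id)
  if (length(missing))
    stop(sprintf("samples absent from design sidecar: %s", paste(missing, collapse = ", ")))
  design[match(samples, design$sample_id), , drop = FALSE]
}

#' Write a lipidomics dataset as a long-format TSV
#'
#' @param ds A [lipidomics_dataset()].
#' @param path Output TSV path; a design sidecar is written next to it with
#'   suffix `_design.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_lipidomics_table <- function(ds, path) {
  ab <- ds$abundance
  long <- data.frame(sample = rep(rownames(ab), times = ncol(ab)),
                     lipid = rep(colnames(ab), each = nrow(ab)),
                     pmol = as.vector(ab), stringsAsFactors = FALSE)
  long <- long[long$pmol > 0, ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dpath <- sub("(\\.[a-zA-Z]+)?$", "_design.tsv", path)
  utils::write.table(ds$design, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, dpath))
}

#' Normalize abundances to mol percent of total sample lipid
#'
#' Each sample row is divided by its total pmol and multiplied by 100, so
#' every row sums to 100. Scaling a sample's amounts by any positive constant
#' leaves its mol% unchanged.
#'
#' @param ds A [lipidomics_dataset()] or non-negative samples x species matrix.
#' @return Matrix of mol% values, same shape and dimnames.
#' @export
normalize_molpct <- function(ds) {
  mat <- if (inherits(ds, "lipidomics_dataset")) ds$abundance else as.matrix(ds)
  totals <- rowSums(mat)
  zero <- totals <= 0
  if (any(zero))
    stop(sprintf("sample(s) with zero total lipid: %s",
                 paste(rownames(mat)[zero], collapse = ", ")))
  100 * mat / totals
}

#' Class-level composition table
#'
#' Sums mol% over the species of each lipid class; per sample the class
#' values sum to 100.
#'
#' @param mp Mol% matrix (samples x species, colnames are canonical
#'   annotations).
#' @return Matrix classes x samples of mol% values.
#' @export
class_composition <- function(mp) {
  cls <- vapply(parse_species_annotation(colnames(mp)), `[[`, "", "lipid_class")
  out <- t(rowsum(t(mp), group = cls))
  t(out)
}

#' Group summary of a class composition table
#'
#' Mean and SD of each class's mol% within groups of samples (for example
#' timepoint x treatment), the numbers behind a class-level time-course plot.
#'
#' @param comp Classes x samples matrix from [class_composition()].
#' @param groups Factor/character of group labels, one per sample.
#' @return Data frame with `class`, `group`, `mean`, `sd`, `n`.
#' @export
class_composition_summary <- function(comp, groups) {
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(rownames(comp), function(cl) {
    do.call(rbind, lapply(unique(groups), function(g) {
      v <- comp[cl, groups == g]
      data.frame(class = cl, group = g, mean = mean(v),
                 sd = stats::sd(v), n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Z-score species across samples
#'
#' Standardizes each species column to mean 0, SD 1 (sample SD, n-1
#' denominator). Zero-SD species are dropped with a warning by default, or
#' raise an error with `on_constant = "error"`.
#'
#' @param mp Samples x species matrix (mol% by default in this pipeline).
#' @param on_constant `"drop"` or `"error"`.
#' @return Z-score matrix (possibly fewer columns).
#' @export
zscore_by_species <- function(mp, on_constant = c("drop", "error")) {
  on_constant <- match.arg(on_constant)
  if (nrow(mp) < 2L) stop("Z-scoring needs at least 2 samples")
  sds <- apply(mp, 2L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    if (on_constant == "error")
      stop(sprintf("constant species: %s", paste(colnames(mp)[const], collapse = ", ")))
    warning(sprintf("dropping %d constant species before Z-scoring", sum(const)))
    mp <- mp[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  scale(mp, center = TRUE, scale = sds)
}

#' Remove near-zero-variance species
#'
#' Default rule (matching the filter used by the multivariate toolchain this
#' pipeline mirrors): a column is removed when the frequency ratio of its
#' most common to second most common value exceeds 95/5 AND the fraction of
#' distinct values is below 10%; zero-variance columns are always removed.
#' `rule = "variance"` instead removes columns with variance below `tol`.
#'
#' @param mat Samples x species numeric matrix.
#' @param rule `"freq"` (default) or `"variance"`.
#' @param freq_cut,unique_cut Thresholds for the frequency rule.
#' @param tol Variance threshold for the variance rule.
#' @return List with `matrix` (reduced), `removed` (colnames) and `reasons`.
#' @export
remove_near_zero_variance <- function(mat, rule = c("freq", "variance"),
                                      freq_cut = 95 / 5, unique_cut = 10,
                                      tol = 1e-12) {
  rule <- match.arg(rule)
  reasons <- character(0)
  if (rule == "variance") {
    v <- apply(mat, 2L, stats::var)
    drop <- v < tol
    reasons <- rep("variance below tolerance", sum(drop))
  } else {
    drop <- logical(ncol(mat))
    reasons <- character(ncol(mat))
    for (j in seq_len(ncol(mat))) {
      tab <- sort(table(mat[, j]), decreasing = TRUE)
      if (length(tab) == 1L) {
        drop[j] <- TRUE
        reasons[j] <- "zero variance"
        next
      }
      freq_ratio <- tab[1L] / tab[2L]
      pct_unique <- 100 * length(tab) / nrow(mat)
      if (freq_ratio > freq_cut && pct_unique < unique_cut) {
        drop[j] <- TRUE
        reasons[j] <- sprintf("freqRatio %.1f, %.1f%% unique", freq_ratio, pct_unique)
      }
    }
    reasons <- reasons[drop]
  }
  list(matrix = mat[, !drop, drop = FALSE],
       removed = colnames(mat)[drop],
       reasons = reasons)
}

#' Hierarchical clustering with deterministic leaf order
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (the convention of the heat maps this pipeline reproduces). Leaves are
#' reordered so that at every merge the subtree containing the smaller
#' original index comes first, making the leaf order reproducible across
#' input permutations (up to the inherent mirror ambiguity, which this rule
#' resolves).
#'
#' @param mat Numeric matrix.
#' @param axis Cluster `"samples"` (rows) or `"species"` (columns).
#' @return List with `hclust` (an [stats::hclust] object), `order`
#'   (deterministic leaf order, original indices) and `labels`.
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "species")) {
  axis <- match.arg(axis)
  x <- if (axis == "species") t(mat) else mat
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  if (anyNA(x)) stop("NaN/NA entries in clustering input")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
  ord <- .deterministic_leaf_order(hc$merge, hc$labels)
  hc$order <- ord
  list(hclust = hc, order = ord, labels = rownames(x)[ord])
}

# Leaf order: recurse the merge table, putting the child subtree whose
# smallest item (lexicographically by label, falling back to index) comes
# first, so the order is reproducible across input permutations.
.deterministic_leaf_order <- function(merge, labels = NULL) {
  key <- function(idx) {
    if (is.null(labels)) as.character(min(idx)) else min(labels[idx])
  }
  leaves <- function(k) {
    if (k < 0) return(-k)
    a <- leaves(merge[k, 1L])
    b <- leaves(merge[k, 2L])
    if (key(a) <= key(b)) c(a, b) else c(b, a)
  }
  leaves(nrow(merge))
}

#' Principal component analysis with explained variance
#'
#' Columns are mean-centered and, when `scale = TRUE`, unit-variance scaled
#' before the decomposition (via [stats::prcomp]).
#'
#' @param mat Samples x variables matrix.
#' @param ncomp Number of components; must be at most
#'   `min(nrow - 1, ncol)`.
#' @param scale Unit-variance scale columns (default TRUE).
#' @return List with `scores`, `loadings`, `explained` (fractions of total
#'   variance, non-increasing) and `center`/`scale` vectors.
#' @export
pca <- function(mat, ncomp = 2L, scale = TRUE) {
  maxc <- min(nrow(mat) - 1L, ncol(mat))
  if (ncomp < 1L || ncomp > maxc)
    stop(sprintf("ncomp must be in 1..%d", maxc))
  pr <- stats::prcomp(mat, center = TRUE, scale. = scale)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(ncomp), drop = FALSE],
       loadings = pr$rotation[, seq_len(ncomp), drop = FALSE],
       explained = expl[seq_len(ncomp)],
       center = pr$center,
       scale = if (scale) pr$scale else NULL)
}
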