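# Discriminant lipid nomination: loading-threshold + enrichment rules,
# fold-change reports and cross-experiment intersection.

#' Sentinel for fold changes with an undetectable control
#'
#' When a species is absent from the control condition but present after a
#' perturbation, no numeric fold change exists; reports print the literal
#' `"Accumulated"`. Internally the value is `Inf`.
#' @export
ACCUMULATED <- "Accumulated"

#' Assign suspension-model class labels
#'
#' The four-class model of suspension-induced differentiation: 0 h samples
#' are "adherent" (whatever the arm); untreated samples at 4/8 h are
#' "commitment" and at 12/24 h "differentiated"; all PKCi-treated samples
#' after 0 h are "inhibited".
#'
#' @param design Data frame with `timepoint` (hours) and `treatment`
#'   (`"control"` or `"PKCi"`).
#' @return The design with a `class_label` column added.
#' @export
assign_suspension_classes <- function(design) {
  tp <- design$timepoint
  tr <- design$treatment
  lab <- ifelse(tp == 0, "adherent",
         ifelse(tr == "PKCi", "inhibited",
         ifelse(tr == "control" & tp %in% c(4, 8), "commitment",
         ifelse(tr == "control" & tp %in% c(12, 24), "differentiated", NA))))
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1L]
    stop(sprintf("unknown (timepoint, treatment) combination: (%s h, %s)",
                 tp[bad], tr[bad]))
  }
  design$class_label <- lab
  design
}

#' Class-median enrichment test
#'
#' A species is enriched in the target class when its median mol% in that
#' class strictly exceeds the median of every other class
#' (`mode = "pooled"` compares against the pooled remaining samples instead).
#'
#' @param mp Samples x species mol% matrix.
#' @param labels Class label per sample.
#' @param target_class Class tested for enrichment.
#' @param mode `"each"` (strict superiority over every other class, default)
#'   or `"pooled"`.
#' @return Named logical vector over species.
#' @export
enriched_by_class_median <- function(mp, labels, target_class,
                                     mode = c("each", "pooled")) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  if (!target_class %in% labels) stop(sprintf("class '%s' has no samples", target_class))
  in_t <- labels == target_class
  med_t <- apply(mp[in_t, , drop = FALSE], 2L, stats::median)
  if (mode == "pooled") {
    med_o <- apply(mp[!in_t, , drop = FALSE], 2L, stats::median)
    return(med_t > med_o)
  }
  others <- setdiff(unique(labels), target_class)
  ok <- rep(TRUE, ncol(mp))
  for (cl in others) {
    med_o <- apply(mp[labels == cl, , drop = FALSE], 2L, stats::median)
    ok <- ok & (med_t > med_o)
  }
  stats::setNames(ok, colnames(mp))
}

#' Group-mean enrichment and fold change
#'
#' Fold change is `mean(groupA) / mean(groupB)` on mol%; a species is
#' enriched when the fold change exceeds 1. A positive group-A mean over a
#' zero control mean yields `enriched = TRUE` with `fold_change = Inf`
#' (reported as the Accumulated sentinel); two zero means yield
#' `enriched = FALSE` with `fold_change = NaN`.
#'
#' @param mp Samples x species mol% matrix.
#' @param groupA,groupB Logical or integer sample indices (both non-empty).
#' @return Data frame `species`, `enriched`, `fold_change`.
#' @export
enriched_by_mean <- function(mp, groupA, groupB) {
  a <- mp[groupA, , drop = FALSE]
  b <- mp[groupB, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  ma <- colMeans(a); mb <- colMeans(b)
  fc <- ifelse(mb == 0 & ma > 0, Inf, ifelse(mb == 0 & ma == 0, NaN, ma / mb))
  data.frame(species = colnames(mp),
             enriched = !is.nan(fc) & fc > 1,
             fold_change = fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

.new_discriminant_set <- function(records) {
  records <- records[order(records$species, records$component), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, species = sort(unique(records$species))),
            class = "discriminant_set")
}

#' @export
print.discriminant_set <- function(x, ...) {
  cat(sprintf("<discriminant_set> %d unique species, %d records (%s)\n",
              length(x$species), nrow(x$records),
              paste(unique(x$records$source), collapse = ", ")))
  invisible(x)
}

#' Discriminant lipids of suspension-induced differentiation
#'
#' Fits a 3-component sPLS-DA (keepX species per component) on the mol%
#' matrix under the four-class suspension model, then nominates the species
#' with |loading| above the threshold on component 2 that are
#' median-enriched in the "differentiated" class, united with those above
#' threshold on component 3 that are median-enriched in "commitment".
#' Components are oriented against their class before signs are reported,
#' and the rule itself uses absolute loadings plus the enrichment direction,
#' so it is independent of component sign conventions.
#'
#' @param ds A [lipidomics_dataset()] of the suspension experiment (labels
#'   are assigned via [assign_suspension_classes()] when absent).
#' @param ncomp,keepX sPLS-DA parameters (defaults 3 and 250).
#' @param loading_threshold Absolute loading cutoff (default 0.01).
#' @param enrichment_mode Passed to [enriched_by_class_median()].
#' @return A `discriminant_set`; records carry component, loading,
#'   enriched-in class and the class-vs-rest mean fold change.
#' @export
suspension_discriminants <- function(ds, ncomp = 3L, keepX = 250L,
                                     loading_threshold = 0.01,
                                     enrichment_mode = "each") {
  design <- ds$design
  if (is.null(design$class_label) || anyNA(design$class_label))
    design <- assign_suspension_classes(design)
  mp <- normalize_molpct(ds)
  nz <- remove_near_zero_variance(mp)
  fit <- fit_splsda(nz$matrix, design$class_label, ncomp = ncomp, keepX = keepX)
  fit <- orient_component(fit, 2L, "differentiated")
  fit <- orient_component(fit, 3L, "commitment")

  rules <- list(list(comp = 2L, class = "differentiated"),
                list(comp = 3L, class = "commitment"))
  recs <- list()
  for (r in rules) {
    w <- fit$weights[, r$comp]
    enr <- enriched_by_class_median(mp, design$class_label, r$class,
                                    mode = enrichment_mode)
    sel <- names(w)[abs(w) > loading_threshold]
    sel <- sel[enr[sel]]
    if (!length(sel)) next
    in_cl <- design$class_label == r$class
    fc <- enriched_by_mean(mp[, sel, drop = FALSE], in_cl, !in_cl)
    recs[[length(recs) + 1L]] <- data.frame(
      species = sel, source = "suspension", component = r$comp,
      loading = unname(w[sel]), enriched_in = r$class, timepoint = NA_real_,
      fold_change = fc$fold_change, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(.new_discriminant_set(data.frame(species = character(0), source = character(0),
                                            component = integer(0), loading = numeric(0),
                                            enriched_in = character(0), timepoint = numeric(0),
                                            fold_change = numeric(0), stringsAsFactors = FALSE)))
  .new_discriminant_set(do.call(rbind, recs))
}

#' Discriminant lipids of a knockdown time course
#'
#' Fits one 3-component sPLS-DA per timepoint (48 h and 72 h) on mol% with
#' treatment labels, then nominates species with |loading| above threshold
#' on the relevant components that are mean-enriched in the target treatment
#' versus the scrambled control at that timepoint. For `siELOVL1` the
#' relevant components are 1 and 2; for `siSLC27A1` component 2 only (a
#' literal reading of the extraction rule; set `components` to override).
#' The set is the union over components and timepoints.
#'
#' @param ds48,ds72 [lipidomics_dataset()]s of the 48 h and 72 h samples
#'   (treatments `siScramble`, `siELOVL1`, `siSLC27A1`).
#' @param target `"siELOVL1"` or `"siSLC27A1"`.
#' @param control Control treatment label (default `"siScramble"`).
#' @param components Components searched; defaults per target as above.
#' @param ncomp,keepX,loading_threshold As in [suspension_discriminants()].
#' @return A `discriminant_set`; records carry the timepoint and fold change
#'   at which each species qualified (`Inf` = accumulated).
#' @export
knockdown_discriminants <- function(ds48, ds72, target = c("siELOVL1", "siSLC27A1"),
                                    control = "siScramble", components = NULL,
                                    ncomp = 3L, keepX = 250L,
                                    loading_threshold = 0.01) {
  target <- match.arg(target)
  if (is.null(components))
    components <- if (target == "siELOVL1") c(1L, 2L) else 2L
  datasets <- list(`48` = ds48, `72` = ds72)
  recs <- list()
  for (tp in names(datasets)) {
    ds <- datasets[[tp]]
    if (!all(c(target, control) %in% ds$design$treatment))
      stop(sprintf("missing treatment group at %s h", tp))
    mp <- normalize_molpct(ds)
    nz <- remove_near_zero_variance(mp)
    fit <- fit_splsda(nz$matrix, ds$design$treatment, ncomp = ncomp, keepX = keepX)
    enr <- enriched_by_mean(mp, ds$design$treatment == target,
                            ds$design$treatment == control)
    enr_ok <- stats::setNames(enr$enriched, enr$species)
    fc <- stats::setNames(enr$fold_change, enr$species)
    for (cp in components) {
      fit <- orient_component(fit, cp, target)
      w <- fit$weights[, cp]
      sel <- names(w)[abs(w) > loading_threshold]
      sel <- sel[enr_ok[sel]]
      if (!length(sel)) next
      recs[[length(recs) + 1L]] <- data.frame(
        species = sel, source = target, component = cp,
        loading = unname(w[sel]), enriched_in = target,
        timepoint = as.numeric(tp), fold_change = unname(fc[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(.new_discriminant_set(data.frame(species = character(0), source = character(0),
                                            component = integer(0), loading = numeric(0),
                                            enriched_in = character(0), timepoint = numeric(0),
                                            fold_change = numeric(0), stringsAsFactors = FALSE)))
  .new_discriminant_set(do.call(rbind, recs))
}

#' Maximum fold-change report for a knockdown discriminant set
#'
#' For every species in the set, the fold change (target vs control mean
#' mol%) is computed at both timepoints and the maximum is reported with its
#' timepoint. A species undetectable in the control while present in the
#' target prints the `"Accumulated"` sentinel with the timepoints at which
#' that applies.
#'
#' @param set A `discriminant_set` from [knockdown_discriminants()].
#' @param ds48,ds72 The timepoint datasets.
#' @param target,control Treatment labels.
#' @return Data frame `species`, `max_fold_change` (numeric, `Inf` when
#'   accumulated), `timepoint` and `label` (printable, e.g. `"8.3 (72 h)"`
#'   or `"Accumulated (48 and 72 h)"`).
#' @export
max_fold_change_table <- function(set, ds48, ds72, target = NULL,
                                  control = "siScramble") {
  if (is.null(target)) target <- unique(set$records$source)[1L]
  fcs <- lapply(list(`48` = ds48, `72` = ds72), function(ds) {
    mp <- normalize_molpct(ds)
    e <- enriched_by_mean(mp, ds$design$treatment == target,
                          ds$design$treatment == control)
    stats::setNames(e$fold_change, e$species)
  })
  out <- do.call(rbind, lapply(set$species, function(sp) {
    v <- c(`48` = unname(fcs[["48"]][sp]), `72` = unname(fcs[["72"]][sp]))
    acc <- names(v)[is.infinite(v)]
    if (length(acc)) {
      lab <- sprintf("%s (%s h)", ACCUMULATED, paste(acc, collapse = " and "))
      data.frame(species = sp, max_fold_change = Inf,
                 timepoint = as.numeric(acc[1L]), label = lab,
                 stringsAsFactors = FALSE)
    } else {
      v <- v[!is.nan(v)]
      i <- which.max(v)
      data.frame(species = sp, max_fold_change = unname(v[i]),
                 timepoint = as.numeric(names(v)[i]),
                 label = sprintf("%.3g (%s h)", v[i], names(v)[i]),
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Intersect two discriminant sets
#'
#' Species are compared by canonical annotation (class plus chain
#' descriptors; aliases ignored). Records from both sources are kept for the
#' shared species.
#'
#' @param a,b `discriminant_set` objects.
#' @return A `discriminant_set` over the shared species.
#' @export
intersect_sets <- function(a, b) {
  common <- intersect(a$species, b$species)
  recs <- rbind(a$records[a$records$species %in% common, , drop = FALSE],
                b$records[b$records$species %in% common, , drop = FALSE])
  if (!nrow(recs))
    recs <- a$records[0, , drop = FALSE]
  .new_discriminant_set(recs)
}

#' Write a discriminant set as TSV
#'
#' Fold changes of `Inf` print as the `"Accumulated"` literal.
#'
#' @param set A `discriminant_set`.
#' @param path Output TSV path.
#' @export
write_discriminant_set <- function(set, path) {
  recs <- set$records
  recs$fold_change <- ifelse(is.infinite(recs$fold_change), ACCUMULATED,
                             format(recs$fold_change, digits = 6))
  utils::write.table(recs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
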