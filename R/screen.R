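# Plate-based siRNA screen scoring: modified Z-scores, per-plate fold
# changes, replicate QC and volcano-style hit calling.

#' Modified Z-score
#'
#' Robust standardization `z = c * (x - median) / MAD`, with the raw median
#' absolute deviation (no 1.4826 rescaling) and the Iglewicz-Hoaglin
#' consistency constant c = 0.6745 by default, so that `median(z) = 0` and
#' `median(|z|) = c`. The constant only rescales the values and can be set
#' to 1.
#'
#' @param values Numeric vector (>= 3 values, non-degenerate).
#' @param constant Consistency constant (default 0.6745).
#' @return Numeric vector of modified Z-scores.
#' @export
modified_zscore <- function(values, constant = 0.6745) {
  if (length(values) < 3L) stop("need at least 3 values")
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) stop("MAD is zero for this normalization unit")
  constant * (values - med) / mad_raw
}

#' Validate a screen well table
#'
#' @param screen Data frame with columns `plate`, `well`, `target`, `role`
#'   (`test`, `nontargeting`, `no_siRNA`, `positive_control`), `condition`,
#'   `replicate`, `readout` (fraction of marker-positive cells in 0..1).
#' @return The table, invisibly, after checks.
#' @export
validate_screen <- function(screen) {
  need <- c("plate", "well", "target", "role", "condition", "replicate", "readout")
  miss <- setdiff(need, names(screen))
  if (length(miss)) stop(sprintf("screen table missing columns: %s", paste(miss, collapse = ", ")))
  if (any(screen$readout < 0 | screen$readout > 1))
    stop("readouts must be fractions in [0, 1]")
  bad <- !screen$role %in% c("test", "nontargeting", "no_siRNA", "positive_control")
  if (any(bad)) stop(sprintf("unknown role(s): %s", paste(unique(screen$role[bad]), collapse = ", ")))
  invisible(screen)
}

#' Pool culture conditions through per-condition modified Z-scores
#'
#' The modified Z-score is computed within each culture condition (the
#' normalization unit, so each condition's location and spread are removed
#' before pooling), or per plate with `unit = "plate"`.
#'
#' @param screen Screen well table (see [validate_screen()]).
#' @param unit `"condition"` (default) or `"plate"`.
#' @param constant Passed to [modified_zscore()].
#' @return The table with a `z` column added.
#' @export
pool_conditions <- function(screen, unit = c("condition", "plate"),
                            constant = 0.6745) {
  unit <- match.arg(unit)
  validate_screen(screen)
  key <- if (unit == "condition") screen$condition else screen$plate
  screen$z <- NA_real_
  for (u in unique(key)) {
    idx <- key == u
    if (sum(idx) < 3L) stop(sprintf("normalization unit '%s' has fewer than 3 wells", u))
    screen$z[idx] <- tryCatch(modified_zscore(screen$readout[idx], constant),
                              error = function(e) stop(sprintf("unit '%s': %s", u, conditionMessage(e)), call. = FALSE))
  }
  screen
}

#' Per-plate fold changes against nontargeting controls
#'
#' Each well's readout is divided by the mean readout of the nontargeting
#' wells on the same plate; per-target fold changes for reporting are the
#' mean over that target's wells (i.e. computed per replicate, then averaged).
#'
#' @param screen Screen well table.
#' @return The table with an `fc` column added.
#' @export
plate_fold_change <- function(screen) {
  validate_screen(screen)
  screen$fc <- NA_real_
  for (pl in unique(screen$plate)) {
    idx <- screen$plate == pl
    ctrl <- screen$readout[idx & screen$role == "nontargeting"]
    if (!length(ctrl)) stop(sprintf("plate '%s' has no nontargeting wells", pl))
    m <- mean(ctrl)
    if (m == 0) stop(sprintf("plate '%s' control mean is zero", pl))
    screen$fc[idx] <- screen$readout[idx] / m
  }
  screen
}

#' Replicate concordance (Pearson r against the replicate mean)
#'
#' For each replicate, the Pearson correlation across targets between its
#' mean Z-score and the mean Z-score over all replicates.
#'
#' @param screen Screen table with a `z` column (see [pool_conditions()]).
#' @return Named numeric vector, one r per replicate.
#' @export
replicate_correlation <- function(screen) {
  if (is.null(screen$z)) screen <- pool_conditions(screen)
  test <- screen[screen$role == "test", ]
  reps <- sort(unique(test$replicate))
  if (length(reps) < 2L) stop("need at least 2 replicates")
  targets <- sort(unique(test$target))
  zmat <- matrix(NA_real_, length(targets), length(reps),
                 dimnames = list(targets, reps))
  for (i in seq_along(reps)) {
    sub <- test[test$replicate == reps[i], ]
    zmat[, i] <- tapply(sub$z, factor(sub$target, levels = targets), mean)
  }
  overall <- rowMeans(zmat)
  if (stats::sd(overall) == 0) stop("zero variance in replicate-mean Z")
  r <- apply(zmat, 2L, function(v) stats::cor(v, overall))
  stats::setNames(r, paste0("rep", reps))
}

#' Call screen hits from pooled Z-scores and per-plate fold changes
#'
#' Per test target: a two-sided Welch t test of the target wells' pooled
#' Z-scores against the nontargeting wells of the same plates, and the mean
#' per-well fold change. A target is an inducer when `p < alpha` and
#' `fc > fc_high` (strict), an inhibitor when `p < alpha` and `fc < fc_low`.
#' Positive-control and no-siRNA wells take no part in calling. Targets with
#' fewer than 2 usable wells are reported uncalled (`call = NA`).
#'
#' @param screen Screen well table.
#' @param fc_low,fc_high Fold-change thresholds (defaults 0.6 and 2.5).
#' @param alpha Significance level (default 0.05).
#' @param constant Modified Z-score constant.
#' @return Data frame `target`, `mean_z`, `fold_change`, `p_value`, `call`
#'   (`"inducer"`, `"inhibitor"`, `"none"` or NA), one row per target.
#' @export
call_hits <- function(screen, fc_low = 0.6, fc_high = 2.5, alpha = 0.05,
                      constant = 0.6745) {
  if (is.null(screen$z)) screen <- pool_conditions(screen, constant = constant)
  if (is.null(screen$fc)) screen <- plate_fold_change(screen)
  test <- screen[screen$role == "test", ]
  ctrl <- screen[screen$role == "nontargeting", ]
  out <- do.call(rbind, lapply(sort(unique(test$target)), function(tg) {
    tw <- test[test$target == tg, ]
    cw <- ctrl[ctrl$plate %in% tw$plate, ]
    fc <- mean(tw$fc)
    mz <- mean(tw$z)
    if (nrow(tw) < 2L || stats::sd(c(tw$z, cw$z)) == 0) {
      return(data.frame(target = tg, mean_z = mz, fold_change = fc,
                        p_value = NA_real_, call = NA_character_,
                        stringsAsFactors = FALSE))
    }
    p <- stats::t.test(tw$z, cw$z)$p.value
    call <- if (p < alpha && fc > fc_high) "inducer"
            else if (p < alpha && fc < fc_low) "inhibitor"
            else "none"
    data.frame(target = tg, mean_z = mz, fold_change = fc, p_value = p,
               call = call, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
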