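#' Quantile threshold from pooled control cells
#'
#' Both gating thresholds of the pipeline come from this one rule: the
#' transfection threshold is the empirical quantile (default 0.995) of
#' pooled `fp_cell` values of mock-transfected cells, and the surface-stain
#' threshold is the same quantile of pooled `ab_cell` values of cells
#' expressing an untagged construct. Pooling is across all biological
#' replicates. By construction the fraction of control cells strictly above
#' the threshold is at most `1 - quantile` — the bound on falsely calling a
#' control cell positive.
#'
#' Empirical quantiles use linear interpolation between order statistics
#' (R's default, type 7); the convention is fixed so thresholds are
#' reproducible.
#'
#' @param control_values Numeric vector of pooled control intensities.
#' @param quantile Fraction in (0, 1); default 0.995.
#' @return Scalar threshold.
#' @export
compute_threshold <- function(control_values, quantile = 0.995) {
  if (length(control_values) == 0) {
    stop("cannot compute a threshold from an empty control set")
  }
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1) {
    stop("quantile must be a single number in (0, 1)")
  }
  if (length(control_values) < 100) {
    warning("fewer than 100 control cells; threshold will be noisy")
  }
  unname(stats::quantile(control_values, probs = quantile, type = 7,
                         names = FALSE))
}

#' Derive both gating thresholds from control samples
#'
#' @param mock_fp Pooled `fp_cell` values from mock-transfected samples
#'   (all replicates).
#' @param untagged_ab Pooled `ab_cell` values from untagged-construct
#'   samples (all replicates).
#' @inheritParams compute_threshold
#' @return An object of class `surface_thresholds` with elements `t_fp`,
#'   `t_ab`, `quantile`, `n_mock_cells`, `n_untagged_cells`.
#' @export
surface_thresholds <- function(mock_fp, untagged_ab, quantile = 0.995) {
  structure(
    list(t_fp = compute_threshold(mock_fp, quantile),
         t_ab = compute_threshold(untagged_ab, quantile),
         quantile = quantile,
         n_mock_cells = length(mock_fp),
         n_untagged_cells = length(untagged_ab)),
    class = "surface_thresholds")
}

#' @export
print.surface_thresholds <- function(x, ...) {
  cat(sprintf(
    "Gating thresholds (%.4g quantile of pooled controls)\n", x$quantile))
  cat(sprintf("  transfection threshold (FPcell): %.6g  [%d mock cells]\n",
              x$t_fp, x$n_mock_cells))
  cat(sprintf("  surface-stain threshold (Abcell): %.6g  [%d untagged cells]\n",
              x$t_ab, x$n_untagged_cells))
  invisible(x)
}

#' Flag transfected cells
#'
#' A cell is transfected when its `fp_cell` strictly exceeds the
#' transfection threshold. All downstream metrics use only transfected,
#' non-saturated cells.
#'
#' @param cells Cell table (see [quantify_field()]); saturated cells should
#'   already be excluded.
#' @param t_fp Transfection threshold.
#' @return The table with a logical `transfected` column set.
#' @export
flag_transfected <- function(cells, t_fp) {
  cells$transfected <- cells$fp_cell > t_fp
  cells
}

#' Fraction of transfected cells with measurable surface staining (f+)
#'
#' The fraction of cells in `table` (already filtered to transfected cells)
#' whose `ab_cell` strictly exceeds the surface-stain threshold.
#'
#' @param table Cell table filtered to transfected cells, or a numeric
#'   vector of `ab_cell` values.
#' @param t_ab Surface-stain threshold.
#' @return Fraction in \[0, 1\]; `NA` when there are no transfected cells
#'   (f+ is then undefined, not zero).
#' @export
fraction_stained <- function(table, t_ab) {
  ab <- if (is.numeric(table)) table else table$ab_cell
  if (length(ab) == 0) return(NA_real_)
  mean(ab > t_ab)
}

#' Mean surface signal of transfected cells (Ab-bar)
#'
#' The plain mean of `ab_cell` over transfected cells, negative values
#' included — proportional to the average surface protein concentration.
#'
#' @inheritParams fraction_stained
#' @return Scalar mean; `NA` for an empty table.
#' @export
mean_surface_signal <- function(table) {
  ab <- if (is.numeric(table)) table else table$ab_cell
  if (length(ab) == 0) return(NA_real_)
  mean(ab)
}

#' Normalize a surface signal to a positive-control reference
#'
#' @param value Raw mean surface signal.
#' @param reference Mean Ab-bar of the designated positive-control sample
#'   across replicates; must be positive.
#' @return `value / reference`.
#' @export
normalize_ab <- function(value, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || is.na(reference) ||
      reference <= 0) {
    stop("reference must be a single positive number")
  }
  value / reference
}

#' Shared expression-bin edges
#'
#' Defines the bin edges over `fp_cell` used for every sample's
#' dose-response curve. `log_spaced` (default) places `n_bins` bins
#' geometrically between the minimum and maximum of the pooled values;
#' `equal_count` places edges at quantiles so each bin holds an equal share
#' of the pooled cells (which yields approximately log-scaled bins for
#' lognormal-like expression). Pooling is over all transfected cells across
#' samples and replicates, so every sample shares the same edges.
#'
#' Non-positive values cannot enter log spacing; they are dropped here (and
#' excluded from the dose-response fit only — they still count toward f+
#' and Ab-bar).
#'
#' @param pooled_fp Numeric vector: `fp_cell` of all transfected cells.
#' @param n_bins Number of bins (default 20).
#' @param mode `"log_spaced"` or `"equal_count"`.
#' @return Object of class `dose_bins`: list with `edges` (length
#'   `n_bins + 1`, strictly increasing), `n_bins`, `mode`, `n_dropped`
#'   (non-positive values removed).
#' @export
define_bins <- function(pooled_fp, n_bins = 20,
                        mode = c("log_spaced", "equal_count")) {
  mode <- match.arg(mode)
  if (n_bins < 2) stop("n_bins must be at least 2")
  keep <- pooled_fp[!is.na(pooled_fp) & pooled_fp > 0]
  n_dropped <- length(pooled_fp) - length(keep)
  if (length(keep) < n_bins) {
    stop("need at least n_bins positive fp values to define bins")
  }
  edges <- switch(mode,
    log_spaced = exp(seq(log(min(keep)), log(max(keep)),
                         length.out = n_bins + 1)),
    equal_count = unname(stats::quantile(keep,
                                         probs = seq(0, 1, length.out = n_bins + 1),
                                         type = 7, names = FALSE)))
  # guard against floating-point wobble at the extremes
  edges[1] <- min(keep)
  edges[n_bins + 1] <- max(keep)
  if (any(diff(edges) <= 0)) {
    stop("bin edges are not strictly increasing; use fewer bins")
  }
  structure(list(edges = edges, n_bins = n_bins, mode = mode,
                 n_dropped = n_dropped),
            class = "dose_bins")
}

#' @export
print.dose_bins <- function(x, ...) {
  cat(sprintf("%d %s bins over [%.6g, %.6g]", x$n_bins,
              gsub("_", "-", x$mode), x$edges[1], x$edges[x$n_bins + 1]))
  if (x$n_dropped > 0) {
    cat(sprintf("  (%d non-positive values excluded)", x$n_dropped))
  }
  cat("\n")
  invisible(x)
}

#' Assign values to bins
#'
#' Bins are half-open `[e_i, e_{i+1})`; the last bin is closed at the top so
#' the pooled maximum belongs to a bin. Values outside the edge range (or
#' non-positive under log spacing) get `NA`.
#'
#' @param x Numeric values (`fp_cell`).
#' @param bins A [define_bins()] object or a numeric vector of edges.
#' @return Integer bin index per value (1..n_bins) or `NA`.
#' @export
bin_assign <- function(x, bins) {
  edges <- if (inherits(bins, "dose_bins")) bins$edges else bins
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx == 0 | idx > length(edges) - 1 | is.na(x)] <- NA_integer_
  idx
}

#' Per-sample binned dose-response means
#'
#' For one sample's transfected cells, the mean `fp_cell` (FPbin) and mean
#' `ab_cell` (Abbin) within each shared expression bin, with cell counts.
#'
#' @param table Cell table filtered to transfected cells of one
#'   sample-replicate.
#' @param bins A [define_bins()] object.
#' @return `data.frame` with columns `bin`, `fp_bin`, `ab_bin`, `n`
#'   (one row per bin; empty bins have `n = 0` and `NA` means).
#' @export
binned_dose <- function(table, bins) {
  idx <- bin_assign(table$fp_cell, bins)
  nb <- if (inherits(bins, "dose_bins")) bins$n_bins else length(bins) - 1
  f <- factor(idx, levels = seq_len(nb))
  n <- as.integer(table(f))
  fp_bin <- as.numeric(tapply(table$fp_cell, f, mean))
  ab_bin <- as.numeric(tapply(table$ab_cell, f, mean))
  data.frame(bin = seq_len(nb), fp_bin = fp_bin, ab_bin = ab_bin, n = n)
}

#' Surface-delivery efficiency from binned dose-response means
#'
#' Ordinary least-squares regression of `log(ab_bin)` on `log(fp_bin)`
#' (natural logarithms; the slope is invariant to the base and to
#' multiplicative rescaling of either channel). The slope is Esurface: 1
#' means surface signal grows proportionally with expression, 0 means no
#' expression dependence. Bins with non-positive `ab_bin` or `fp_bin`, or
#' with no cells, are excluded since their logarithm is undefined.
#'
#' @param fp_bin,ab_bin Numeric vectors of per-bin means.
#' @return List with `slope`, `intercept` (natural-log scale), `stderr`
#'   (standard error of the slope), `n_bins_used`, `n_bins_excluded`.
#'   `slope` is `NA` with a diagnostic attribute when fewer than 2 usable
#'   bins remain.
#' @export
fit_esurface <- function(fp_bin, ab_bin) {
  stopifnot(length(fp_bin) == length(ab_bin))
  use <- !is.na(fp_bin) & !is.na(ab_bin) & fp_bin > 0 & ab_bin > 0
  n_used <- sum(use)
  if (n_used < 2) {
    out <- list(slope = NA_real_, intercept = NA_real_, stderr = NA_real_,
                n_bins_used = n_used,
                n_bins_excluded = length(fp_bin) - n_used)
    attr(out, "diagnostic") <- "fewer than 2 bins with positive means"
    return(out)
  }
  x <- log(fp_bin[use])
  y <- log(ab_bin[use])
  fit <- stats::lm(y ~ x)
  # slope SE computed directly (avoids summary.lm noise on zero-residual fits)
  se <- if (n_used > 2) {
    sqrt(sum(stats::residuals(fit)^2) / (n_used - 2) /
           sum((x - mean(x))^2))
  } else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       stderr = se,
       n_bins_used = n_used,
       n_bins_excluded = length(fp_bin) - n_used)
}

#' Metrics for one sample-replicate
#'
#' Computes f+, the mean surface signal (raw and, when a reference is
#' given, normalized) and Esurface for the transfected cells of a single
#' sample-replicate. This is the per-sample worker behind
#' [surface_delivery()].
#'
#' @param table Cell table of one sample-replicate with `saturated` cells
#'   still present or already removed (they are removed here).
#' @param thresholds A [surface_thresholds()] object.
#' @param bins A [define_bins()] object (shared across samples).
#' @param reference Optional positive scalar: the positive-control mean
#'   Ab-bar used to normalize.
#' @return One-row `data.frame` (fields of the sample metrics record).
#' @export
sample_metrics <- function(table, thresholds, bins, reference = NULL) {
  stopifnot(inherits(thresholds, "surface_thresholds"))
  if ("saturated" %in% names(table)) table <- table[!table$saturated, ]
  table <- flag_transfected(table, thresholds$t_fp)
  tr <- table[table$transfected, ]
  f_plus <- fraction_stained(tr, thresholds$t_ab)
  ab_mean <- mean_surface_signal(tr)
  ab_mean_norm <- if (!is.null(reference)) normalize_ab(ab_mean, reference) else NA_real_
  bd <- binned_dose(tr, bins)
  fit <- fit_esurface(bd$fp_bin, bd$ab_bin)
  data.frame(
    sample_id = if (nrow(table)) table$sample_id[1] else NA_character_,
    replicate_id = if (nrow(table)) table$replicate_id[1] else NA_character_,
    f_plus = f_plus,
    ab_mean = ab_mean,
    ab_mean_norm = ab_mean_norm,
    e_surface = fit$slope,
    fit_intercept = fit$intercept,
    fit_stderr = fit$stderr,
    n_transfected = nrow(tr),
    n_bins_used = fit$n_bins_used,
    stringsAsFactors = FALSE)
}
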