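#' Fit surface-delivery metrics to a per-cell table
#'
#' The central estimator of the package. Given a cell table covering one or
#' more samples and biological replicates, it (1) removes saturated cells,
#' (2) gates transfected cells at the control-derived FPcell threshold, (3)
#' defines shared expression bins from the pooled transfected cells, and
#' (4) computes, per sample-replicate, the stained-cell fraction f+, the
#' mean surface signal Ab-bar (optionally normalized to a positive
#' control), and the surface-delivery efficiency Esurface — the slope of
#' the least-squares line through (log FPbin, log Abbin).
#'
#' @param cells Cell table: columns `sample_id`, `replicate_id`, `fp_cell`,
#'   `ab_cell`, optional `saturated` (see [quantify_field()] or
#'   [simulate_cell_table()]).
#' @param thresholds A [surface_thresholds()] object, or a list of the raw
#'   control values as `list(mock_fp = ..., untagged_ab = ...)` from which
#'   thresholds are derived at `quantile`.
#' @param bins Optional [define_bins()] object. When `NULL`, bins are
#'   defined here from the pooled transfected cells of all samples.
#' @param n_bins,bin_mode Used only when `bins` is `NULL`.
#' @param reference Positive-control reference for normalizing Ab-bar:
#'   either a `sample_id` present in `cells` (its replicate-mean Ab-bar is
#'   used), a positive number, or `NULL` to skip normalization.
#' @param quantile Quantile for threshold derivation when raw controls are
#'   supplied.
#' @return An object of class `surface_delivery`; see
#'   [summary.surface_delivery()], [coef.surface_delivery()],
#'   [plot.surface_delivery()], [predict.surface_delivery()].
#' @examples
#' sim <- simulate_cell_table(sample_id = "gC3", n_cells = 2000, seed = 1)
#' ctl <- simulate_controls(n_cells = 2000, seed = 2)
#' fit <- surface_delivery(sim$cells,
#'                         thresholds = list(mock_fp = ctl$mock$fp_cell,
#'                                           untagged_ab = ctl$untagged$ab_cell))
#' summary(fit)
#' @export
surface_delivery <- function(cells, thresholds, bins = NULL, n_bins = 20,
                             bin_mode = c("log_spaced", "equal_count"),
                             reference = NULL, quantile = 0.995) {
  bin_mode <- match.arg(bin_mode)
  cl <- match.call()
  req <- c("sample_id", "replicate_id", "fp_cell", "ab_cell")
  if (!all(req %in% names(cells))) {
    stop("cells must have columns ", paste(req, collapse = ", "))
  }
  if (is.list(thresholds) && !inherits(thresholds, "surface_thresholds")) {
    if (!all(c("mock_fp", "untagged_ab") %in% names(thresholds))) {
      stop("thresholds must be a surface_thresholds object or ",
           "list(mock_fp=, untagged_ab=)")
    }
    thresholds <- surface_thresholds(thresholds$mock_fp,
                                     thresholds$untagged_ab, quantile)
  }
  stopifnot(inherits(thresholds, "surface_thresholds"))

  n_saturated <- 0L
  if ("saturated" %in% names(cells)) {
    n_saturated <- sum(cells$saturated)
    cells <- cells[!cells$saturated, ]
  }
  cells <- flag_transfected(cells, thresholds$t_fp)

  if (is.null(bins)) {
    bins <- define_bins(cells$fp_cell[cells$transfected], n_bins = n_bins,
                        mode = bin_mode)
  }
  stopifnot(inherits(bins, "dose_bins"))

  key <- interaction(cells$sample_id, cells$replicate_id, drop = TRUE,
                     sep = "\r")
  groups <- split(cells, key)
  # stable order: by sample then replicate
  ord <- order(vapply(groups, function(g) g$sample_id[1], ""),
               vapply(groups, function(g) g$replicate_id[1], ""))
  groups <- groups[ord]

  metrics <- do.call(rbind, lapply(groups, sample_metrics,
                                   thresholds = thresholds, bins = bins,
                                   reference = NULL))
  rownames(metrics) <- NULL

  ref_value <- NULL
  if (!is.null(reference)) {
    if (is.character(reference)) {
      sel <- metrics$sample_id == reference
      if (!any(sel)) stop("reference sample '", reference, "' not in cells")
      ref_value <- mean(metrics$ab_mean[sel])
    } else {
      ref_value <- reference
    }
    metrics$ab_mean_norm <- normalize_ab(metrics$ab_mean, ref_value)
  }

  dose <- lapply(groups, function(g) {
    tr <- g[g$transfected, ]
    binned_dose(tr, bins)
  })
  names(dose) <- vapply(groups, function(g)
    paste(g$sample_id[1], g$replicate_id[1], sep = "/"), "")

  structure(
    list(metrics = metrics, thresholds = thresholds, bins = bins,
         dose = dose, reference = ref_value, n_saturated = n_saturated,
         call = cl),
    class = "surface_delivery")
}

#' @export
print.surface_delivery <- function(x, digits = 3, ...) {
  cat("Surface-delivery fit:",
      nrow(x$metrics), "sample-replicate(s),",
      sum(x$metrics$n_transfected), "transfected cells\n")
  print(x$thresholds)
  print(x$bins)
  if (x$n_saturated > 0) {
    cat(sprintf("  %d saturated cells excluded\n", x$n_saturated))
  }
  df <- x$metrics[, c("sample_id", "replicate_id", "f_plus", "ab_mean",
                      "e_surface")]
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summarize a surface-delivery fit
#'
#' Replicate-level means and standard deviations of f+, Ab-bar and
#' Esurface per sample — the quantities plotted and compared between
#' constructs.
#'
#' @param object A [surface_delivery()] fit.
#' @param ... Unused.
#' @return A `data.frame` of class `summary.surface_delivery` with one row
#'   per sample.
#' @method summary surface_delivery
#' @export
summary.surface_delivery <- function(object, ...) {
  m <- object$metrics
  agg <- function(v) {
    mu <- tapply(v, m$sample_id, mean)
    sd <- tapply(v, m$sample_id, stats::sd)
    list(mean = as.numeric(mu), sd = as.numeric(sd),
         id = names(mu))
  }
  f <- agg(m$f_plus); a <- agg(m$ab_mean); e <- agg(m$e_surface)
  out <- data.frame(
    sample_id = f$id,
    n_replicates = as.integer(table(m$sample_id)[f$id]),
    f_plus = f$mean, f_plus_sd = f$sd,
    ab_mean = a$mean, ab_mean_sd = a$sd,
    e_surface = e$mean, e_surface_sd = e$sd,
    stringsAsFactors = FALSE)
  if (!is.null(object$reference)) {
    out$ab_mean_norm <- out$ab_mean / object$reference
  }
  rownames(out) <- NULL
  class(out) <- c("summary.surface_delivery", "data.frame")
  out
}

#' @export
print.summary.surface_delivery <- function(x, digits = 3, ...) {
  cat("Per-sample surface-delivery metrics (replicate mean +/- SD)\n")
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Esurface coefficients of a surface-delivery fit
#'
#' @param object A [surface_delivery()] fit.
#' @param ... Unused.
#' @return Named numeric vector of Esurface slopes, one per
#'   sample-replicate (`sample/replicate` names).
#' @method coef surface_delivery
#' @export
coef.surface_delivery <- function(object, ...) {
  stats::setNames(object$metrics$e_surface,
                  paste(object$metrics$sample_id,
                        object$metrics$replicate_id, sep = "/"))
}

#' Predicted surface signal at given expression levels
#'
#' Evaluates each sample-replicate's fitted power law
#' `ab = exp(intercept) * fp^slope` at new FPcell values.
#'
#' @param object A [surface_delivery()] fit.
#' @param newdata Numeric vector of `fp_cell` values (must be positive).
#' @param ... Unused.
#' @return Matrix with one row per `newdata` value and one column per
#'   sample-replicate.
#' @method predict surface_delivery
#' @export
predict.surface_delivery <- function(object, newdata, ...) {
  if (missing(newdata)) {
    newdata <- exp(seq(log(object$bins$edges[1]),
                       log(max(object$bins$edges)), length.out = 50))
  }
  stopifnot(all(newdata > 0))
  m <- object$metrics
  out <- vapply(seq_len(nrow(m)), function(i) {
    exp(m$fit_intercept[i] + m$e_surface[i] * log(newdata))
  }, numeric(length(newdata)))
  out <- matrix(out, nrow = length(newdata))
  colnames(out) <- paste(m$sample_id, m$replicate_id, sep = "/")
  rownames(out) <- NULL
  out
}

#' Log-log residuals of the dose-response fits
#'
#' @param object A [surface_delivery()] fit.
#' @param ... Unused.
#' @return List (one element per sample-replicate) of residuals
#'   `log(ab_bin) - fitted` over the bins used in each fit.
#' @method residuals surface_delivery
#' @export
residuals.surface_delivery <- function(object, ...) {
  m <- object$metrics
  out <- lapply(seq_len(nrow(m)), function(i) {
    bd <- object$dose[[i]]
    use <- !is.na(bd$fp_bin) & !is.na(bd$ab_bin) & bd$fp_bin > 0 & bd$ab_bin > 0
    log(bd$ab_bin[use]) -
      (m$fit_intercept[i] + m$e_surface[i] * log(bd$fp_bin[use]))
  })
  names(out) <- names(object$dose)
  out
}

#' Dose-response plot of a surface-delivery fit
#'
#' Binned means (points) and fitted power laws (lines) on log-log axes,
#' one color per sample-replicate.
#'
#' @param x A [surface_delivery()] fit.
#' @param ... Passed to [graphics::plot()].
#' @method plot surface_delivery
#' @export
plot.surface_delivery <- function(x, ...) {
  pts <- do.call(rbind, lapply(seq_along(x$dose), function(i) {
    bd <- x$dose[[i]]
    use <- !is.na(bd$fp_bin) & !is.na(bd$ab_bin) & bd$fp_bin > 0 & bd$ab_bin > 0
    if (!any(use)) return(NULL)
    data.frame(fp = bd$fp_bin[use], ab = bd$ab_bin[use], grp = i)
  }))
  if (is.null(pts) || nrow(pts) == 0) {
    stop("no positive binned means to plot")
  }
  cols <- grDevices::hcl.colors(max(pts$grp), "Dark 3")
  graphics::plot(pts$fp, pts$ab, log = "xy", col = cols[pts$grp], pch = 16,
                 xlab = "FPbin (AU)", ylab = "Abbin (AU)", ...)
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$e_surface[i])) next
    fp <- exp(seq(log(min(pts$fp)), log(max(pts$fp)), length.out = 50))
    graphics::lines(fp, exp(m$fit_intercept[i] + m$e_surface[i] * log(fp)),
                    col = cols[i])
  }
  graphics::legend("topleft", legend = names(x$dose), col = cols[seq_len(nrow(m))],
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
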