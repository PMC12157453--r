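# Brute-force oracles kept deliberately naive and independent of the
# package implementation paths they check.

# Per-label mean of background-subtracted pixels via an explicit double
# loop (column-major, matching R's storage order so equality is exact).
oracle_cell_means <- function(image, mask, background) {
  labels <- sort(unique(mask[mask > 0]))
  out <- stats::setNames(numeric(length(labels)), labels)
  for (li in seq_along(labels)) {
    vals <- numeric(0)
    for (j in seq_len(ncol(image))) {
      for (i in seq_len(nrow(image))) {
        if (mask[i, j] == labels[li]) {
          vals <- c(vals, image[i, j] - background)
        }
      }
    }
    out[li] <- mean(vals)
  }
  out
}

# Type-7 quantile recomputed from sorted order statistics.
oracle_quantile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Welch statistic, degrees of freedom and p from the formulas.
oracle_welch <- function(a, b, alternative = "greater") {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- switch(alternative,
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p)
}

# A small dense cell table with a fixed power-law dose-response and
# degenerate expression levels (one distinct fp value per eventual bin).
make_degenerate_table <- function(k, a = 2, n_levels = 20, copies = 50,
                                  sample_id = "s") {
  fp <- rep(10 * (100)^((seq_len(n_levels) - 1) / (n_levels - 1)),
            each = copies)
  data.frame(sample_id = sample_id, replicate_id = "r1", field_id = "x",
             cell_id = seq_along(fp), fp_cell = fp, ab_cell = a * fp^k,
             saturated = FALSE, stringsAsFactors = FALSE)
}

fixed_thresholds <- function(t_fp = 1, t_ab = 1) {
  structure(list(t_fp = t_fp, t_ab = t_ab, quantile = 0.995,
                 n_mock_cells = 0L, n_untagged_cells = 0L),
            class = "surface_thresholds")
}
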