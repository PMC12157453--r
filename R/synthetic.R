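#' Simulate a per-cell fluorescence table
#'
#' Generates a cell table with the statistical structure the metrics
#' assume: untransfected cells draw their FPcell from a narrow
#' background-subtracted distribution centered on zero; transfected cells
#' draw FPcell from a lognormal (the expression spread of transient
#' transfection); a `stained_fraction` of transfected cells follow an
#' approximately power-law dose-response
#' `ab = a * fp^k * exp(sigma * z)` with multiplicative lognormal noise,
#' while the remaining transfected cells (and all untransfected ones) show
#' only additive background around zero in the Ab channel. Ground-truth
#' labels are returned alongside so downstream estimates can be scored.
#'
#' @param sample_id,replicate_id Identifiers written into the table.
#' @param n_cells Total cells.
#' @param transfected_fraction Fraction of cells that are transfected.
#' @param fp_meanlog,fp_sdlog Lognormal parameters of transfected FPcell
#'   (arbitrary units).
#' @param dose_amplitude,dose_exponent Power-law parameters `a` and `k`.
#' @param noise_sigma Multiplicative lognormal noise (SD of `log` Ab).
#' @param stained_fraction Fraction of transfected cells with any surface
#'   signal.
#' @param mock_sigma SD of untransfected FPcell around 0.
#' @param background_sigma SD of background Ab around 0.
#' @param seed Integer; fixed seed gives bit-identical output. The caller's
#'   RNG state is left untouched.
#' @return List: `cells` (standard cell-table `data.frame`, `saturated`
#'   all `FALSE`), `truth` (`data.frame` with logical `transfected`,
#'   `stained`), `params`.
#' @export
simulate_cell_table <- function(sample_id = "sample", replicate_id = "r1",
                                n_cells = 10000, transfected_fraction = 0.5,
                                fp_meanlog = log(500), fp_sdlog = 1.0,
                                dose_amplitude = 0.5, dose_exponent = 0.8,
                                noise_sigma = 0.3, stained_fraction = 0.85,
                                mock_sigma = 15, background_sigma = 15,
                                seed = NULL) {
  stopifnot(n_cells >= 1,
            transfected_fraction >= 0, transfected_fraction <= 1,
            stained_fraction >= 0, stained_fraction <= 1,
            noise_sigma >= 0, mock_sigma >= 0, background_sigma >= 0,
            dose_amplitude > 0)
  gen <- function() {
    transfected <- stats::runif(n_cells) < transfected_fraction
    stained <- transfected & stats::runif(n_cells) < stained_fraction
    fp <- numeric(n_cells)
    fp[!transfected] <- stats::rnorm(sum(!transfected), 0, mock_sigma)
    fp[transfected] <- stats::rlnorm(sum(transfected), fp_meanlog, fp_sdlog)
    ab <- stats::rnorm(n_cells, 0, background_sigma)
    ab[stained] <- dose_amplitude * fp[stained]^dose_exponent *
      exp(noise_sigma * stats::rnorm(sum(stained)))
    list(
      cells = data.frame(
        sample_id = sample_id, replicate_id = replicate_id,
        field_id = "sim", cell_id = seq_len(n_cells),
        fp_cell = fp, ab_cell = ab, saturated = FALSE,
        stringsAsFactors = FALSE),
      truth = data.frame(cell_id = seq_len(n_cells),
                         transfected = transfected, stained = stained),
      params = list(transfected_fraction = transfected_fraction,
                    dose_amplitude = dose_amplitude,
                    dose_exponent = dose_exponent,
                    noise_sigma = noise_sigma,
                    stained_fraction = stained_fraction))
  }
  if (is.null(seed)) gen() else .with_local_seed(seed, gen())
}

#' Simulate mock-transfected and untagged-construct control tables
#'
#' The mock sample has only untransfected-like cells (FP and Ab both
#' background); the untagged sample expresses like a transfected sample in
#' FP but, lacking the extracellular epitope, shows only background Ab.
#' These are the samples the gating thresholds are derived from.
#'
#' @inheritParams simulate_cell_table
#' @return List of two cell tables: `mock` and `untagged` (with `sample_id`
#'   `"mock"` / `"untagged"`).
#' @export
simulate_controls <- function(n_cells = 10000, replicate_id = "r1",
                              fp_meanlog = log(500), fp_sdlog = 1.0,
                              mock_sigma = 15, background_sigma = 15,
                              seed = NULL) {
  gen <- function() {
    mock <- simulate_cell_table("mock", replicate_id, n_cells,
                                transfected_fraction = 0,
                                mock_sigma = mock_sigma,
                                background_sigma = background_sigma)$cells
    untagged <- simulate_cell_table("untagged", replicate_id, n_cells,
                                    transfected_fraction = 1,
                                    stained_fraction = 0,
                                    fp_meanlog = fp_meanlog,
                                    fp_sdlog = fp_sdlog,
                                    mock_sigma = mock_sigma,
                                    background_sigma = background_sigma)$cells
    list(mock = mock, untagged = untagged)
  }
  if (is.null(seed)) gen() else .with_local_seed(seed, gen())
}

#' Simulate a microscope field of view
#'
#' Places non-overlapping disk-shaped cells of constant per-cell intensity
#' on a constant background level, in both channels, and optionally plants
#' saturated pixels in chosen cells. Because every cell and the background
#' are piecewise constant, the quantified background-subtracted means
#' equal the ground truth exactly, which makes this the reference fixture
#' for the image-quantification path.
#'
#' @param field_id Field identifier.
#' @param size Integer pair: image dimensions (rows, columns).
#' @param n_cells Number of disks to place.
#' @param radius_range Integer pair: min/max disk radius in pixels.
#' @param background_level Constant background intensity added everywhere.
#' @param fp_range,ab_range Ranges the constant per-cell intensities
#'   (above background) are drawn from.
#' @param saturation_value Channel saturation code for both channels.
#' @param saturate_cells Integer vector of cell ids that get one planted
#'   saturated pixel in the FP channel.
#' @param max_tries Placement retries before giving up.
#' @param seed Integer seed (caller's RNG state untouched).
#' @return List: `fov` (a [field_of_view()]), `truth` (`data.frame` with
#'   `cell_id`, `fp`, `ab` — the true background-subtracted means before
#'   any planted saturated pixel), `saturate_cells`.
#' @export
simulate_field <- function(field_id = "f1", size = c(96, 96), n_cells = 5,
                           radius_range = c(4, 8), background_level = 100,
                           fp_range = c(200, 3000), ab_range = c(50, 1500),
                           saturation_value = 65535,
                           saturate_cells = integer(0),
                           max_tries = 200, seed = NULL) {
  gen <- function() {
    nr <- size[1]; nc <- size[2]
    mask <- matrix(0L, nr, nc)
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    centers <- matrix(NA_real_, n_cells, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries * n_cells) {
        stop("could not place ", n_cells,
             " non-overlapping cells; enlarge the field or shrink radii")
      }
      r <- sample(radius_range[1]:radius_range[2], 1)
      cy <- stats::runif(1, r + 2, nr - r - 1)
      cx <- stats::runif(1, r + 2, nc - r - 1)
      if (placed > 0) {
        d <- sqrt((centers[seq_len(placed), 1] - cy)^2 +
                  (centers[seq_len(placed), 2] - cx)^2)
        if (any(d < centers[seq_len(placed), 3] + r + 2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cy, cx, r)
      mask[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- placed
    }
    fp_true <- stats::runif(n_cells, fp_range[1], fp_range[2])
    ab_true <- stats::runif(n_cells, ab_range[1], ab_range[2])
    fp_img <- matrix(background_level, nr, nc)
    ab_img <- matrix(background_level, nr, nc)
    for (k in seq_len(n_cells)) {
      fp_img[mask == k] <- background_level + fp_true[k]
      ab_img[mask == k] <- background_level + ab_true[k]
    }
    for (k in saturate_cells) {
      px <- which(mask == k)[1]
      fp_img[px] <- saturation_value
    }
    list(fov = field_of_view(field_id, fp_img, ab_img, mask,
                             saturation_fp = saturation_value,
                             saturation_ab = saturation_value),
         truth = data.frame(cell_id = seq_len(n_cells), fp = fp_true,
                            ab = ab_true),
         saturate_cells = saturate_cells)
  }
  if (is.null(seed)) gen() else .with_local_seed(seed, gen())
}

#' Simulate a grouped alignment with planted column classes
#'
#' Builds an aligned set of sequences over two groups in which every
#' column belongs to a planted conservation class:
#' `conserved_same` (one residue fixed across both groups),
#' `conserved_different` (each group fixed on a different residue),
#' `one_variable` (group a fixed, group b uniform random), or
#' `both_variable` (uniform random in both). Downstream, differential
#' conservation scoring should rank `conserved_different` columns at the
#' top and score `conserved_same` columns near zero.
#'
#' @param n_a,n_b Sequences per group.
#' @param classes Character vector of column classes, in column order.
#' @param group_names Names of the two groups.
#' @param seed Integer seed (caller's RNG state untouched).
#' @return List: `alignment` (named character vector of aligned
#'   sequences), `group_map` (`data.frame`: `sequence_id`, `group`),
#'   `classes` (the planted labels).
#' @export
simulate_alignment <- function(n_a = 8, n_b = 8,
                               classes = rep(c("conserved_same",
                                               "conserved_different",
                                               "one_variable",
                                               "both_variable"), each = 5),
                               group_names = c("trafficking",
                                               "non_trafficking"),
                               seed = NULL) {
  stopifnot(all(classes %in% c("conserved_same", "conserved_different",
                               "one_variable", "both_variable")))
  gen <- function() {
    nc <- length(classes)
    a <- matrix("", n_a, nc)
    b <- matrix("", n_b, nc)
    for (j in seq_len(nc)) {
      cls <- classes[j]
      if (cls == "conserved_same") {
        r <- sample(.AA, 1)
        a[, j] <- r; b[, j] <- r
      } else if (cls == "conserved_different") {
        rs <- sample(.AA, 2)
        a[, j] <- rs[1]; b[, j] <- rs[2]
      } else if (cls == "one_variable") {
        a[, j] <- sample(.AA, 1)
        b[, j] <- sample(.AA, n_b, replace = TRUE)
      } else {
        a[, j] <- sample(.AA, n_a, replace = TRUE)
        b[, j] <- sample(.AA, n_b, replace = TRUE)
      }
    }
    ids <- c(paste0(group_names[1], "_", seq_len(n_a)),
             paste0(group_names[2], "_", seq_len(n_b)))
    aln <- stats::setNames(
      c(apply(a, 1, paste, collapse = ""), apply(b, 1, paste, collapse = "")),
      ids)
    list(alignment = aln,
         group_map = data.frame(
           sequence_id = ids,
           group = rep(group_names, c(n_a, n_b)),
           stringsAsFactors = FALSE),
         classes = classes)
  }
  if (is.null(seed)) gen() else .with_local_seed(seed, gen())
}
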