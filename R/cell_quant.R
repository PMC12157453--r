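#' Construct a field of view
#'
#' Bundles the two fluorescence channels of one microscope field (the
#' transfection-marker "FP" channel and the surface-stain antibody "Ab"
#' channel) with its integer label mask. The mask assigns every pixel to
#' background (0) or to a cell (k > 0); segmentation itself is upstream of
#' this package and consumed, never produced.
#'
#' @param field_id Character scalar identifying the field.
#' @param fp_image,ab_image Numeric matrices of raw intensities (arbitrary
#'   fluorescence units), identical dimensions.
#' @param mask Integer matrix of the same dimensions; 0 = background,
#'   k > 0 = pixels of cell k.
#' @param saturation_fp,saturation_ab Intensity at or above which a pixel
#'   counts as saturated in each channel. Defaults to the maximum value
#'   actually representable for the channel's sample format; pass the
#'   detector's saturation code when it is known.
#' @return An object of class `field_of_view`.
#' @export
field_of_view <- function(field_id, fp_image, ab_image, mask,
                          saturation_fp = NULL, saturation_ab = NULL) {
  fp_image <- as.matrix(fp_image)
  ab_image <- as.matrix(ab_image)
  mask <- as.matrix(mask)
  if (!identical(dim(fp_image), dim(ab_image)) ||
      !identical(dim(fp_image), dim(mask))) {
    stop("fp_image, ab_image and mask must have identical dimensions")
  }
  if (any(mask < 0) || any(mask != round(mask))) {
    stop("mask labels must be non-negative integers")
  }
  if (is.null(saturation_fp)) saturation_fp <- .default_saturation(fp_image)
  if (is.null(saturation_ab)) saturation_ab <- .default_saturation(ab_image)
  if (saturation_fp <= 0 || saturation_ab <= 0) {
    stop("saturation values must be positive")
  }
  structure(
    list(field_id = as.character(field_id), fp_image = fp_image,
         ab_image = ab_image, mask = mask,
         saturation_fp = saturation_fp, saturation_ab = saturation_ab),
    class = "field_of_view")
}

# Bit-depth maximum for integer-like data; Inf for float data, where no
# saturation code can be inferred and none is assumed.
.default_saturation <- function(image) {
  if (all(image == round(image), na.rm = TRUE)) {
    mx <- max(image, na.rm = TRUE)
    if (mx <= 255) 255 else if (mx <= 4095) 4095 else 65535
  } else {
    Inf
  }
}

#' @export
print.field_of_view <- function(x, ...) {
  cat("Field of view '", x$field_id, "': ",
      nrow(x$mask), "x", ncol(x$mask), " px, ",
      length(setdiff(unique(as.vector(x$mask)), 0L)), " cells\n", sep = "")
  invisible(x)
}

#' Estimate the image background level
#'
#' The background of each individual image (one field of view, one channel)
#' is the median intensity over all non-cell pixels, i.e. pixels the mask
#' labels 0. The mean is available as an alternative statistic. Backgrounds
#' are never pooled across fields.
#'
#' @param image Numeric intensity matrix.
#' @param mask Integer label matrix of the same dimensions.
#' @param stat `"median"` (default) or `"mean"`.
#' @return Scalar background level.
#' @export
estimate_background <- function(image, mask, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask must have identical dimensions")
  }
  bg <- image[mask == 0]
  if (length(bg) == 0) {
    stop("mask contains no background (label 0) pixels; cannot estimate background")
  }
  if (stat == "median") stats::median(bg) else mean(bg)
}

#' Background-subtracted mean intensity per cell
#'
#' For each mask label k > 0, the mean of `pixel - background` over the
#' pixels of cell k. Values may be negative: background subtraction can
#' overshoot for dim cells.
#'
#' @inheritParams estimate_background
#' @param background Scalar background level already estimated for this image.
#' @return Named numeric vector, one entry per cell label (names are the
#'   labels, sorted increasingly); empty vector when the mask has no cells.
#' @export
per_cell_means <- function(image, mask, background) {
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask must have identical dimensions")
  }
  inside <- mask > 0
  if (!any(inside)) return(stats::setNames(numeric(0), character(0)))
  m <- tapply(image[inside] - background, mask[inside], mean)
  lab <- as.integer(names(m))
  out <- as.numeric(m)[order(lab)]
  names(out) <- sort(lab)
  out
}

#' Cells containing saturated pixels
#'
#' A cell counts as saturated when any of its pixels is at or above the
#' channel's saturation value; such cells are excluded from all downstream
#' statistics.
#'
#' @inheritParams estimate_background
#' @param saturation_value Scalar saturation intensity for this channel.
#' @return Integer vector of saturated cell labels (possibly empty).
#' @export
flag_saturated <- function(image, mask, saturation_value) {
  sel <- mask > 0 & image >= saturation_value
  sort(unique(as.integer(mask[sel])))
}

#' Quantify one field of view
#'
#' Runs background estimation, per-cell averaging and saturation flagging
#' independently on the FP and Ab channels and assembles one row per cell.
#' The `saturated` flag is the union over both channels.
#'
#' @param fov A [field_of_view()].
#' @param sample_id,replicate_id Identifiers attached to every cell record.
#' @param background_stat Passed to [estimate_background()].
#' @return A `data.frame` (cell table) with columns `sample_id`,
#'   `replicate_id`, `field_id`, `cell_id`, `fp_cell`, `ab_cell`,
#'   `saturated`; zero rows for an empty mask.
#' @export
quantify_field <- function(fov, sample_id, replicate_id,
                           background_stat = c("median", "mean")) {
  stopifnot(inherits(fov, "field_of_view"))
  background_stat <- match.arg(background_stat)
  bg_fp <- estimate_background(fov$fp_image, fov$mask, background_stat)
  bg_ab <- estimate_background(fov$ab_image, fov$mask, background_stat)
  fp <- per_cell_means(fov$fp_image, fov$mask, bg_fp)
  ab <- per_cell_means(fov$ab_image, fov$mask, bg_ab)
  ids <- as.integer(names(fp))
  sat <- union(flag_saturated(fov$fp_image, fov$mask, fov$saturation_fp),
               flag_saturated(fov$ab_image, fov$mask, fov$saturation_ab))
  data.frame(
    sample_id = rep(as.character(sample_id), length(ids)),
    replicate_id = rep(as.character(replicate_id), length(ids)),
    field_id = rep(fov$field_id, length(ids)),
    cell_id = ids,
    fp_cell = unname(fp),
    ab_cell = unname(ab),
    saturated = ids %in% sat,
    stringsAsFactors = FALSE)
}

#' Quantify many fields of view
#'
#' @param fovs List of [field_of_view()] objects.
#' @param sample_id,replicate_id Identifiers (recycled across fields).
#' @inheritParams quantify_field
#' @return Row-bound cell table.
#' @export
quantify_fields <- function(fovs, sample_id, replicate_id,
                            background_stat = c("median", "mean")) {
  background_stat <- match.arg(background_stat)
  do.call(rbind, lapply(fovs, quantify_field, sample_id = sample_id,
                        replicate_id = replicate_id,
                        background_stat = background_stat))
}
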