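#' Default run configuration
#'
#' The full set of tunable parameters of the pipeline with their defaults.
#' [read_config()] overlays a YAML file on these and rejects unknown keys.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    quantile = 0.995,
    n_bins = 20,
    bin_mode = "log_spaced",
    background_stat = "median",
    saturation_fp = NULL,
    saturation_ab = NULL,
    positive_control = NULL,
    untagged_controls = "untagged",
    mock_samples = "mock",
    fp_channel = "FP",
    ab_channel = "Ab",
    logicle_m = 4.5,
    logicle_w = NULL,
    logicle_a = 0,
    kl_direction = "b_vs_a",
    pseudocount = NULL,
    seed = 1L)
}

#' Read a run configuration file
#'
#' @param path YAML file with any subset of the keys of
#'   [default_config()]; unknown keys are an error.
#' @return Full configuration list (file values over defaults).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  base[names(cfg)] <- cfg
  base
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

.provenance_header <- function(config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("surfdeliv")),
                  error = function(e) "dev")
  h <- if (is.null(config)) "none" else .config_hash(config)
  sprintf("# surfdeliv %s config=%s", ver, h)
}

# Fixed floating-point formatting so identical inputs give byte-identical
# output tables.
.format_table <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.10g", df[[j]])
      df[[j]][df[[j]] == "NA"] <- "NA"
    }
  }
  df
}

#' Write a pipeline table as CSV
#'
#' All primary output tables (cells, metrics, bins, test results,
#' conservation profiles) are written through this function: a `#`
#' provenance comment line (tool version + configuration hash) followed by
#' a header and comma-separated rows with fixed floating-point formatting,
#' so re-running on identical inputs reproduces the file byte for byte.
#'
#' @param df `data.frame` to write.
#' @param path Output file.
#' @param config Optional configuration list recorded in the provenance
#'   line.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.provenance_header(config), con)
  utils::write.table(.format_table(as.data.frame(df)), con, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a pipeline CSV table
#'
#' @param path CSV written by [write_table_csv()] (comment lines starting
#'   with `#` are skipped) or any compatible CSV.
#' @return `data.frame`.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write per-cell tables
#'
#' The per-cell schema is `sample_id, replicate_id, field_id, cell_id,
#' fp_cell, ab_cell, saturated`.
#'
#' @param path CSV file.
#' @param cells Cell table.
#' @param config Optional configuration for the provenance header.
#' @return `read_cells()`: the cell table; `write_cells()`: the path.
#' @export
read_cells <- function(path) {
  df <- read_table_csv(path)
  req <- c("sample_id", "replicate_id", "fp_cell", "ab_cell")
  if (!all(req %in% names(df))) {
    stop("cell table must have columns ", paste(req, collapse = ", "))
  }
  if (!"saturated" %in% names(df)) df$saturated <- FALSE
  df$saturated <- as.logical(df$saturated)
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path, config = NULL) {
  write_table_csv(cells, path, config)
}

#' Read a single-channel TIFF image or label mask
#'
#' Integer TIFFs are returned at their native scale (not rescaled to
#' \[0, 1\]); masks come back as integer matrices.
#'
#' @param path TIFF file.
#' @param mask Logical: coerce to an integer label matrix.
#' @return Numeric (or integer) matrix.
#' @export
read_image_tiff <- function(path, mask = FALSE) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (mask) storage.mode(img) <- "integer"
  img
}

#' Write a single-channel TIFF image or label mask
#'
#' Integer data are written as 16-bit; values must fit in 0..65535.
#'
#' @param image Numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (any(image < 0) || any(image > 65535)) {
    stop("16-bit TIFF output requires values in 0..65535")
  }
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA (protein).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' Write an aligned FASTA file
#'
#' @param alignment Named character vector of aligned sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(alignment)) {
    writeLines(c(paste0(">", names(alignment)[i]), alignment[[i]]), con)
  }
  invisible(path)
}

#' Read a group-membership map
#'
#' @param path CSV with columns `sequence_id`, `group`.
#' @return `data.frame`.
#' @export
read_group_map <- function(path) {
  df <- read_table_csv(path)
  if (!all(c("sequence_id", "group") %in% names(df))) {
    stop("group map must have columns sequence_id, group")
  }
  df
}
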