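#' Read a flow-cytometry FCS file
#'
#' Minimal reader for list-mode FCS 3.0/3.1 files: parses the HEADER and
#' TEXT segments and decodes an uncompressed DATA segment of type `F`
#' (32-bit float), `D` (64-bit double) or `I` (unsigned integers of a
#' uniform bit width), in either byte order. This covers the conventional
#' output of modern cytometers; analysis segments and multi-dataset files
#' are ignored.
#'
#' @param path FCS file.
#' @return `data.frame` with one row per event and one column per channel
#'   (named from `$PnN`); keywords in attribute `keywords`.
#' @export
read_fcs <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version)
  }
  off <- function(i) {
    as.numeric(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8)))
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)

  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))

  need <- function(key) {
    if (!key %in% names(kw)) stop("FCS file lacks required keyword ", key)
    kw[[key]]
  }
  if (data_start == 0) data_start <- as.numeric(need("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(need("$ENDDATA"))
  if (toupper(need("$MODE")) != "L") stop("only list-mode FCS is supported")
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  bits <- vapply(seq_len(n_par), function(i)
    as.integer(need(sprintf("$P%dB", i))), 0L)
  ch <- vapply(seq_len(n_par), function(i) {
    key <- sprintf("$P%dN", i)
    if (key %in% names(kw)) kw[[key]] else sprintf("P%d", i)
  }, "")

  seek(con, data_start)
  n_values <- n_par * n_tot
  values <- switch(dtype,
    F = readBin(con, "numeric", n_values, size = 4, endian = endian),
    D = readBin(con, "numeric", n_values, size = 8, endian = endian),
    I = {
      if (length(unique(bits)) != 1 || !bits[1] %in% c(8, 16, 32)) {
        stop("integer FCS data requires a uniform $PnB of 8, 16 or 32")
      }
      readBin(con, "integer", n_values, size = bits[1] / 8,
              signed = bits[1] < 32, endian = endian)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(values) < n_values) stop("FCS data segment is truncated")
  m <- matrix(values, ncol = n_par, byrow = TRUE)
  colnames(m) <- ch
  out <- as.data.frame(m)
  attr(out, "keywords") <- kw
  out
}

#' Write a flow-cytometry FCS 3.1 file
#'
#' Writes events as 32-bit little-endian floats in list mode. Primarily a
#' round-trip companion to [read_fcs()] so flow-path code can be exercised
#' without shipping binary fixtures.
#'
#' @param events `data.frame` or matrix of events (columns = channels).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  m <- as.matrix(events)
  storage.mode(m) <- "double"
  n_par <- ncol(m); n_tot <- nrow(m)
  data_start <- 4096
  data_end <- data_start + 4 * n_par * n_tot - 1

  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = as.character(data_start),
          "$ENDDATA" = as.character(data_end),
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- colnames(m)[i] %||% sprintf("P%d", i)
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(ceiling(max(m[, i], 1)))
  }
  delim <- "/"
  text <- paste0(delim, paste0(names(kw), delim, unname(kw), delim,
                               collapse = ""))
  text_start <- 256
  text_end <- text_start + nchar(text) - 1
  if (text_end >= data_start) stop("TEXT segment too large for fixed layout")

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0, 0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(raw(text_start - nchar(header)), con)
  writeBin(charToRaw(text), con)
  writeBin(raw(data_start - text_end - 1), con)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert FCS events to the per-cell table schema
#'
#' Flow-cytometry events are used directly as cells: thresholds apply to
#' the raw event intensities (no image-style background subtraction). The
#' channel mapping must be explicit — channel names are never guessed.
#'
#' @param events `data.frame` from [read_fcs()].
#' @param fp_channel,ab_channel Channel names carrying the transfection
#'   marker and the surface stain.
#' @param sample_id,replicate_id Identifiers for the table.
#' @return Cell table `data.frame`.
#' @export
fcs_to_cells <- function(events, fp_channel, ab_channel,
                         sample_id, replicate_id) {
  if (missing(fp_channel) || missing(ab_channel)) {
    stop("fp_channel and ab_channel must be given explicitly")
  }
  for (ch in c(fp_channel, ab_channel)) {
    if (!ch %in% colnames(events)) {
      stop("channel '", ch, "' not present in FCS data (have: ",
           paste(colnames(events), collapse = ", "), ")")
    }
  }
  data.frame(
    sample_id = as.character(sample_id),
    replicate_id = as.character(replicate_id),
    field_id = "flow",
    cell_id = seq_len(nrow(events)),
    fp_cell = events[[fp_channel]],
    ab_cell = events[[ab_channel]],
    saturated = FALSE,
    stringsAsFactors = FALSE)
}
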