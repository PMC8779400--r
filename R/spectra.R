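#' Construct a spectra set
#'
#' The basic container for NIR spectra: a numeric matrix with one row per
#' sample and one column per wavelength, together with the wavelength grid
#' in nanometres and a flag saying whether the signal is reflectance (a
#' fraction, conventionally in (0, 1.5] to tolerate white-reference drift)
#' or absorbance (log10(1/R)).
#'
#' @param signal numeric matrix, rows = samples, columns = wavelengths.
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths
#'   in nm, one per column of `signal`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `signal`.
#' @param signal_kind `"reflectance"` or `"absorbance"`.
#' @param instrument_label free-text label for the acquiring instrument.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(signal, wavelengths_nm, sample_ids,
                        signal_kind = c("reflectance", "absorbance"),
                        instrument_label = "") {
  signal_kind <- match.arg(signal_kind)
  signal <- as.matrix(signal)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  sample_ids <- as.character(sample_ids)
  if (nrow(signal) != length(sample_ids))
    stop("row count (", nrow(signal), ") != number of sample ids (",
         length(sample_ids), ")")
  if (ncol(signal) != length(wavelengths_nm))
    stop("column count (", ncol(signal), ") != number of wavelengths (",
         length(wavelengths_nm), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("signal contains non-finite values")
  if (signal_kind == "reflectance") {
    if (any(signal <= 0))
      stop("reflectance must be strictly positive")
    if (any(signal > 1.5))
      stop("reflectance > 1.5; expected a fraction, not percent")
  }
  dimnames(signal) <- list(sample_ids, format(wavelengths_nm, trim = TRUE))
  structure(
    list(sample_ids = sample_ids,
         wavelengths_nm = wavelengths_nm,
         signal = signal,
         signal_kind = signal_kind,
         instrument_label = instrument_label),
    class = "spectra_set")
}

#' @exportS3Method base::print
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", length(x$sample_ids), " samples x ",
      length(x$wavelengths_nm), " wavelengths (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm), ",
      x$signal_kind,
      if (nzchar(x$instrument_label)) paste0(", instrument: ", x$instrument_label),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$signal)

#' Subset a spectra set by sample and/or wavelength index
#' @param x a `spectra_set`.
#' @param i sample index (integer, logical, or sample-id character).
#' @param j wavelength column index.
#' @param ... unused.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$wavelengths_nm)
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra_set(x$signal[i, j, drop = FALSE], x$wavelengths_nm[j],
              x$sample_ids[i], x$signal_kind, x$instrument_label)
}

#' Read spectra from a wide CSV
#'
#' Expects a header row `id,<wl1>,<wl2>,...` where the wavelength headers
#' parse as numbers in nm, followed by one row per sample. The wavelength
#' order in the file is preserved and must already be strictly increasing.
#'
#' @param path path to the CSV file.
#' @param signal_kind `"reflectance"` or `"absorbance"`.
#' @param instrument_label optional label stored on the result.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, signal_kind = c("reflectance", "absorbance"),
                         instrument_label = "") {
  signal_kind <- match.arg(signal_kind)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "id")
    stop("spectra CSV must have header 'id,<wl1>,<wl2>,...'")
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl))
    stop("wavelength headers do not all parse as numbers: ",
         paste(names(df)[-1][is.na(wl)], collapse = ", "))
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])), nrow = nrow(df)))
  if (anyNA(mat)) stop("non-numeric cell in spectra CSV")
  spectra_set(mat, wl, df$id, signal_kind, instrument_label)
}

#' Write spectra to a wide CSV
#'
#' Writes the dialect [read_spectra()] accepts, at full double precision
#' (15 significant digits), so that a write/read round trip reproduces the
#' signal to well under 1e-9 per cell.
#'
#' @param s a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  header <- paste(c("id", format(s$wavelengths_nm, trim = TRUE)), collapse = ",")
  rows <- character(length(s$sample_ids))
  for (i in seq_along(s$sample_ids)) {
    rows[i] <- paste(c(s$sample_ids[i],
                       formatC(s$signal[i, ], format = "g", digits = 15)),
                     collapse = ",")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct a laboratory reference table
#'
#' Holds per-sample constituent values in % of dry matter and, optionally,
#' the per-constituent standard error of the laboratory (SEL, % DM) of the
#' reference assay.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param constituents numeric matrix or data frame (samples x constituents),
#'   columns named by constituent (e.g. NDF, IVTD, NDFD, ADF, ADL, CP).
#' @param sel named numeric vector of SELs, one per constituent column;
#'   may be `NULL` when laboratory error is not used downstream.
#' @return An object of class `reference_table`.
#' @export
reference_table <- function(sample_ids, constituents, sel = NULL) {
  sample_ids <- as.character(sample_ids)
  constituents <- as.matrix(constituents)
  if (is.null(colnames(constituents)))
    stop("constituent columns must be named")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(constituents) != length(sample_ids))
    stop("constituent rows != number of sample ids")
  if (anyNA(constituents) || any(!is.finite(constituents)))
    stop("constituent values must all be finite")
  if (any(constituents < 0 | constituents > 100))
    stop("constituent values must lie in [0, 100] % DM")
  if (!is.null(sel)) {
    sel <- sel[colnames(constituents)]
    if (anyNA(sel)) stop("sel must name every constituent column")
    if (any(sel <= 0)) stop("sel values must be strictly positive")
  }
  rownames(constituents) <- sample_ids
  structure(list(sample_ids = sample_ids, constituents = constituents,
                 sel = sel),
            class = "reference_table")
}

#' @exportS3Method base::print
print.reference_table <- function(x, ...) {
  cat("<reference_table> ", length(x$sample_ids), " samples, constituents: ",
      paste(colnames(x$constituents), collapse = ", "), "\n", sep = "")
  if (!is.null(x$sel)) {
    cat("  SEL (% DM): ",
        paste(sprintf("%s=%.3g", names(x$sel), x$sel), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a reference table from CSV
#'
#' @param path CSV with header `id,<constituent>,...`.
#' @param sel_path optional CSV `constituent,sel` giving the laboratory
#'   standard error per constituent.
#' @return A [reference_table()].
#' @export
read_reference <- function(path, sel_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "id") stop("reference CSV must start with an 'id' column")
  sel <- NULL
  if (!is.null(sel_path)) {
    sdf <- utils::read.csv(sel_path)
    sel <- stats::setNames(as.numeric(sdf$sel), sdf$constituent)
  }
  reference_table(df$id, df[, -1, drop = FALSE], sel)
}

#' Write a reference table to CSV
#' @param r a `reference_table`.
#' @param path output CSV path.
#' @param sel_path optional path for the `constituent,sel` companion CSV.
#' @return `path`, invisibly.
#' @export
write_reference <- function(r, path, sel_path = NULL) {
  df <- data.frame(id = r$sample_ids, r$constituents, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sel_path) && !is.null(r$sel)) {
    utils::write.csv(data.frame(constituent = names(r$sel), sel = r$sel),
                     sel_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Construct sample metadata
#'
#' @param sample_ids character vector of unique ids.
#' @param species character vector, `"alfalfa"` or `"grass"`, one per sample.
#' @param harvest_date_index positive integer per sample; odd indices form
#'   the validation partition in [split_by_harvest()].
#' @return An object of class `sample_meta` (a data frame).
#' @export
sample_meta <- function(sample_ids, species, harvest_date_index) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  species <- match.arg(as.character(species), c("alfalfa", "grass"),
                       several.ok = TRUE)
  harvest_date_index <- as.integer(harvest_date_index)
  if (any(is.na(harvest_date_index)) || any(harvest_date_index < 1))
    stop("harvest_date_index must be a positive integer")
  df <- data.frame(id = sample_ids, species = species,
                   harvest_date_index = harvest_date_index,
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from CSV (`id,species,harvest_date_index`)
#' @param path CSV path.
#' @return A [sample_meta()].
#' @export
read_meta <- function(path) {
  df <- utils::read.csv(path)
  sample_meta(df$id, df$species, df$harvest_date_index)
}

#' Write sample metadata to CSV
#' @param m a `sample_meta`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_meta <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align spectra, reference values and metadata on shared sample ids
#'
#' Restricts all three objects to the intersection of their sample ids, in
#' the spectra set's order, and reports which ids were dropped from each.
#' Idempotent: aligning an aligned triple changes nothing.
#'
#' @param s a `spectra_set`.
#' @param r a `reference_table`.
#' @param m a `sample_meta`, or `NULL` to align spectra and reference only.
#' @return A list with elements `spectra`, `reference`, `meta` and
#'   `dropped` (character vector of ids not present in every input).
#' @export
align_dataset <- function(s, r, m = NULL) {
  ids <- intersect(s$sample_ids, r$sample_ids)
  if (!is.null(m)) ids <- intersect(ids, m$id)
  if (length(ids) == 0) stop("no sample ids shared by all inputs")
  keep <- s$sample_ids[s$sample_ids %in% ids]  # spectra order
  all_ids <- unique(c(s$sample_ids, r$sample_ids, if (!is.null(m)) m$id))
  dropped <- setdiff(all_ids, keep)
  sa <- s[keep, ]
  ra <- reference_table(keep,
                        r$constituents[match(keep, r$sample_ids), , drop = FALSE],
                        r$sel)
  ma <- NULL
  if (!is.null(m)) {
    ma <- m[match(keep, m$id), , drop = FALSE]
    rownames(ma) <- NULL
    class(ma) <- c("sample_meta", "data.frame")
  }
  list(spectra = sa, reference = ra, meta = ma, dropped = dropped)
}
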