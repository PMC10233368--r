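#' Write a two-channel membrane image as a multi-page 16-bit TIFF
#'
#' Page 0 carries the streptavidin signal channel, page 1 the loading
#' control.  Intensities are integer counts in 0..65535.
#'
#' @param image `list(signal =, control =)` integer matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_membrane_tiff <- function(image, path) {
  stopifnot(is.list(image), !is.null(image$signal), !is.null(image$control))
  for (ch in c("signal", "control")) {
    m <- image[[ch]]
    if (any(m < 0 | m > 65535)) stop("intensities must be in 0..65535")
  }
  tiff::writeTIFF(list(image$signal / 65535, image$control / 65535),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a two-channel membrane TIFF
#'
#' @param path TIFF written by [write_membrane_tiff()] (page 0 = signal,
#'   page 1 = loading control, 16-bit).
#' @return `list(signal =, control =)` integer matrices of counts.
#' @export
read_membrane_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L)
    stop(path, ": expected 2 pages (signal, control), found ", length(pages))
  to_counts <- function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  }
  list(signal = to_counts(pages[[1L]]), control = to_counts(pages[[2L]]))
}

#' @rdname tsv_io
#' @param df Data frame to write.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

#' Strict TSV reading and writing
#'
#' Tab-separated tables with a header row, UTF-8, newline-terminated.
#' Readers check the required schema and report the offending column or
#' row; unknown extra columns are preserved.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numeric; a value that
#'   does not is reported with its (1-based, header-excluded) row number.
#' @return `read_tsv_file`: the data frame.
#' @name tsv_io
#' @export
read_tsv_file <- function(path, required = character(0),
                          numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !(df[[cc]] %in% c("NA", "")))
    if (length(bad) > 0L)
      stop(sprintf("%s: column '%s' is not numeric at row %d (value '%s')",
                   path, cc, bad[1L], df[[cc]][bad[1L]]))
    df[[cc]] <- v
  }
  df
}

#' Readers for the pipeline's table formats
#'
#' Thin schema-checked wrappers over [read_tsv_file()] for the plate map
#' (`membrane_id, row, col, bait_id, prey_id, bio_rep, tech_rep`), the
#' pre-lysis OD table (`strain_id, od600`), the protein feature
#' annotations (`protein_id, has_sp, has_tmd, has_mts[, sp_sequence]`)
#' and per-dot measurements.
#'
#' @param path File path.
#' @return Data frame with typed columns.
#' @name table_readers
#' @export
read_plate_map <- function(path) {
  df <- read_tsv_file(path, required = c("membrane_id", "row", "col",
                                         "bait_id", "prey_id", "bio_rep",
                                         "tech_rep"),
                      numeric_cols = c("row", "col", "bio_rep", "tech_rep"))
  for (cc in c("row", "col", "bio_rep", "tech_rep"))
    df[[cc]] <- as.integer(df[[cc]])
  df
}

#' @rdname table_readers
#' @export
read_od_table <- function(path)
  read_tsv_file(path, required = c("strain_id", "od600"),
                numeric_cols = "od600")

#' @rdname table_readers
#' @export
read_annotations <- function(path) {
  df <- read_tsv_file(path, required = c("protein_id", "has_sp", "has_tmd",
                                         "has_mts"))
  for (cc in c("has_sp", "has_tmd", "has_mts")) {
    v <- toupper(df[[cc]])
    if (!all(v %in% c("TRUE", "FALSE", "NA")))
      stop(path, ": column '", cc, "' must be TRUE/FALSE")
    df[[cc]] <- as.logical(v)
  }
  df
}

#' @rdname table_readers
#' @export
read_dots <- function(path)
  read_tsv_file(path,
                required = c("membrane_id", "row", "col", "signal_raw",
                             "control_raw", "signal_corrected",
                             "control_corrected", "flags"),
                numeric_cols = c("row", "col", "signal_raw", "control_raw",
                                 "signal_bg", "control_bg",
                                 "signal_corrected", "control_corrected"))

#' Read and write amino-acid FASTA
#'
#' @param path FASTA file.
#' @return `read_fasta`: named character vector of sequences.  Duplicate
#'   record IDs are an error (every duplicate is listed).
#' @name fasta_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop(path, ": duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  stats::setNames(as.character(ss), ids)
}

#' @rdname fasta_io
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
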