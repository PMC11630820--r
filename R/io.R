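#' Write a frequency-domain dataset as a Weber CSV
#'
#' Plain CSV with columns `frequency_hz`, `phase_deg`, `mod_ratio` and
#' optionally `phase_sd_deg`, `mod_sd`; one file per replicate. Values are
#' written with full double precision so a write/read round trip is
#' lossless.
#'
#' @param dataset an [fd_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weber_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "fd_dataset"))
  df <- data.frame(frequency_hz = dataset$frequencies,
                   phase_deg = dataset$phase_deg,
                   mod_ratio = dataset$mod_ratio)
  if (!is.null(dataset$phase_sd)) df$phase_sd_deg <- dataset$phase_sd
  if (!is.null(dataset$mod_sd)) df$mod_sd <- dataset$mod_sd
  chr <- as.data.frame(lapply(df, function(x) sprintf("%.17g", x)))
  names(chr) <- names(df)
  utils::write.csv(chr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Weber CSV into a frequency-domain dataset
#'
#' Strict parser: required columns must be present and numeric, frequencies
#' strictly increasing, modulation ratios in (0, 1]; violations raise
#' errors naming the offending row. Condition metadata comes from the
#' caller (typically a manifest entry).
#'
#' @param path CSV file path.
#' @param ... metadata (`condition`, `acceptor`, `ionic`, `replicate_id`,
#'   `sample_id`) forwarded to [fd_dataset()].
#' @return An [fd_dataset()].
#' @export
read_weber_csv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frequency_hz", "phase_deg", "mod_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  for (cn in intersect(c(need, "phase_sd_deg", "mod_sd"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v)))
      stop(sprintf("%s: non-numeric value in column '%s' (row %d)",
                   path, cn, which(is.na(v))[1L]))
    df[[cn]] <- v
  }
  fd_dataset(df$frequency_hz, df$phase_deg, df$mod_ratio,
             phase_sd = df$phase_sd_deg, mod_sd = df$mod_sd, ...)
}

#' Write a study manifest
#'
#' JSON manifest mapping Weber CSV files to their condition metadata, plus
#' global analysis settings (temperature, resting floor, default weights).
#'
#' @param entries `data.frame` with columns `file`, `condition`,
#'   `acceptor`, `ionic`, `replicate_id` and optionally `sample_id`.
#' @param path output path.
#' @param settings named list of global settings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path,
                           settings = list(temperature_K = 298,
                                           resting_floor = 0.01,
                                           phase_sd_deg = 0.2,
                                           mod_sd = 0.004)) {
  need <- c("file", "condition", "acceptor", "ionic", "replicate_id")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop(sprintf("manifest entries missing column(s): %s",
                 paste(miss, collapse = ", ")))
  jsonlite::write_json(list(entries = entries, settings = settings), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a study manifest and load its datasets
#'
#' Validates that every referenced file exists and every acceptor resolves
#' in the pair registry, then reads all Weber CSVs.
#'
#' @param path manifest JSON path.
#' @param pairs pair registry, see [default_pairs()].
#' @return List with `datasets` (list of [fd_dataset()]s), `entries`, and
#'   `settings`.
#' @export
read_manifest <- function(path, pairs = default_pairs()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(m$entries)
  dir <- dirname(path)
  files <- ifelse(file.exists(entries$file), entries$file,
                  file.path(dir, entries$file))
  for (i in seq_len(nrow(entries))) {
    if (!file.exists(files[i]))
      stop(sprintf("manifest references missing file: %s", entries$file[i]))
    get_pair(entries$acceptor[i], pairs)
  }
  datasets <- lapply(seq_len(nrow(entries)), function(i) {
    sid <- if ("sample_id" %in% names(entries) && !is.na(entries$sample_id[i]))
      entries$sample_id[i] else NULL
    read_weber_csv(files[i], condition = entries$condition[i],
                   acceptor = entries$acceptor[i],
                   ionic = entries$ionic[i],
                   replicate_id = entries$replicate_id[i],
                   sample_id = sid)
  })
  list(datasets = datasets, entries = entries, settings = m$settings)
}

#' Write a generated study to disk
#'
#' Writes one Weber CSV per dataset plus a manifest JSON and a truth JSON,
#' the complete on-disk form of a synthetic study.
#'
#' @param study result of [generate_fd_study()].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_fd_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- do.call(rbind, lapply(study$datasets, function(ds) {
    fn <- paste0(gsub("[^A-Za-z0-9._-]+", "_", dataset_id(ds)), ".csv")
    write_weber_csv(ds, file.path(dir, fn))
    data.frame(file = fn, condition = ds$condition, acceptor = ds$acceptor,
               ionic = ds$ionic, replicate_id = ds$replicate_id,
               sample_id = ds$sample_id)
  }))
  manifest <- file.path(dir, "manifest.json")
  write_manifest(entries, manifest)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}

#' Read a tabulated distance distribution for overlay comparison
#'
#' Reads a two-column table (distance in Angstrom, probability density) as
#' exported by rotamer-modeling tools, renormalizes the density to unit
#' area by trapezoid rule, and returns it for plotting and comparison. Such
#' imported distributions are overlay-only; they are never used as fit
#' models.
#'
#' @param path CSV or TSV path (delimiter inferred).
#' @return List of class `distribution_table` with `r`, `density` (unit
#'   area) and `mean` (trapezoid-rule mean distance).
#' @export
read_distribution_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("%s: empty file", path))
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = grepl("[A-Za-z]", first), sep = sep)
  if (ncol(df) < 2L) stop(sprintf("%s: expected two numeric columns", path))
  r <- suppressWarnings(as.numeric(df[[1]]))
  d <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(r)) || any(is.na(d)))
    stop(sprintf("%s: non-numeric values in distribution table", path))
  if (any(d < 0)) stop(sprintf("%s: negative density values", path))
  o <- order(r); r <- r[o]; d <- d[o]
  if (length(r) < 2L) stop(sprintf("%s: too few rows", path))
  area <- sum(diff(r) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
  if (area <= 0) stop(sprintf("%s: density integrates to zero", path))
  d <- d / area
  m <- sum(diff(r) * (utils::head(r * d, -1) + utils::tail(r * d, -1)) / 2)
  structure(list(r = r, density = d, mean = m), class = "distribution_table")
}

#' Export a distance distribution as a two-column table
#'
#' @param dist a `distance_distribution`.
#' @param path output CSV path.
#' @param r distance grid (Angstrom) at which to tabulate the density.
#' @return `path`, invisibly.
#' @export
write_distribution_table <- function(dist, path,
                                     r = seq(5, 70, by = 0.1)) {
  d <- distribution_density(dist, r)
  utils::write.csv(data.frame(r_angstrom = r, density = d), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Table-1-style energetics CSV
#'
#' @param df energetics table, e.g. from [state_energetics()] with added
#'   grouping columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_energetics_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
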