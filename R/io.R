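#' Read and write the plate-map CSV
#'
#' Columns `well`, `kind`, `treatment_id`, `concentration`.
#'
#' @param plate_map plate-map data frame.
#' @param path CSV path.
#' @return `read_plate_map` returns a validated plate map.
#' @export
write_plate_map <- function(plate_map, path) {
  write.csv(validate_plate_map(plate_map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  validate_plate_map(read.csv(path, stringsAsFactors = FALSE))
}

#' Read and write cell-level tables as one long-format CSV
#'
#' Long format: a `well` column, a `cell` index column, then one column per
#' raw feature.
#'
#' @param cells named list (well -> cells x features matrix).
#' @param path CSV path.
#' @return `read_cell_tables` returns the named list of matrices.
#' @export
write_cell_tables <- function(cells, path) {
  long <- do.call(rbind, lapply(names(cells), function(w) {
    data.frame(well = w, cell = seq_len(nrow(cells[[w]])), cells[[w]],
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_tables
#' @export
read_cell_tables <- function(path) {
  long <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- setdiff(colnames(long), c("well", "cell"))
  split_idx <- split(seq_len(nrow(long)), long$well)
  lapply(split_idx, function(i) as.matrix(long[i, feats, drop = FALSE]))
}

#' Read and write the aligned MS feature-table CSV
#'
#' The networking/annotation dialect: first column is the feature id
#' `"rt_mz"` (e.g. `"1.87_416.2431"`), remaining columns are per-sample
#' intensities. On read, `rt` and `mz` are recovered from the id and the
#' table invariants (rt in \[0, 14\] min, m/z in \[50, 1500\], unique ids)
#' are enforced.
#'
#' @param table MS feature table data frame (with `feature_id`, `rt`, `mz`
#'   columns; `rt`/`mz` are not written, they live in the id).
#' @param path CSV path.
#' @return `read_ms_features` returns the table data frame.
#' @export
write_ms_features <- function(table, path) {
  samples <- setdiff(colnames(table), c("feature_id", "rt", "mz"))
  write.csv(table[, c("feature_id", samples), drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_ms_features
#' @export
read_ms_features <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad))
    stop(sprintf("feature id not in 'rt_mz' form: '%s'", ids[bad][1L]),
         call. = FALSE)
  rt <- as.numeric(vapply(parts, `[[`, "", 1L))
  mz <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyDuplicated(ids))
    stop("duplicated feature ids", call. = FALSE)
  if (any(is.na(rt)) || any(rt < 0 | rt > 14))
    stop("retention time outside [0, 14] min", call. = FALSE)
  if (any(is.na(mz)) || any(mz < 50 | mz > 1500))
    stop("m/z outside [50, 1500]", call. = FALSE)
  out <- data.frame(feature_id = ids, rt = rt, mz = mz,
                    raw[, -1L, drop = FALSE], check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Read a compound database CSV
#'
#' Columns `name`, `formula`, optionally `cas`.
#'
#' @param path CSV path.
#' @return data frame with validated formulas.
#' @export
read_compound_db <- function(path) {
  db <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula") %in% colnames(db)))
  invisible(lapply(db$formula, parse_formula)) # fail fast on bad formulas
  db
}

#' Write bioactivity fingerprints with CP scores
#'
#' CSV dialect: `sample`, `concentration`, `score`, then one column per
#' fingerprint feature.
#'
#' @param fingerprints matrix samples x features.
#' @param cp_scores named numeric vector of per-sample CP scores.
#' @param path CSV path.
#' @param concentration optional named concentrations.
#' @return the path, invisibly.
#' @export
write_fingerprints <- function(fingerprints, cp_scores, path,
                               concentration = NULL) {
  ids <- rownames(fingerprints)
  conc <- if (is.null(concentration)) NA_real_ else concentration[ids]
  out <- data.frame(sample = ids, concentration = conc,
                    score = cp_scores[ids], fingerprints,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- setdiff(colnames(raw), c("sample", "concentration", "score"))
  fp <- as.matrix(raw[, feats, drop = FALSE])
  rownames(fp) <- raw$sample
  list(fingerprints = fp,
       cp_scores = stats::setNames(raw$score, raw$sample),
       concentration = stats::setNames(raw$concentration, raw$sample))
}
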