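PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

#' Default 384-well plate layout
#'
#' Reproduces the screening layout this package emulates: rows A, B, O, P
#' and columns 1 and 24 hold DMSO vehicle controls (edge buffering);
#' columns 2 and 23 (rows C-N) hold 12-point 2-fold serial dilutions of the
#' two positive controls; the remaining 240 wells hold sample treatments in
#' 4-point 2-fold dilution series laid out row-wise.
#'
#' @param treatments character vector of sample treatment ids (at most 60;
#'   each occupies 4 consecutive wells).
#' @param top_conc top sample concentration (ug/mL) of each 4-point series.
#' @param positive_controls two treatment ids for the column-2 and
#'   column-23 dilution series.
#' @param pos_top_conc top positive-control concentration.
#' @return data frame with columns `well`, `kind`
#'   (`vehicle`/`positive_control`/`sample`), `treatment_id`,
#'   `concentration` (`NA` for vehicle); exactly 384 rows.
#' @export
synth_plate_map <- function(treatments = sprintf("T%02d", 1:18),
                            top_conc = 200,
                            positive_controls = c("brefeldin_a", "etoposide"),
                            pos_top_conc = 25600) {
  stopifnot(length(treatments) <= 60, length(positive_controls) == 2L)
  wells <- as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
  row_of <- substr(wells, 1L, 1L)
  col_of <- as.integer(substring(wells, 2L))
  kind <- rep("empty", length(wells))
  trt <- rep(NA_character_, length(wells))
  conc <- rep(NA_real_, length(wells))

  vehicle <- row_of %in% c("A", "B", "O", "P") | col_of %in% c(1L, 24L)
  kind[vehicle] <- "vehicle"

  for (k in 1:2) {
    colk <- c(2L, 23L)[k]
    pc <- which(col_of == colk & row_of %in% LETTERS[3:14]) # C..N
    kind[pc] <- "positive_control"
    trt[pc] <- positive_controls[k]
    conc[pc] <- pos_top_conc / 2^(seq_along(pc) - 1L)
  }

  open <- which(kind == "empty" & row_of %in% LETTERS[3:14] &
                  col_of >= 3L & col_of <= 22L)
  series <- rep(treatments, each = 4L)
  dil <- rep(top_conc / c(1, 2, 4, 8), times = length(treatments))
  take <- seq_len(min(length(series), length(open)))
  kind[open[take]] <- "sample"
  trt[open[take]] <- series[take]
  conc[open[take]] <- dil[take]
  kind[kind == "empty"] <- "vehicle" # unused wells default to vehicle

  data.frame(well = wells, kind = kind, treatment_id = trt,
             concentration = conc, stringsAsFactors = FALSE)
}

#' Validate a plate map
#'
#' Checks the 384-well invariants: exactly one entry per address A1..P24,
#' known role kinds, no concentration on vehicle wells.
#'
#' @param plate_map plate-map data frame.
#' @return the plate map, invisibly usable, or an error naming the first
#'   offending well address.
#' @export
validate_plate_map <- function(plate_map) {
  need <- c("well", "kind", "treatment_id", "concentration")
  stopifnot(all(need %in% colnames(plate_map)))
  valid <- as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
  bad <- setdiff(plate_map$well, valid)
  if (length(bad) > 0L)
    stop(sprintf("unknown well address: %s", bad[1L]), call. = FALSE)
  if (anyDuplicated(plate_map$well))
    stop(sprintf("duplicated well address: %s",
                 plate_map$well[duplicated(plate_map$well)][1L]),
         call. = FALSE)
  if (nrow(plate_map) != 384L)
    stop(sprintf("plate map has %d wells; a 384-well map is required",
                 nrow(plate_map)), call. = FALSE)
  if (!all(plate_map$kind %in% c("vehicle", "positive_control", "sample")))
    stop("unknown well role kind", call. = FALSE)
  if (any(plate_map$kind == "vehicle" & !is.na(plate_map$concentration)))
    stop("vehicle wells must not carry a concentration", call. = FALSE)
  plate_map
}

#' Planted ground truth for the synthetic plate
#'
#' Active treatments are grouped into mechanism-of-action classes; each
#' class gets one effect vector (a random subset of `n_affected` features
#' shifted by `effect_size` baseline standard deviations at saturation,
#' random sign, zero elsewhere) and every active treatment inherits its
#' class vector scaled by an individual potency factor, emulating related
#' extracts that share an active metabolite at varying abundance. Inactive
#' treatments get a zero vector. Positive controls get their own stronger,
#' broader effects. The concentration response is the saturating
#' \eqn{s(c) = c / (c + ec50)}.
#'
#' @param n_features number of raw cell-level features.
#' @param treatments sample treatment ids.
#' @param active character vector of treatments with a real phenotype
#'   (subset of `treatments`); the rest get a zero effect vector.
#' @param n_classes number of MOA classes the active treatments split into.
#' @param positive_controls positive-control ids (always active).
#' @param n_affected features perturbed per class.
#' @param effect_size shift in baseline SD units at saturation.
#' @param ec50 concentration of half-maximal effect (same units as the
#'   plate-map concentrations).
#' @param potency_range range of the per-treatment potency multiplier.
#' @param seed RNG seed.
#' @return list with `effects` (named list treatment -> numeric vector),
#'   `class_of` (named character, `NA` for inactive treatments), `ec50`,
#'   `active_treatments`.
#' @export
synth_ground_truth <- function(n_features, treatments,
                               active = treatments[seq_len(min(8, length(treatments)))],
                               n_classes = 2L,
                               positive_controls = c("brefeldin_a", "etoposide"),
                               n_affected = 20, effect_size = 3,
                               ec50 = 300, potency_range = c(0.8, 1.25),
                               seed = 1L) {
  stopifnot(n_features >= 2, all(active %in% treatments),
            n_classes >= 1, length(active) == 0 || n_classes <= length(active))
  set.seed(derive_seed(seed, 11L))
  class_vec <- lapply(seq_len(n_classes), function(k) {
    e <- numeric(n_features)
    idx <- sample.int(n_features, min(n_affected, n_features))
    e[idx] <- effect_size * sample(c(-1, 1), length(idx), replace = TRUE)
    e
  })
  cls <- rep(seq_len(max(n_classes, 1L)), length.out = length(active))
  class_of <- stats::setNames(rep(NA_character_, length(treatments)),
                              treatments)
  eff <- list()
  for (t in treatments) {
    if (t %in% active) {
      k <- cls[match(t, active)]
      class_of[t] <- sprintf("moa%d", k)
      potency <- stats::runif(1, potency_range[1], potency_range[2])
      eff[[t]] <- class_vec[[k]] * potency
    } else {
      eff[[t]] <- numeric(n_features)
    }
  }
  for (pc in positive_controls) {
    e <- numeric(n_features)
    idx <- sample.int(n_features, min(2L * n_affected, n_features))
    e[idx] <- 1.5 * effect_size * sample(c(-1, 1), length(idx), replace = TRUE)
    eff[[pc]] <- e
  }
  list(effects = eff, class_of = class_of, ec50 = ec50,
       active_treatments = c(active, positive_controls))
}

#' Saturating concentration-response scale
#'
#' @param conc concentration(s).
#' @param ec50 half-maximal concentration.
#' @return \eqn{c / (c + ec50)} in \[0, 1), monotone increasing in `conc`.
#' @export
conc_scale <- function(conc, ec50) conc / (conc + ec50)

#' Generate synthetic cell-level feature tables for a plate
#'
#' Draws per-well cells x features tables. Every feature has a baseline
#' location-scale distribution (a mix of Gaussian, shifted-lognormal and
#' scaled-t families when `heavy_tails = TRUE`, so downstream histogram
#' normalization is exercised on non-Gaussian shapes). Vehicle wells draw
#' from the baseline; treated wells shift each feature by
#' `effect * conc_scale(concentration, ec50) * baseline SD`. Cell counts
#' are Poisson around `n_cells` (floored at 10). Wells are generated from
#' per-well derived seeds, so the same `seed` yields identical tables and
#' the content of a well does not depend on which other wells are
#' requested.
#'
#' @param plate_map plate map (validated, 384 wells).
#' @param ground_truth from [synth_ground_truth()].
#' @param n_features number of raw features (>= 2).
#' @param n_cells nominal cells per well (>= 10).
#' @param seed RNG seed.
#' @param wells optional character vector of well addresses to populate
#'   (default: all wells with a role on the map).
#' @param heavy_tails include non-Gaussian baseline families?
#' @return list with `cells` (named list well -> matrix), `plate_map`.
#' @export
synth_cell_tables <- function(plate_map, ground_truth, n_features = 200L,
                              n_cells = 300L, seed = 1L, wells = NULL,
                              heavy_tails = TRUE) {
  plate_map <- validate_plate_map(plate_map)
  stopifnot(n_features >= 2L, n_cells >= 10L)
  if (is.null(wells)) wells <- plate_map$well
  bad <- setdiff(wells, plate_map$well)
  if (length(bad) > 0L)
    stop(sprintf("unknown well address: %s", bad[1L]), call. = FALSE)

  set.seed(derive_seed(seed, 21L))
  fam <- if (heavy_tails)
    sample(c("normal", "lognormal", "t"), n_features, replace = TRUE,
           prob = c(0.6, 0.2, 0.2))
  else rep("normal", n_features)
  mu <- stats::rnorm(n_features, 0, 2)
  sigma <- stats::runif(n_features, 0.5, 2)
  fnames <- sprintf("f%03d", seq_len(n_features))

  map_idx <- match(wells, plate_map$well)
  out <- vector("list", length(wells))
  names(out) <- wells
  for (i in seq_along(wells)) {
    w <- wells[i]
    set.seed(derive_seed(seed, 1000L + match(w, plate_map$well)))
    n <- max(10L, stats::rpois(1L, n_cells))
    x <- matrix(0, n, n_features, dimnames = list(NULL, fnames))
    for (j in seq_len(n_features)) {
      base <- switch(fam[j],
        normal = stats::rnorm(n),
        # centred, unit-ish scale versions so mu/sigma stay interpretable
        lognormal = (stats::rlnorm(n, 0, 0.5) - exp(0.125)) / 0.6,
        t = stats::rt(n, df = 5) / sqrt(5 / 3))
      x[, j] <- mu[j] + sigma[j] * base
    }
    row <- plate_map[map_idx[i], ]
    if (row$kind != "vehicle" && !is.na(row$treatment_id)) {
      eff <- ground_truth$effects[[row$treatment_id]]
      if (!is.null(eff)) {
        s <- conc_scale(row$concentration %||% ground_truth$ec50,
                        ground_truth$ec50)
        if (is.na(s)) s <- 1
        x <- x + rep(eff * s * sigma, each = n)
      }
    }
    out[[i]] <- x
  }
  list(cells = out, plate_map = plate_map)
}

#' Generate a synthetic aligned LC-MS feature table
#'
#' Features get uniform retention times in `rt_range` minutes and m/z in
#' `mz_range`. The first `length(active_samples)` features are planted
#' bioactive markers, present exactly in their stated sample sets; the
#' remaining background features are present in `background_cardinality`
#' samples drawn uniformly. Independently, every absent cell flips to a
#' false presence with probability `background_rate`. Present cells get
#' log-normal intensities; absent cells are 0.
#'
#' @param samples character vector of sample ids (table columns).
#' @param n_features total feature count (>= number of planted features).
#' @param active_samples named list: planted-feature label -> character
#'   vector (>= 2) of containing sample ids.
#' @param background_cardinality containing-set size for background
#'   features.
#' @param background_rate false-presence probability in \[0, 1\].
#' @param seed RNG seed.
#' @param rt_range,mz_range feature coordinate ranges (minutes, Th).
#' @return list with `table` (data frame `feature_id`, `rt`, `mz`, one
#'   intensity column per sample), `active_ids` (feature ids of the planted
#'   markers, named by their `active_samples` labels), `incidence` (logical
#'   features x samples presence matrix as generated).
#' @export
synth_ms_features <- function(samples, n_features = 120L,
                              active_samples = list(),
                              background_cardinality = 4L,
                              background_rate = 0.02, seed = 1L,
                              rt_range = c(0, 11), mz_range = c(50, 1500)) {
  n_active <- length(active_samples)
  if (n_features < n_active)
    stop("n_features is smaller than the number of planted active features",
         call. = FALSE)
  for (nm in names(active_samples)) {
    s <- active_samples[[nm]]
    if (length(s) < 2L)
      stop(sprintf("planted feature '%s' needs >= 2 containing samples", nm),
           call. = FALSE)
    if (!all(s %in% samples))
      stop(sprintf("planted feature '%s' references unknown samples", nm),
           call. = FALSE)
  }
  set.seed(derive_seed(seed, 31L))
  rt <- round(stats::runif(n_features, rt_range[1], rt_range[2]), 2)
  mz <- round(stats::runif(n_features, mz_range[1], mz_range[2]), 4)
  ids <- sprintf("%.2f_%.4f", rt, mz)
  while (anyDuplicated(ids)) { # vanishingly rare; keep ids unique
    dup <- which(duplicated(ids))
    mz[dup] <- round(stats::runif(length(dup), mz_range[1], mz_range[2]), 4)
    ids <- sprintf("%.2f_%.4f", rt, mz)
  }

  inc <- matrix(FALSE, n_features, length(samples),
                dimnames = list(ids, samples))
  for (k in seq_len(n_active))
    inc[k, active_samples[[k]]] <- TRUE
  card <- min(background_cardinality, length(samples))
  for (k in seq.int(n_active + 1L, length.out = n_features - n_active))
    inc[k, sample(seq_along(samples), card)] <- TRUE
  if (background_rate > 0) {
    flip <- matrix(stats::runif(length(inc)) < background_rate,
                   nrow(inc), ncol(inc))
    inc <- inc | flip
  }

  intensity <- matrix(0, n_features, length(samples),
                      dimnames = list(ids, samples))
  n_present <- sum(inc)
  intensity[inc] <- stats::rlnorm(n_present, meanlog = 11, sdlog = 1)

  table <- data.frame(feature_id = ids, rt = rt, mz = mz, intensity,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      row.names = NULL)
  active_ids <- stats::setNames(ids[seq_len(n_active)], names(active_samples))
  list(table = table, active_ids = active_ids, incidence = inc)
}

#' Generate a synthetic known-MOA reference library
#'
#' Fingerprints within a mechanism-of-action class are Gaussian draws
#' around a shared class centroid; class labels are retained so clustering
#' purity can be scored against ground truth. Optionally appends tight
#' positive-control replicates around their own centroid (label `"POS"`),
#' used to exercise dendrogram gating.
#'
#' @param n_compounds library size (>= `n_moa_classes`).
#' @param n_moa_classes number of MOA classes.
#' @param n_features fingerprint length.
#' @param noise within-class SD relative to the unit-SD centroid draw.
#' @param n_pos_replicates positive-control replicate count (0 = none).
#' @param pos_noise within-replicate SD for the positive control.
#' @param seed RNG seed.
#' @return list with `fingerprints` (matrix, rownames = compound ids),
#'   `labels` (named character), `pos_ids`.
#' @export
synth_reference_library <- function(n_compounds = 60L, n_moa_classes = 5L,
                                    n_features = 50L, noise = 0.3,
                                    n_pos_replicates = 0L, pos_noise = 0.05,
                                    seed = 1L) {
  if (n_compounds < n_moa_classes)
    stop("n_compounds must be >= n_moa_classes", call. = FALSE)
  set.seed(derive_seed(seed, 41L))
  centroids <- matrix(stats::rnorm(n_moa_classes * n_features),
                      n_moa_classes, n_features)
  cls <- rep(seq_len(n_moa_classes), length.out = n_compounds)
  fp <- centroids[cls, , drop = FALSE] +
    noise * matrix(stats::rnorm(n_compounds * n_features),
                   n_compounds, n_features)
  ids <- sprintf("lib_%03d", seq_len(n_compounds))
  labels <- stats::setNames(sprintf("MOA%d", cls), ids)
  pos_ids <- character(0)
  if (n_pos_replicates > 0L) {
    pc <- stats::rnorm(n_features, 0, 1.5)
    pos <- matrix(rep(pc, each = n_pos_replicates), n_pos_replicates) +
      pos_noise * matrix(stats::rnorm(n_pos_replicates * n_features),
                         n_pos_replicates, n_features)
    pos_ids <- sprintf("pos_%02d", seq_len(n_pos_replicates))
    rownames(pos) <- pos_ids
    fp <- rbind(fp, pos)
    labels <- c(labels, stats::setNames(rep("POS", n_pos_replicates), pos_ids))
    ids <- c(ids, pos_ids)
  }
  rownames(fp) <- ids
  colnames(fp) <- sprintf("f%03d", seq_len(n_features))
  list(fingerprints = fp, labels = labels, pos_ids = pos_ids)
}
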