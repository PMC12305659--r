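#' Histogram-difference (HistDiff) normalization of a treated well
#'
#' Converts the single-cell feature distributions of one treated well into a
#' signed per-feature score against the pooled vehicle-control distribution.
#' For each feature a common equal-width bin grid is laid over the pooled
#' range of control plus treated values, both distributions are histogrammed,
#' optionally smoothed with a small Gaussian kernel over bins, and rescaled
#' to unit mass. The score is the total histogram discrepancy
#' \eqn{\sum_b |h_{trt}(b) - h_{ctl}(b)| = 2 (1 - \mathrm{overlap})},
#' signed by the direction of displacement relative to the control median:
#' positive when treated mass sits predominantly above the control median,
#' negative below. Identical distributions score 0 and \eqn{|score| \le 2}.
#'
#' @param treated numeric matrix, cells x features, for one well.
#' @param control numeric matrix (or list of matrices, pooled by row-binding)
#'   of vehicle-control cells x features.
#' @param n_bins number of histogram bins (>= 8).
#' @param smooth standard deviation, in bins, of the Gaussian smoothing
#'   kernel applied to both histograms; 0 disables smoothing.
#' @param well optional well address used in error messages.
#' @return named numeric vector of HistDiff scores, one per feature.
#' @examples
#' ctl <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' trt <- cbind(a = rnorm(300, 3), b = rnorm(300))
#' round(histdiff_normalize(trt, ctl), 2)
#' @export
histdiff_normalize <- function(treated, control, n_bins = 32L, smooth = 1,
                               well = NULL) {
  if (is.list(control) && !is.matrix(control))
    control <- do.call(rbind, control)
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  if (nrow(treated) == 0L)
    stop("empty treated cell table", if (!is.null(well))
      sprintf(" for well '%s'", well), call. = FALSE)
  if (nrow(control) == 0L) stop("vehicle control pool is empty", call. = FALSE)
  if (ncol(treated) != ncol(control))
    stop("treated and control feature counts differ", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 8L) stop("n_bins must be >= 8", call. = FALSE)

  p <- ncol(treated)
  feat <- colnames(treated) %||% paste0("f", seq_len(p))

  lo <- pmin(col_min(treated), col_min(control))
  hi <- pmax(col_max(treated), col_max(control))
  const <- !is.finite(lo) | !is.finite(hi) | (hi - lo) <= 0
  if (any(const))
    notice("HistDiff: %d constant feature(s) scored 0 (e.g. '%s')",
           sum(const), feat[which(const)[1L]])
  width <- (hi - lo) / n_bins
  width[const] <- 1 # avoid 0-division; scores forced to 0 below

  h_t <- bin_counts(treated, lo, width, n_bins)
  h_c <- bin_counts(control, lo, width, n_bins)
  if (smooth > 0) {
    K <- smoothing_kernel(n_bins, smooth)
    h_t <- K %*% h_t
    h_c <- K %*% h_c
  }
  h_t <- sweep(h_t, 2L, colSums(h_t), "/")
  h_c <- sweep(h_c, 2L, colSums(h_c), "/")

  # direction weights: +1 strictly above the control-median bin, -1 at/below
  med_bin <- bin_of(apply(control, 2L, stats::median), lo, width, n_bins)
  bins <- seq_len(n_bins)
  S <- outer(bins, med_bin, ">") * 2 - 1

  diff <- h_t - h_c
  magnitude <- colSums(abs(diff))
  direction <- colSums(diff * S)
  score <- magnitude * sign(direction)
  score[const] <- 0
  names(score) <- feat
  score
}

col_min <- function(x) suppressWarnings(apply(x, 2L, min))
col_max <- function(x) suppressWarnings(apply(x, 2L, max))

# equal-width bin index for one value per feature, clamped to [1, n_bins]
bin_of <- function(x, lo, width, n_bins) {
  idx <- floor((x - lo) / width) + 1L
  pmin(pmax(idx, 1L), n_bins)
}

bin_counts <- function(x, lo, width, n_bins) {
  n <- nrow(x); p <- ncol(x)
  idx <- floor(sweep(sweep(x, 2L, lo, "-"), 2L, width, "/")) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  off <- rep((seq_len(p) - 1L) * n_bins, each = n)
  matrix(tabulate(as.integer(idx) + off, nbins = n_bins * p),
         nrow = n_bins, ncol = p)
}

smoothing_kernel <- function(n_bins, smooth) {
  K <- stats::dnorm(outer(seq_len(n_bins), seq_len(n_bins), "-"), sd = smooth)
  sweep(K, 2L, colSums(K), "/") # column-stochastic: mass preserved
}

#' HistDiff profiles for every treated well on a plate
#'
#' Pools the vehicle-control wells of a plate and applies
#' [histdiff_normalize()] to every non-vehicle well with cell data.
#'
#' @param cell_tables named list (by well address) of cells x features
#'   matrices.
#' @param plate_map plate-map data frame as produced by [synth_plate_map()]
#'   (columns `well`, `kind`, `treatment_id`, `concentration`).
#' @inheritParams histdiff_normalize
#' @param vehicle_loo also score each vehicle well, leave-one-out against
#'   the pool of the remaining vehicle wells (needed for the vehicle CP
#'   reference of [activity_filter()]).
#' @return matrix wells x features of HistDiff scores, rownames = well
#'   addresses (treated wells, then vehicle wells when `vehicle_loo`).
#' @export
profile_wells <- function(cell_tables, plate_map, n_bins = 32L, smooth = 1,
                          vehicle_loo = FALSE) {
  stopifnot(is.list(cell_tables), !is.null(names(cell_tables)))
  plate_map <- validate_plate_map(plate_map)
  veh_wells <- intersect(plate_map$well[plate_map$kind == "vehicle"],
                         names(cell_tables))
  if (length(veh_wells) == 0L)
    stop("no vehicle wells with cell data on this plate", call. = FALSE)
  control <- do.call(rbind, cell_tables[veh_wells])
  treated_wells <- setdiff(names(cell_tables), veh_wells)
  prof <- t(vapply(
    treated_wells,
    function(w) histdiff_normalize(cell_tables[[w]], control,
                                   n_bins = n_bins, smooth = smooth,
                                   well = w),
    numeric(ncol(control))
  ))
  if (vehicle_loo) {
    if (length(veh_wells) < 2L)
      stop("leave-one-out vehicle profiling needs >= 2 vehicle wells",
           call. = FALSE)
    vprof <- t(vapply(
      veh_wells,
      function(w) histdiff_normalize(
        cell_tables[[w]],
        do.call(rbind, cell_tables[setdiff(veh_wells, w)]),
        n_bins = n_bins, smooth = smooth, well = w),
      numeric(ncol(control))
    ))
    prof <- rbind(prof, vprof)
  }
  prof
}

#' Per-sample Cell Painting phenotype-strength score
#'
#' The CP score summarises a HistDiff profile into one nonnegative scalar:
#' the Euclidean norm \eqn{\sqrt{\sum_j d_j^2}} over all features (default),
#' or the plain sum of squares with `sqrt = FALSE`.
#'
#' @param profile numeric vector (one well/sample) or matrix (rows =
#'   wells/samples) of HistDiff scores.
#' @param sqrt take the square root (Euclidean norm)? Default `TRUE`.
#' @return numeric scalar or named vector of CP scores, all `>= 0`.
#' @examples
#' cp_score(c(3, 4, 0, 0)) # 5
#' @export
cp_score <- function(profile, sqrt = TRUE) {
  if (is.matrix(profile)) {
    ss <- rowSums(profile^2)
  } else {
    stopifnot(is.numeric(profile))
    ss <- sum(profile^2)
  }
  if (!all(is.finite(ss))) stop("non-finite HistDiff profile", call. = FALSE)
  if (sqrt) base::sqrt(ss) else ss
}

#' Vehicle-based activity filter
#'
#' Removes samples whose CP score is at or below the vehicle-control
#' reference; only samples strictly above the reference are retained.
#' The reference statistic over the vehicle CP scores is the maximum by
#' default (conservative), with median and an upper quantile as
#' alternatives.
#'
#' @param scores named numeric vector of sample CP scores.
#' @param vehicle_scores numeric vector of vehicle-well CP scores (>= 1).
#' @param stat reference statistic: `"max"`, `"median"` or `"quantile"`.
#' @param q quantile level when `stat = "quantile"`.
#' @return character vector of retained sample names (possibly empty).
#' @export
activity_filter <- function(scores, vehicle_scores,
                            stat = c("max", "median", "quantile"),
                            q = 0.95) {
  stat <- match.arg(stat)
  if (length(vehicle_scores) < 1L)
    stop("need at least one vehicle CP score", call. = FALSE)
  ref <- switch(stat,
    max = max(vehicle_scores),
    median = stats::median(vehicle_scores),
    quantile = stats::quantile(vehicle_scores, q, names = FALSE)
  )
  names(scores)[scores > ref]
}

#' Scale HistDiff profiles to \[0, 1\] bioactivity fingerprints
#'
#' Takes absolute HistDiff values and min-max scales each feature across
#' samples to \[0, 1\], the fingerprint format consumed by the networking
#' stage. Features with zero range map to 0.
#'
#' @param profiles matrix samples x features of HistDiff scores.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
fingerprint_normalize <- function(profiles) {
  a <- abs(as.matrix(profiles))
  lo <- col_min(a)
  rng <- col_max(a) - lo
  flat <- rng <= 0
  rng[flat] <- 1
  out <- sweep(sweep(a, 2L, lo, "-"), 2L, rng, "/")
  out[, flat] <- 0
  out
}
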