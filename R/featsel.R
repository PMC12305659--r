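#' Equal-frequency discretization
#'
#' Bins a continuous vector into (at most) `bins` classes at its empirical
#' quantiles. Duplicate cut points (heavy ties) collapse, so fewer classes
#' may result. Already-discrete input (factor, character, logical, or few
#' unique values) is passed through unchanged.
#'
#' @param x numeric (or discrete) vector.
#' @param bins target number of bins.
#' @return integer/factor vector of discrete codes, same length as `x`.
#' @export
discretize_ef <- function(x, bins = 5L) {
  if (is.factor(x) || is.character(x) || is.logical(x)) return(as.factor(x))
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  cuts <- unique(stats::quantile(x, probs = seq_len(bins - 1L) / bins,
                                 names = FALSE, type = 7))
  findInterval(x, cuts, left.open = TRUE) + 1L
}

entropy_nat <- function(x) {
  p <- table(x)
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' \eqn{SU(X,Y) = 2 I(X;Y) / (H(X) + H(Y))}, a normalized mutual
#' information in \[0, 1\]: 0 for independent variables, 1 for a bijective
#' relation between nonconstant variables. Continuous inputs are
#' discretized first with [discretize_ef()]. A constant vector has zero
#' entropy; SU is then defined as 0 (with a notice).
#'
#' @param x,y vectors of equal length (>= 2).
#' @param bins discretization bins for continuous input.
#' @return SU value in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(x, y, bins = 5L) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  x <- discretize_ef(x, bins)
  y <- discretize_ef(y, bins)
  hx <- entropy_nat(x)
  hy <- entropy_nat(y)
  if (hx + hy <= 0) {
    notice("symmetrical_uncertainty: constant vector(s), SU defined as 0")
    return(0)
  }
  if (hx == 0 || hy == 0) {
    notice("symmetrical_uncertainty: constant vector, SU defined as 0")
    return(0)
  }
  joint <- entropy_nat(paste(x, y, sep = "\r"))
  mi <- max(hx + hy - joint, 0)
  min(2 * mi / (hx + hy), 1)
}

#' Permutation-null relevance threshold for FCBF
#'
#' A data-driven choice of the FCBF relevance cutoff: the class labels are
#' permuted `n_perm` times, the maximum SU-with-class across features is
#' recorded for each permutation, and the threshold is the median of those
#' maxima — an estimate of the strongest relevance producible by chance
#' alone on this matrix.
#'
#' @inheritParams fcbf
#' @param n_perm number of label permutations.
#' @param seed RNG seed (permutation determinism).
#' @return a threshold in \[0, 1\].
#' @export
fcbf_auto_threshold <- function(profiles, class_labels, bins = 5L,
                                n_perm = 10L, seed = 1L) {
  profiles <- as.matrix(profiles)
  disc <- lapply(seq_len(ncol(profiles)),
                 function(j) discretize_ef(profiles[, j], bins))
  set.seed(derive_seed(seed, 51L))
  maxima <- vapply(seq_len(n_perm), function(k) {
    perm <- sample(class_labels)
    max(vapply(disc, function(d)
      suppressMessages(symmetrical_uncertainty(d, perm, bins)), 0))
  }, 0)
  stats::median(maxima)
}

#' Fast correlation-based filtering (FCBF)
#'
#' Supervised feature reduction by symmetrical uncertainty: features are
#' ranked by SU with the class label, those below `su_threshold` are
#' dropped, then the ranked list is scanned and every feature whose SU with
#' an already-kept, higher-ranked feature is at least its SU with the class
#' is removed as redundant (the predominant-feature search). Constant
#' (invariant) features are always removed. Ties in SU are broken
#' lexicographically by feature id for reproducibility.
#'
#' @param profiles numeric matrix samples x features (column names = feature
#'   ids).
#' @param class_labels per-sample discrete label; at least two classes.
#' @param su_threshold minimum SU with the class, in `[0, 1)`.
#' @param bins discretization bins for continuous features.
#' @return list with `selected` (feature ids, decreasing relevance) and
#'   `su_with_class` (named numeric over all input features).
#' @export
fcbf <- function(profiles, class_labels, su_threshold = 0, bins = 5L) {
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("f", seq_len(ncol(profiles)))
  stopifnot(nrow(profiles) == length(class_labels),
            su_threshold >= 0, su_threshold < 1)
  if (length(unique(class_labels)) < 2L)
    stop("FCBF needs at least two classes in class_labels", call. = FALSE)

  disc <- lapply(seq_len(ncol(profiles)),
                 function(j) discretize_ef(profiles[, j], bins))
  names(disc) <- colnames(profiles)
  su_c <- vapply(disc, function(d)
    suppressMessages(symmetrical_uncertainty(d, class_labels, bins)), 0)

  keep <- su_c > su_threshold # strict: constants (SU 0) never pass
  order_ids <- names(sort(su_c[keep], decreasing = TRUE))
  # stable tie-break: decreasing SU, then lexicographic id
  order_ids <- order_ids[order(-su_c[order_ids], order_ids)]

  selected <- character(0)
  remaining <- order_ids
  while (length(remaining) > 0L) {
    f <- remaining[1L]
    selected <- c(selected, f)
    remaining <- remaining[-1L]
    if (length(remaining) > 0L) {
      red <- vapply(remaining, function(g) {
        suppressMessages(symmetrical_uncertainty(disc[[g]], disc[[f]],
                                                 bins)) >= su_c[[g]]
      }, logical(1))
      remaining <- remaining[!red]
    }
  }
  list(selected = selected, su_with_class = su_c)
}
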