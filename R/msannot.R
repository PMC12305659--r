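# Monoisotopic atomic masses (Da), CODATA/IUPAC values. C is exactly 12 by
# definition of the unified atomic mass unit.
MONOISOTOPIC_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  S  = 31.97207100,
  P  = 30.97376163,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Si = 27.9769265325
)

ELECTRON_MASS <- 0.00054857990907

#' Parse a molecular formula
#'
#' Accepts Hill-style formula strings such as `"C22H35NO5"`. Underscore
#' subscript markup (`"C_22_H_35_NO_5_"`), whitespace and middle dots are
#' stripped before parsing. Counts for repeated element symbols accumulate.
#'
#' @param text formula string.
#' @return named integer vector of element counts, class `"formula_counts"`.
#' @examples
#' parse_formula("C22H35NO5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("[_[:space:]\u00b7.]", "", text)
  if (!nzchar(clean)) stop("empty formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  toks <- regmatches(clean, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(clean))
    stop(sprintf("cannot parse formula '%s'", text), call. = FALSE)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(MONOISOTOPIC_MASS))
      stop(sprintf("unknown element symbol '%s' in formula '%s'", el, text),
           call. = FALSE)
    cur <- if (el %in% names(counts)) counts[[el]] else 0L
    counts[el] <- cur + n
  }
  counts <- counts[counts > 0L]
  structure(counts, class = "formula_counts")
}

#' @export
format.formula_counts <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (x[[e]] > 1L) x[[e]] else ""), ""), collapse = "")
}

#' @export
print.formula_counts <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic atomic masses
#' (C = 12 exactly, H = 1.00782503, N = 14.0030740, O = 15.9949146,
#' Na = 22.9897693, ...).
#'
#' @param f a `formula_counts` object from [parse_formula()] or a formula
#'   string.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.0105646
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}

#' Parse an ESI adduct rule
#'
#' Understands singly charged positive-mode adduct names of the form
#' `[M+H]+`, `[M+Na]+`, `[M+H-H2O-CH2O]+`: every `+X` / `-X` term after `M`
#' is a molecular formula whose monoisotopic mass is gained or lost. En
#' dashes and spaces are tolerated.
#'
#' @param name adduct name string.
#' @return list with `name` (canonical form), `mass_delta` (Da, signed) and
#'   `charge` (+1).
#' @examples
#' adduct_rule("[M + Na]+")$mass_delta
#' @export
adduct_rule <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  clean <- gsub("\u2212|\u2013|\u2014", "-", name) # unicode minus/dashes
  clean <- gsub("[[:space:]]|\\^", "", clean)
  body <- sub("^\\[(.*)\\]\\+?$", "\\1", clean)
  if (!grepl("^M([+-][A-Za-z0-9]+)*$", body))
    stop(sprintf("unknown adduct rule '%s'", name), call. = FALSE)
  m <- gregexpr("[+-][A-Za-z0-9]+", body)[[1]]
  terms <- if (m[1] == -1L) character(0) else regmatches(body, list(m))[[1]]
  delta <- 0
  canon <- "M"
  for (term in terms) {
    sgn <- if (substr(term, 1L, 1L) == "+") 1 else -1
    frag <- substring(term, 2L)
    delta <- delta + sgn * monoisotopic_mass(parse_formula(frag))
    canon <- paste0(canon, substr(term, 1L, 1L), frag)
  }
  list(name = paste0("[", canon, "]+"), mass_delta = delta, charge = 1L)
}

#' Theoretical adduct m/z
#'
#' `M + mass_delta` for a singly charged adduct. By convention of the
#' upstream vendor software this package mirrors, the electron mass is not
#' subtracted by default; set `electron_correction = TRUE` for the strict
#' physical value.
#'
#' @param M neutral monoisotopic mass (Da), `> 0`.
#' @param rule adduct name string or the result of [adduct_rule()].
#' @param electron_correction subtract one electron mass?
#' @return theoretical m/z (Th).
#' @examples
#' adduct_mz(monoisotopic_mass("C22H35NO5"), "[M+Na]+")
#' @export
adduct_mz <- function(M, rule, electron_correction = FALSE) {
  stopifnot(is.numeric(M), all(M > 0))
  if (is.character(rule)) rule <- adduct_rule(rule)
  mz <- M + rule$mass_delta
  if (electron_correction) mz <- mz - rule$charge * ELECTRON_MASS
  mz
}

#' Signed mass accuracy in parts per million
#'
#' @param observed observed m/z (Th), `> 0`.
#' @param theoretical theoretical m/z (Th), `> 0`.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(observed > 0), all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Annotate MS features against a compound database
#'
#' Enumerates every (feature, compound, adduct) triple and keeps those whose
#' absolute ppm error is within tolerance, ranked by increasing |ppm|.
#' Features may receive multiple candidate annotations.
#'
#' @param table MS feature table data frame (columns `feature_id`, `rt`,
#'   `mz`, then per-sample intensities), e.g. from [read_ms_features()] or
#'   [synth_ms_features()].
#' @param db compound database data frame with columns `name` and `formula`
#'   (optional `cas` carried through).
#' @param rules character vector of adduct names (default `[M+H]+` and
#'   `[M+Na]+`).
#' @param tol_ppm ppm tolerance, `> 0`.
#' @param electron_correction passed to [adduct_mz()].
#' @return data frame `feature_id`, `compound`, `adduct`, `theoretical_mz`,
#'   `ppm`, ordered by |ppm|.
#' @export
annotate_features <- function(table, db, rules = c("[M+H]+", "[M+Na]+"),
                              tol_ppm = 10, electron_correction = FALSE) {
  stopifnot(tol_ppm > 0)
  empty <- data.frame(feature_id = character(0), compound = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0), stringsAsFactors = FALSE)
  if (nrow(db) == 0L) {
    warning("empty compound database: no annotations", call. = FALSE)
    return(empty)
  }
  rules <- lapply(rules, function(r) if (is.character(r)) adduct_rule(r) else r)
  M <- vapply(db$formula, function(f) monoisotopic_mass(parse_formula(f)), 0)
  cand <- do.call(rbind, lapply(rules, function(r) {
    data.frame(compound = db$name, adduct = r$name,
               theoretical_mz = adduct_mz(M, r, electron_correction),
               stringsAsFactors = FALSE)
  }))
  hits <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    ppm <- ppm_error(table$mz[i], cand$theoretical_mz)
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) return(NULL)
    data.frame(feature_id = table$feature_id[i], cand[keep, , drop = FALSE],
               ppm = ppm[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) return(empty)
  hits <- hits[order(abs(hits$ppm), hits$feature_id, hits$compound), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
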