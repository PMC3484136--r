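# Minimum-free-energy indices and the logistic feature score.
#
# Only the three indices that carry signal beyond the Markov log-odds are
# implemented: MFEI1 (stability per GC content), MFEI2 (stability per stem)
# and MFEI4 (MFE per base pair). All are computed on the full structure,
# before any main-stem reduction, following the feature literature's
# conventions: dMFE = -MFE / n * 100 (per 100 nt), GC as a percentage, and
# MFEI4 on the signed (negative) MFE.

#' Compute the MFE-related structure features of a hairpin
#'
#' @param h a [hairpin_record()] with a dot-bracket structure and an MFE.
#' @return list of class `"mfe_features"`: `mfei1`, `mfei2`, `mfei4`,
#'   `dmfe` (adjusted MFE per 100 nt), `gc_pct`, `n_stems` (maximal helices
#'   of >= 3 stacked pairs), `n_bp`.
#' @examples
#' h <- hairpin_record("h", "GGGGAAAACCCC", "((((....))))", mfe = -6)
#' compute_mfe_features(h)$mfei1   # 0.75
#' @export
compute_mfe_features <- function(h) {
  stopifnot(inherits(h, "hairpin_record"))
  if (is.na(h$mfe)) stop(sprintf("record '%s' has no MFE", h$id))
  n <- nchar(h$sequence)
  pt <- parse_pairs(h$dotbracket)
  n_bp <- nrow(pt$pairs)
  if (n_bp == 0L)
    stop(sprintf("degenerate hairpin '%s': no base pairs", h$id))
  gc_pct <- 100 * lengths(regmatches(h$sequence, gregexpr("[GC]", h$sequence))) / n
  if (gc_pct == 0)
    stop(sprintf("degenerate hairpin '%s': GC content is zero", h$id))
  n_stems <- count_stems(pt)
  if (n_stems == 0L)
    stop(sprintf("degenerate hairpin '%s': no stem of >= 3 stacked pairs", h$id))
  dmfe <- -h$mfe / n * 100
  structure(list(mfei1 = dmfe / gc_pct, mfei2 = dmfe / n_stems,
                 mfei4 = h$mfe / n_bp, dmfe = dmfe, gc_pct = unname(gc_pct),
                 n_stems = n_stems, n_bp = n_bp),
            class = "mfe_features")
}

# maximal runs of contiguous stacked pairs (i,j),(i+1,j-1),... of length >= 3
count_stems <- function(pt) {
  P <- pt$pairs   # already sorted by i
  if (nrow(P) == 0L) return(0L)
  if (nrow(P) == 1L) return(0L)
  stacked <- P[-1L, 1L] == P[-nrow(P), 1L] + 1L &
             P[-1L, 2L] == P[-nrow(P), 2L] - 1L
  helix_id <- cumsum(c(TRUE, !stacked))
  sum(tabulate(helix_id) >= 3L)
}

#' Logistic regression coefficients of the feature score
#'
#' Defaults are the fitted binary-logistic coefficients shipped with the
#' predictor: MFEI1 -0.209, MFEI2 0.034, MFEI4 1.679, intercept -13.686.
#'
#' @param mfei1,mfei2,mfei4,const finite regression coefficients.
#' @return list of class `"feature_coefficients"`.
#' @export
feature_coefficients <- function(mfei1 = -0.209, mfei2 = 0.034,
                                 mfei4 = 1.679, const = -13.686) {
  co <- list(mfei1 = mfei1, mfei2 = mfei2, mfei4 = mfei4, const = const)
  if (!all(vapply(co, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all coefficients must be finite numbers")
  structure(co, class = "feature_coefficients")
}

#' Logistic feature score of a hairpin
#'
#' `logistic(const + b1 * MFEI1 + b2 * MFEI2 + b4 * MFEI4)`, a probability in
#' (0, 1). In the combined score it enters as `feature_weight * score`
#' (default weight 50), so the feature can add at most `feature_weight` to
#' the Markov log-odds.
#'
#' @param f an `"mfe_features"` object from [compute_mfe_features()].
#' @param coeffs a [feature_coefficients()] object.
#' @return score in (0, 1).
#' @export
feature_score <- function(f, coeffs = feature_coefficients()) {
  stopifnot(inherits(f, "mfe_features"), inherits(coeffs, "feature_coefficients"))
  stats::plogis(coeffs$const + coeffs$mfei1 * f$mfei1 +
                coeffs$mfei2 * f$mfei2 + coeffs$mfei4 * f$mfei4)
}
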