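#' Constants for the marine-fish lipid normalization of delta-13C
#'
#' Parameter set for the closed-form lipid correction of bulk-tissue
#' \eqn{\delta^{13}}C from the mass C:N ratio, in the marine-organism
#' parameterization of Kiljunen and colleagues.  The correction adds
#' \deqn{D \left( I + \frac{3.90}{1 + 287 / L} \right), \quad
#'   L = \frac{93}{1 + (0.246\,\mathrm{C{:}N} - 0.775)^{-1}}}
#' to the measured \eqn{\delta^{13}}C, where `D` is the isotopic
#' difference between protein and lipid (per mil) and `L` is the
#' estimated percent lipid content of the tissue.
#'
#' @param D protein-lipid discrimination, per mil (default 7.018).
#' @param I constant offset inside the parenthesis (default 0.048).
#' @param a,b coefficients of the lipid-content model
#'   `L = scale / (1 + 1/(a * CN - b))` (defaults 0.246 and 0.775).
#' @param scale asymptotic percent-lipid scale (default 93).
#' @param saturation saturation constant in the correction term
#'   (default 287).
#' @return A named list of class `lipid_norm_constants`.
#' @seealso [lipid_normalize_d13c()]
#' @export
lipid_norm_constants <- function(D = 7.018, I = 0.048, a = 0.246,
                                 b = 0.775, scale = 93, saturation = 287) {
  stopifnot(D >= 0, scale > 0, a > 0)
  structure(list(D = D, I = I, a = a, b = b, scale = scale,
                 saturation = saturation),
            class = "lipid_norm_constants")
}

#' Valid C:N threshold of the lipid-content model
#'
#' Below `b / a` (about 3.15 at defaults) the modelled lipid content is
#' undefined or negative and the correction cannot be applied.
#'
#' @param constants a [lipid_norm_constants()] list.
#' @return The threshold mass C:N ratio.
#' @export
cn_validity_threshold <- function(constants = lipid_norm_constants()) {
  constants$b / constants$a
}

#' Additive lipid-correction term as a function of C:N
#'
#' The per-mil amount added to a measured \eqn{\delta^{13}}C value for a
#' tissue with the given mass C:N ratio.  Strictly increasing in C:N over
#' the valid range at the default constants.
#'
#' @param cn_ratio mass C:N ratio(s); must exceed
#'   [cn_validity_threshold()].
#' @inheritParams cn_validity_threshold
#' @return Numeric vector of corrections, per mil.
#' @export
lipid_correction_term <- function(cn_ratio, constants = lipid_norm_constants()) {
  thr <- cn_validity_threshold(constants)
  if (any(!is.finite(cn_ratio)) || any(cn_ratio <= thr)) {
    stop("C:N ratio must be finite and greater than the validity threshold ",
         format(thr, digits = 6), call. = FALSE)
  }
  L <- constants$scale / (1 + 1 / (constants$a * cn_ratio - constants$b))
  constants$D * (constants$I + 3.90 / (1 + constants$saturation / L))
}

#' Lipid-normalize delta-13C from the tissue C:N ratio
#'
#' Applies the closed-form marine-fish correction to remove the
#' depleting effect of tissue lipid on \eqn{\delta^{13}}C.  Lipid is
#' depleted in \eqn{^{13}}C relative to protein, so the corrected value
#' is never below the measured one at the default constants.
#'
#' @param delta13c measured \eqn{\delta^{13}}C, per mil vs VPDB.
#' @param cn_ratio mass C:N ratio(s), recycled against `delta13c`.
#' @inheritParams cn_validity_threshold
#' @return Lipid-corrected \eqn{\delta^{13}}C, per mil.
#' @export
#' @examples
#' lipid_normalize_d13c(-20.0, 4.0)   # -18.21
lipid_normalize_d13c <- function(delta13c, cn_ratio,
                                 constants = lipid_norm_constants()) {
  stopifnot(is.numeric(delta13c), all(is.finite(delta13c)))
  delta13c + lipid_correction_term(cn_ratio, constants)
}

#' C:N ratio implied by a raw / lipid-corrected delta-13C pair
#'
#' Inverts the correction by one-dimensional root finding: the C:N at
#' which the correction term equals `delta_lc - delta_raw`.  Useful as a
#' consistency check when a source reports both raw and lipid-corrected
#' values but not the C:N itself.
#'
#' @param delta_raw,delta_lc raw and lipid-corrected \eqn{\delta^{13}}C
#'   (per mil); `delta_lc` must exceed `delta_raw` at default constants.
#' @inheritParams cn_validity_threshold
#' @param upper upper bound of the search interval.
#' @return The implied mass C:N ratio.
#' @export
#' @examples
#' implied_cn(-20.48, -17.76)   # about 4.85
implied_cn <- function(delta_raw, delta_lc,
                       constants = lipid_norm_constants(), upper = 100) {
  target <- delta_lc - delta_raw
  thr <- cn_validity_threshold(constants)
  f <- function(cn) lipid_correction_term(cn, constants) - target
  uniroot(f, lower = thr + 1e-8, upper = upper, tol = 1e-12)$root
}

#' Add a lipid-corrected delta-13C column to fish and diet tables
#'
#' Row-wise application of [lipid_normalize_d13c()].  Rows whose C:N is
#' missing or at/below the validity threshold are flagged: their
#' lipid-corrected value is `NA`, the count is reported via `message()`
#' and attached as attribute `n_excluded`.  Original columns are left
#' untouched and row count is preserved.
#'
#' @param x a data frame with a \eqn{\delta^{13}}C column and a C:N
#'   column (per-fish tissue table or per-batch diet table).
#' @param d13c_col,cn_col,out_col column names for input \eqn{\delta^{13}}C,
#'   C:N and the added lipid-corrected column.
#' @inheritParams cn_validity_threshold
#' @return `x` with `out_col` added, attribute `n_excluded` set.
#' @export
apply_lipid_correction <- function(x, d13c_col = "d13c", cn_col = "cn_ratio",
                                   out_col = "d13c_lc",
                                   constants = lipid_norm_constants()) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) {
    x[[out_col]] <- numeric(0)
    attr(x, "n_excluded") <- 0L
    return(x)
  }
  if (!all(c(d13c_col, cn_col) %in% names(x))) {
    stop("columns '", d13c_col, "' and '", cn_col, "' are required",
         call. = FALSE)
  }
  cn <- x[[cn_col]]
  thr <- cn_validity_threshold(constants)
  ok <- is.finite(cn) & cn > thr & is.finite(x[[d13c_col]])
  out <- rep(NA_real_, nrow(x))
  if (any(ok)) {
    out[ok] <- lipid_normalize_d13c(x[[d13c_col]][ok], cn[ok], constants)
  }
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(n_bad, " row(s) with invalid C:N (<= ", format(thr, digits = 6),
            ") excluded from lipid correction")
  }
  x[[out_col]] <- out
  attr(x, "n_excluded") <- as.integer(n_bad)
  x
}
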