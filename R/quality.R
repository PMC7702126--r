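#' Cornilescu quality factor Q
#'
#' \deqn{Q = \sqrt{\sum_i (D_{calc,i} - D_{exp,i})^2 / \sum_i D_{exp,i}^2}}
#' The normalized root-mean-square deviation between back-calculated and
#' experimental RDCs; a relative criterion for comparing structural models
#' (it carries no information about experimental errors).
#'
#' @param dCalc,dExp numeric vectors of equal length, Hz.
#' @return Q, dimensionless.
#' @examples
#' cornilescuQ(c(1, 2), c(1, 2))  # 0
#' @export
cornilescuQ <- function(dCalc, dExp) {
  if (length(dCalc) != length(dExp) || length(dExp) < 1L)
    .err("validation", "dCalc and dExp must have equal length >= 1")
  den <- sum(dExp^2)
  if (den == 0) .err("invalid_input", "all d_exp are zero: Q undefined")
  sqrt(sum((dCalc - dExp)^2) / den)
}

#' Per-coupling error-normalized squared deviations
#'
#' \deqn{\chi_i^2 = ((D_{calc,i} - D_{exp,i}) / \Delta D_{exp,i})^2}
#' with \eqn{\Delta D_{exp,i}} the per-coupling maximum error estimate
#' (~3 sigma). \eqn{\chi_i^2 > 1} means the model misses coupling i by more
#' than its error bound.
#'
#' @param dCalc,dExp,dErr numeric vectors of equal length, Hz; dErr > 0.
#' @return named numeric vector of \eqn{\chi_i^2} (names taken from dExp or
#'   dCalc when present).
#' @export
chi2Terms <- function(dCalc, dExp, dErr) {
  if (length(dCalc) != length(dExp) || length(dExp) != length(dErr))
    .err("validation", "dCalc, dExp, dErr must have equal length")
  if (any(!is.finite(dErr)) || any(dErr <= 0))
    .err("validation", "dErr must be > 0")
  out <- ((dCalc - dExp) / dErr)^2
  nm <- if (!is.null(names(dExp))) names(dExp) else names(dCalc)
  setNames(out, nm)
}

#' Aggregate quality factor n / chi-squared
#'
#' \eqn{n/\chi^2 = n / \sum_i \chi_i^2}: larger is better. A model
#' compatible with every coupling within its maximum error estimate has
#' \eqn{n/\chi^2 > 1}; a value below 1 guarantees at least one violated
#' coupling (the mean of the \eqn{\chi_i^2} exceeding 1 forces the maximum
#' to). A perfect fit returns \code{Inf}.
#'
#' @param object per-coupling \eqn{\chi_i^2} from [chi2Terms()] (numeric), or
#'   a [QualityReport-class].
#' @return dimensionless value (possibly \code{Inf}).
#' @rdname nOverChi2
#' @aliases nOverChi2
#' @export
setMethod("nOverChi2", "numeric", function(object) {
  if (length(object) < 1L) .err("validation", "need >= 1 chi2 term")
  s <- sum(object)
  if (s == 0) Inf else length(object) / s
})

#' Count outlier couplings
#'
#' A coupling is an outlier iff its deviation strictly exceeds the maximum
#' error estimate (\eqn{\chi_i^2 > 1}); a deviation exactly equal to the
#' error counts as fulfilled. Because the errors are ~3-sigma bounds, a
#' single outlier in principle falsifies the structural model.
#'
#' @param chi2 per-coupling \eqn{\chi_i^2}.
#' @return list with \code{count} and integer \code{indices}.
#' @export
countOutliers <- function(chi2) {
  idx <- which(chi2 > 1)
  list(count = length(idx), indices = unname(idx))
}

#' Assemble a QualityReport
#'
#' Computes Q, the per-coupling \eqn{\chi_i^2}, \eqn{n/\chi^2} and the
#' outlier set for one model's back-calculated RDCs.
#'
#' @param dCalc,dExp,dErr numeric vectors, Hz.
#' @param ids vector_ids (defaults to names of dExp, then of dCalc).
#' @return a [QualityReport-class].
#' @examples
#' qualityReport(c(1, 2.4), c(1, 2), c(0.3, 0.3), ids = c("a", "b"))
#' @export
qualityReport <- function(dCalc, dExp, dErr, ids = NULL) {
  if (is.null(ids))
    ids <- if (!is.null(names(dExp))) names(dExp) else names(dCalc)
  if (is.null(ids)) ids <- as.character(seq_along(dExp))
  chi2 <- chi2Terms(dCalc, dExp, dErr)
  names(chi2) <- ids
  out <- countOutliers(chi2)
  new("QualityReport", n = length(dExp),
      dExp = setNames(as.numeric(dExp), ids),
      dCalc = setNames(as.numeric(dCalc), ids),
      dErr = setNames(as.numeric(dErr), ids),
      qFactor = cornilescuQ(dCalc, dExp), chi2 = chi2,
      nOverChi2 = nOverChi2(chi2), outliers = ids[out$indices],
      outlierCount = as.integer(out$count))
}

#' @rdname accessors
setMethod("qFactor", "QualityReport", function(object) object@qFactor)
#' @rdname accessors
setMethod("chi2Values", "QualityReport", function(object) object@chi2)
#' @rdname accessors
setMethod("nOverChi2", "QualityReport", function(object) object@nOverChi2)
#' @rdname accessors
setMethod("outlierIds", "QualityReport", function(object) object@outliers)
#' @rdname accessors
setMethod("outlierCount", "QualityReport", function(object) object@outlierCount)

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: n = %d, Q = %.4f, n/chi2 = %s, outliers = %d\n",
              object@n, object@qFactor,
              if (is.finite(object@nOverChi2))
                sprintf("%.4f", object@nOverChi2) else "Inf",
              object@outlierCount))
  if (object@outlierCount > 0L)
    cat("  outlier couplings:", paste(object@outliers, collapse = ", "), "\n")
})

#' Per-coupling table of a QualityReport
#'
#' @param x a [QualityReport-class].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per coupling: \code{vector_id, d_exp_hz,
#'   d_calc_hz, d_err_hz, chi2, outlier}.
#' @export
as.data.frame.QualityReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(vector_id = names(x@chi2), d_exp_hz = unname(x@dExp),
             d_calc_hz = unname(x@dCalc), d_err_hz = unname(x@dErr),
             chi2 = unname(x@chi2), outlier = unname(x@chi2 > 1),
             stringsAsFactors = FALSE)
}

#' Serialize a QualityReport
#'
#' Writes JSON (aggregate statistics plus the per-coupling table) and/or a
#' flat TSV (one row per coupling).
#'
#' @param report a [QualityReport-class].
#' @param json,tsv output paths (either may be NULL).
#' @return invisibly, the report list written to JSON.
#' @export
writeQualityReport <- function(report, json = NULL, tsv = NULL) {
  tab <- as.data.frame(report)
  out <- list(n = report@n, q_factor = report@qFactor,
              n_over_chi2 = report@nOverChi2,
              outlier_count = report@outlierCount,
              outliers = report@outliers, couplings = tab)
  if (!is.null(json))
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "string")
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
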