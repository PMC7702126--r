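#' @rdname accessors
setMethod("isFalsified", "CandidateResult", function(object) object@falsified)

setMethod("show", "CandidateResult", function(object) {
  cat(sprintf("CandidateResult %s (%s, mode %s): ", object@descriptor,
              ifelse(is.na(object@configId), "unmatched",
                     paste0("id ", object@configId)), object@mode))
  if (!is.na(object@failure)) {
    cat("FAILED -", object@failure, "\n")
  } else {
    q <- object@quality
    cat(sprintf("n/chi2 = %s, outliers = %d%s\n",
                if (is.finite(q@nOverChi2)) sprintf("%.4f", q@nOverChi2)
                else "Inf", q@outlierCount,
                if (object@falsified) " [falsified]" else ""))
  }
})

.candidateResult <- function(descriptor, mode, quality = NULL, tensor = NULL,
                             failure = NA_character_) {
  configId <- if (grepl("^[RS]{7}$", descriptor))
    matchConfigId(descriptor) else NA_integer_
  new("CandidateResult", configId = configId, descriptor = descriptor,
      mode = mode, quality = quality, tensor = tensor,
      falsified = !is.null(quality) && quality@outlierCount >= 1L,
      failure = failure)
}

#' Score an externally supplied set of back-calculated RDCs
#'
#' Evaluate-only scoring: no structures or tensor fit, just the quality
#' statistics of given \eqn{D_{calc}} values against the dataset's
#' \eqn{D_{exp}} and error estimates. Couplings are used when flagged usable
#' in the dataset and present (non-NA) in \code{dCalc}.
#'
#' @param ds a [CouplingDataset-class].
#' @param dCalc numeric back-calculated RDCs named by vector_id (NA entries
#'   are dropped).
#' @param name candidate name (descriptor string when applicable).
#' @return a [CandidateResult-class] with mode "evaluate-only".
#' @examples
#' ds <- rd1CouplingTable()
#' res <- evaluateCalculated(ds, setNames(couplingRecords(ds)$d_calc_mdoc,
#'                                        couplingRecords(ds)$vector_id),
#'                           name = "MDOC")
#' outlierCount(res@quality)  # 0
#' @export
evaluateCalculated <- function(ds, dCalc, name = "candidate") {
  stopifnot(is(ds, "CouplingDataset"))
  rec <- couplingRecords(ds)
  keep <- rec$use_in_fit & rec$vector_id %in% names(dCalc) &
    !is.na(dCalc[rec$vector_id])
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L)
    .err("validation", "no usable couplings covered by dCalc")
  q <- qualityReport(dCalc[rec$vector_id], rec$d_exp_hz, rec$d_err_hz,
                     ids = rec$vector_id)
  .candidateResult(name, "evaluate-only", quality = q)
}

#' Rank scored candidate configurations
#'
#' Orders candidates by descending \eqn{n/\chi^2}; ties are broken by
#' ascending outlier count, then by running number. All candidates must have
#' been scored on the same coupling subset, otherwise their quality factors
#' are not comparable and an error is raised. Failed candidates sort last.
#'
#' @param results list of [CandidateResult-class] objects.
#' @return the same list, reordered; each element's position is its rank.
#' @export
rankCandidates <- function(results) {
  if (length(results) < 1L) .err("validation", "need >= 1 candidate result")
  ok <- vapply(results, function(r) is.na(r@failure), logical(1))
  scored <- results[ok]
  if (length(scored) > 1L) {
    sets <- lapply(scored, function(r) sort(names(r@quality@chi2)))
    if (!all(vapply(sets, identical, logical(1), sets[[1L]])))
      .err("incomparable",
           "candidates scored on different coupling subsets cannot be ranked")
  }
  keyOf <- function(rs) {
    nchi <- vapply(rs, function(r) r@quality@nOverChi2, numeric(1))
    outl <- vapply(rs, function(r) r@quality@outlierCount, integer(1))
    cid <- vapply(rs, function(r) r@configId, integer(1))
    order(-nchi, outl, is.na(cid), cid,
          vapply(rs, function(r) r@descriptor, character(1)))
  }
  failed <- results[!ok]
  if (length(failed) > 1L)
    failed <- failed[order(vapply(failed, function(r) r@descriptor,
                                  character(1)))]
  c(if (length(scored)) scored[keyOf(scored)] else list(), failed)
}

#' Tabulate candidate results
#'
#' @param results list of [CandidateResult-class] objects (ranked or not).
#' @param ranked logical: are positions ranks?
#' @return data.frame with columns \code{config_id, descriptor, mode, n,
#'   n_over_chi2, q, outliers, falsified, rank}.
#' @export
reportTable <- function(results, ranked = TRUE) {
  if (length(results) == 0L)
    return(data.frame(config_id = integer(0), descriptor = character(0),
                      mode = character(0), n = integer(0),
                      n_over_chi2 = numeric(0), q = numeric(0),
                      outliers = integer(0), falsified = logical(0),
                      rank = integer(0), failure = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    q <- r@quality
    data.frame(config_id = r@configId, descriptor = r@descriptor,
               mode = r@mode,
               n = if (is.null(q)) NA_integer_ else q@n,
               n_over_chi2 = if (is.null(q)) NA_real_ else q@nOverChi2,
               q = if (is.null(q)) NA_real_ else q@qFactor,
               outliers = if (is.null(q)) NA_integer_ else q@outlierCount,
               falsified = r@falsified,
               rank = if (ranked) i else NA_integer_,
               failure = r@failure, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the configuration-discrimination pipeline
#'
#' End-to-end orchestration: per candidate, fit or evaluate, score, then
#' rank. Methyl couplings are excluded from the fits in "single" and "multi"
#' modes (fast methyl rotation averages their RDCs) and retained in
#' "ensemble" and "evaluate-only" modes, where averaging is explicit or
#' already done. Per-candidate failures are recorded (and ranked last), not
#' fatal. Re-running with identical inputs yields identical reports.
#'
#' @param candidates named list; element type depends on mode:
#'   \describe{
#'     \item{"single"}{a [Conformer-class] per candidate.}
#'     \item{"multi"}{an [EnsembleModel-class] (fixed weights) or a plain
#'       list of conformers (populations then optimized) per candidate.}
#'     \item{"ensemble"}{an [RdcTimeSeries-class] of per-frame RDCs, or a
#'       list with elements \code{trajectory} and \code{tensor}.}
#'     \item{"evaluate-only"}{a numeric \eqn{D_{calc}} vector named by
#'       vector_id.}
#'   }
#' @param ds a [CouplingDataset-class].
#' @param mode one of "single", "multi", "ensemble", "evaluate-only".
#' @param weighting "none" (default) or "inverse-variance" least-squares
#'   weighting for the tensor fits.
#' @param skip initial frames discarded in ensemble mode.
#' @param effectiveR optional fixed effective C-H distance, Angstrom.
#' @return list with \code{results} (ranked [CandidateResult-class] list;
#'   empty input gives an empty list), \code{table} (see [reportTable()]),
#'   and \code{ranked} (FALSE when candidates cover different coupling
#'   subsets, in which case input order is kept).
#' @export
runPipeline <- function(candidates, ds,
                        mode = c("single", "multi", "ensemble",
                                 "evaluate-only"),
                        weighting = c("none", "inverse-variance"),
                        skip = 0L, effectiveR = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  stopifnot(is(ds, "CouplingDataset"))
  if (length(candidates) == 0L)
    return(list(results = list(),
                table = reportTable(list()), ranked = TRUE))
  if (is.null(names(candidates)))
    .err("validation", "candidates must be a named list")
  dsFit <- if (mode %in% c("single", "multi")) filterMethyls(ds) else ds
  rec <- couplingRecords(dsFit)
  rec <- rec[rec$use_in_fit, , drop = FALSE]
  lsw <- if (weighting == "inverse-variance") 1 / rec$d_err_hz^2 else NULL
  evalOne <- function(obj, name) {
    if (mode == "evaluate-only") return(evaluateCalculated(dsFit, obj, name))
    if (nrow(rec) < 5L && mode != "ensemble")
      .err("underdetermined",
           "tensor fit needs >= 5 usable couplings, got %d", nrow(rec))
    pairs <- rec[, c("vector_id", "atom_c", "atom_h")]
    if (mode == "single") {
      v <- extractVectors(obj, pairs, effectiveR = effectiveR)
      fit <- svdFit(v, rec$d_exp_hz, weights = lsw)
      q <- qualityReport(fit@dCalc, rec$d_exp_hz, rec$d_err_hz,
                         ids = rec$vector_id)
      return(.candidateResult(name, mode, quality = q, tensor = fit@tensor))
    }
    if (mode == "multi") {
      if (is(obj, "EnsembleModel")) {
        fit <- multiConformerFit(obj, pairs, rec$d_exp_hz, weights = lsw,
                                 effectiveR = effectiveR)
      } else {
        fit <- optimizePopulations(obj, pairs, rec$d_exp_hz, rec$d_err_hz,
                                   effectiveR = effectiveR)
      }
      q <- qualityReport(fit@dCalc, rec$d_exp_hz, rec$d_err_hz,
                         ids = rec$vector_id)
      return(.candidateResult(name, mode, quality = q, tensor = fit@tensor))
    }
    # ensemble mode
    if (is(obj, "RdcTimeSeries")) {
      m <- averageRdc(obj, skip = skip)
      tensor <- NULL
    } else {
      out <- ensembleRdcFromTrajectory(obj$trajectory, pairs, obj$tensor,
                                       skip = skip, effectiveR = effectiveR)
      m <- out$mean
      tensor <- obj$tensor
    }
    keep <- rec$vector_id %in% names(m)
    q <- qualityReport(m[rec$vector_id[keep]], rec$d_exp_hz[keep],
                       rec$d_err_hz[keep], ids = rec$vector_id[keep])
    .candidateResult(name, mode, quality = q, tensor = tensor)
  }
  results <- lapply(names(candidates), function(nm) {
    tryCatch(evalOne(candidates[[nm]], nm), error = function(e)
      .candidateResult(nm, mode, failure = conditionMessage(e)))
  })
  ranked <- TRUE
  out <- tryCatch(rankCandidates(results),
                  rdcrank_incomparable = function(e) {
                    ranked <<- FALSE
                    results
                  })
  list(results = out, table = reportTable(out, ranked = ranked),
       ranked = ranked)
}

#' Write a machine-readable pipeline report
#'
#' Writes \code{report.json} and \code{report.tsv} into a directory. The
#' report body carries no timestamps, so identical inputs produce
#' byte-identical reports.
#'
#' @param pipelineResult return value of [runPipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
exportReport <- function(pipelineResult, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- pipelineResult$table
  jsonPath <- file.path(dir, "report.json")
  tsvPath <- file.path(dir, "report.tsv")
  jsonlite::write_json(list(ranked = pipelineResult$ranked,
                            candidates = tab),
                       jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.table(tab, tsvPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json = jsonPath, tsv = tsvPath))
}
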