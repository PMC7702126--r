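#' Construct a CouplingDataset
#'
#' @param records data.frame with the coupling-table columns (see
#'   [CouplingDataset-class]). Rows with missing \code{d_exp_hz} but both
#'   \code{j_iso_hz} and \code{t_aniso_hz} present get the RDC derived as
#'   \eqn{{}^1D = {}^1T - {}^1J}.
#' @param name dataset name.
#' @return a [CouplingDataset-class].
#' @examples
#' rec <- data.frame(vector_id = "C1-H1", atom_c = "C1", atom_h = "H1",
#'                   j_iso_hz = 130.8, t_aniso_hz = 157.5, d_exp_hz = NA,
#'                   d_err_hz = 0.3, group = "CH", use_in_fit = TRUE)
#' couplingDataset(rec)
#' @export
couplingDataset <- function(records, name = "coupling data") {
  missing <- setdiff(.REQUIRED_COUPLING_COLS, names(records))
  if (length(missing) > 0L)
    .err("format", "missing required column(s): %s",
         paste(missing, collapse = ", "))
  derive <- is.na(records$d_exp_hz) & !is.na(records$j_iso_hz) &
    !is.na(records$t_aniso_hz)
  if (any(derive))
    records$d_exp_hz[derive] <-
      deriveRdc(records$j_iso_hz[derive], records$t_aniso_hz[derive])
  bad <- which(is.na(records$d_err_hz) | records$d_err_hz <= 0)
  if (length(bad) > 0L)
    .err("validation", "d_err_hz must be > 0 (violated in row %d)", bad[1L])
  rownames(records) <- NULL
  new("CouplingDataset", records = records, name = name)
}

#' Derive a residual dipolar coupling from splittings
#'
#' The RDC is the difference between the total one-bond splitting under
#' partial alignment and the isotropic scalar coupling:
#' \eqn{{}^1D_{CH} = {}^1T_{CH} - {}^1J_{CH}}.
#'
#' @param jIso isotropic scalar coupling, Hz.
#' @param tAniso total splitting under alignment, Hz.
#' @return RDC in Hz (vectorized).
#' @examples
#' deriveRdc(130.8, 157.5)  # 26.7 Hz
#' @export
deriveRdc <- function(jIso, tAniso) {
  if (any(!is.finite(jIso)) || any(!is.finite(tAniso)))
    .err("invalid_input", "couplings must be finite")
  tAniso - jIso
}

#' Read and write coupling tables (CSV)
#'
#' Comma-separated, UTF-8, "." decimal, mandatory header, "NA" for missing
#' values. Required columns: \code{vector_id, atom_c, atom_h, j_iso_hz,
#' t_aniso_hz, d_exp_hz, d_err_hz, group, use_in_fit}; extra columns (such as
#' back-calculated RDCs) are preserved. Row order is preserved.
#'
#' @param path file path.
#' @param name dataset name (defaults to the file name).
#' @param ds a [CouplingDataset-class].
#' @return \code{readCouplingTable}: a [CouplingDataset-class];
#'   \code{writeCouplingTable}: invisibly, \code{path}.
#' @examples
#' tab <- system.file("extdata", "table3.csv", package = "RDCrank")
#' ds <- readCouplingTable(tab)
#' nrow(couplingRecords(ds))  # 21
#' @export
readCouplingTable <- function(path, name = basename(path)) {
  if (!file.exists(path)) .err("invalid_input", "file not found: %s", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  for (col in c("j_iso_hz", "t_aniso_hz", "d_exp_hz", "d_err_hz"))
    if (col %in% names(rec)) rec[[col]] <- as.numeric(rec[[col]])
  missing <- setdiff(.REQUIRED_COUPLING_COLS, names(rec))
  if (length(missing) > 0L)
    .err("format", "coupling table %s lacks column(s): %s", path,
         paste(missing, collapse = ", "))
  couplingDataset(rec, name = name)
}

#' @rdname readCouplingTable
#' @export
writeCouplingTable <- function(ds, path) {
  stopifnot(is(ds, "CouplingDataset"))
  rec <- couplingRecords(ds)
  # full double precision so that save/load round-trips bit-for-bit
  for (col in names(rec)) if (is.double(rec[[col]]))
    rec[[col]] <- ifelse(is.na(rec[[col]]), NA,
                         sub("(\\.[0-9]*?)0+$", "\\1",
                             sprintf("%.17g", rec[[col]])))
  utils::write.csv(rec, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Exclude methyl couplings from fitting
#'
#' Fast methyl rotation averages the dipolar interaction over the three C-H
#' bonds, so static single- or multi-conformer tensor fits cannot use methyl
#' RDCs directly; their \code{use_in_fit} flag is set to FALSE. The records
#' remain in the dataset (trajectory-averaged evaluation can still score
#' them). Idempotent; all non-methyl flags are left untouched.
#'
#' @param ds a [CouplingDataset-class].
#' @return a modified copy of \code{ds}.
#' @examples
#' ds <- filterMethyls(rd1CouplingTable())
#' nUsable(ds)  # 19
#' @export
filterMethyls <- function(ds) {
  stopifnot(is(ds, "CouplingDataset"))
  rec <- ds@records
  rec$use_in_fit[rec$group == "CH3"] <- FALSE
  initialize(ds, records = rec)
}

#' Diagnose amine inversion from the Perlin effect
#'
#' Adjacent to a nitrogen lone pair, axial one-bond C-H couplings are
#' systematically smaller than equatorial ones (Perlin effect). If the amine
#' inverted rapidly the two would average out, so a large equatorial-axial
#' difference diagnoses a configurationally locked amine, while a near-zero
#' difference is non-diagnostic ("averaged").
#'
#' @param jAx axial \eqn{^1J_{CH}}, Hz (> 0).
#' @param jEq equatorial \eqn{^1J_{CH}}, Hz (> 0).
#' @param threshold decision threshold on \eqn{J_{eq} - J_{ax}}, Hz. The
#'   default 5 Hz separates the decisive (~8 Hz) from the non-diagnostic
#'   (~0-1.5 Hz) regime.
#' @return list with \code{classification} ("locked" or "averaged") and
#'   \code{delta} = \eqn{J_{eq} - J_{ax}} in Hz.
#' @examples
#' amineInversionCheck(128.7, 136.4)  # locked, delta 7.7 Hz
#' @export
amineInversionCheck <- function(jAx, jEq, threshold = 5.0) {
  if (!is.finite(jAx) || !is.finite(jEq) || jAx <= 0 || jEq <= 0)
    .err("invalid_input", "couplings must be positive and finite")
  delta <- jEq - jAx
  list(classification = if (delta >= threshold) "locked" else "averaged",
       delta = delta)
}

## -- accessors & show ------------------------------------------------------

#' @rdname accessors
setMethod("couplingRecords", "CouplingDataset", function(object) object@records)

#' @rdname accessors
setMethod("datasetName", "CouplingDataset", function(object) object@name)

#' @rdname accessors
setMethod("nUsable", "CouplingDataset",
          function(object) sum(object@records$use_in_fit))

setMethod("show", "CouplingDataset", function(object) {
  rec <- object@records
  cat(sprintf("CouplingDataset \"%s\": %d couplings (%d usable in fits)\n",
              object@name, nrow(rec), sum(rec$use_in_fit)))
  if (nrow(rec) > 0L)
    cat(sprintf("  d_exp range [%.1f, %.1f] Hz; d_err range [%.1f, %.1f] Hz\n",
                min(rec$d_exp_hz), max(rec$d_exp_hz),
                min(rec$d_err_hz), max(rec$d_err_hz)))
})
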