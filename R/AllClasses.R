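#' @import methods
NULL

.REQUIRED_COUPLING_COLS <- c("vector_id", "atom_c", "atom_h", "j_iso_hz",
                             "t_aniso_hz", "d_exp_hz", "d_err_hz", "group",
                             "use_in_fit")
.COUPLING_GROUPS <- c("CH", "CH2_ax", "CH2_eq", "CH3")

#' CouplingDataset: a table of one-bond C-H couplings
#'
#' Holds measured one-bond couplings for a set of C-H vectors: the isotropic
#' scalar coupling \eqn{^1J_{CH}}, the total splitting under partial alignment
#' \eqn{^1T_{CH}}, the residual dipolar coupling
#' \eqn{^1D_{CH} = {}^1T_{CH} - {}^1J_{CH}} (Hz), and a per-coupling maximum
#' error estimate (a conservative bound of roughly three standard deviations).
#' Extra columns (e.g. back-calculated RDC columns) are carried along
#' untouched.
#'
#' @slot records data.frame with at least the columns
#'   \code{vector_id, atom_c, atom_h, j_iso_hz, t_aniso_hz, d_exp_hz,
#'   d_err_hz, group, use_in_fit}.
#' @slot name character scalar naming the dataset.
#' @seealso [couplingDataset()], [readCouplingTable()], [filterMethyls()]
#' @exportClass CouplingDataset
setClass("CouplingDataset",
         slots = c(records = "data.frame", name = "character"))

setValidity("CouplingDataset", function(object) {
  rec <- object@records
  missing <- setdiff(.REQUIRED_COUPLING_COLS, names(rec))
  if (length(missing) > 0L)
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (anyDuplicated(rec$vector_id))
    return("vector_id values must be unique within a dataset")
  if (any(is.na(rec$d_exp_hz)))
    return("d_exp_hz must not contain NA")
  if (any(!is.na(rec$d_err_hz) & rec$d_err_hz <= 0) || any(is.na(rec$d_err_hz)))
    return("d_err_hz must be > 0 for every record")
  if (!all(rec$group %in% .COUPLING_GROUPS))
    return(sprintf("group must be one of %s",
                   paste(.COUPLING_GROUPS, collapse = ", ")))
  both <- !is.na(rec$j_iso_hz) & !is.na(rec$t_aniso_hz)
  if (any(both)) {
    dd <- rec$t_aniso_hz[both] - rec$j_iso_hz[both] - rec$d_exp_hz[both]
    if (any(abs(dd) > 1e-8))
      return("d_exp_hz must equal t_aniso_hz - j_iso_hz where both are present")
  }
  if (!is.logical(rec$use_in_fit) || any(is.na(rec$use_in_fit)))
    return("use_in_fit must be TRUE/FALSE with no NA")
  TRUE
})

#' Conformer: labelled atoms with Cartesian coordinates
#'
#' A single rigid 3D structure. Coordinates are in Angstrom. An optional
#' relative energy (kcal/mol) supports Boltzmann weighting and energy-window
#' filtering of conformer sets.
#'
#' @slot labels character, unique atom labels (e.g. "C9", "H9B").
#' @slot elements character element symbols, parallel to \code{labels}.
#' @slot coords numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @slot name character scalar.
#' @slot energy numeric scalar, kcal/mol (NA when unknown).
#' @seealso [conformer()], [extractVectors()], [dihedralAngle()]
#' @exportClass Conformer
setClass("Conformer",
         slots = c(labels = "character", elements = "character",
                   coords = "matrix", name = "character", energy = "numeric"))

setValidity("Conformer", function(object) {
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) return("atom labels must be unique")
  if (length(object@elements) != n) return("elements/labels length mismatch")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n)
    return("coords must be a numeric n x 3 matrix matching labels")
  if (n > 0L && !all(is.finite(object@coords)))
    return("coordinates must all be finite")
  if (length(object@energy) != 1L) return("energy must be a scalar (NA allowed)")
  TRUE
})

#' Trajectory: an ordered series of conformer frames
#'
#' @slot frames list of [Conformer-class] objects sharing identical atom
#'   labels in identical order.
#' @slot frameInterval numeric scalar, time between frames in ps (NA when
#'   unknown).
#' @seealso [trajectory()], [averageRdc()], [dihedralPopulation()]
#' @exportClass Trajectory
setClass("Trajectory",
         slots = c(frames = "list", frameInterval = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) == 0L) return("trajectory must have >= 1 frame")
  if (!all(vapply(object@frames, is, logical(1), "Conformer")))
    return("all frames must be Conformer objects")
  ref <- object@frames[[1L]]@labels
  same <- vapply(object@frames, function(f) identical(f@labels, ref),
                 logical(1))
  if (!all(same)) return("all frames must share identical atom labels/order")
  TRUE
})

#' SaupeTensor: the alignment (Saupe order) tensor
#'
#' A symmetric traceless 3 x 3 order matrix with five independent elements
#' \eqn{(S_{xx}, S_{yy}, S_{xy}, S_{xz}, S_{yz})}; \eqn{S_{zz} = -S_{xx} -
#' S_{yy}}. It describes the average orientation of a molecule in a partially
#' aligning medium and, together with the C-H unit vectors, determines all
#' RDCs of a rigid structure.
#'
#' @slot components named numeric of length 5:
#'   \code{sxx, syy, sxy, sxz, syz} (dimensionless).
#' @seealso [saupeTensor()], [saupeMatrix()], [forwardRdc()], [svdFit()]
#' @exportClass SaupeTensor
setClass("SaupeTensor", slots = c(components = "numeric"))

setValidity("SaupeTensor", function(object) {
  s <- object@components
  if (length(s) != 5L || !all(is.finite(s)))
    return("components must be 5 finite numbers (sxx, syy, sxy, sxz, syz)")
  ev <- eigen(.saupeMatrixFromComponents(s), symmetric = TRUE,
              only.values = TRUE)$values
  if (any(ev < -0.5 - 1e-9) || any(ev > 1 + 1e-9))
    return("order-matrix eigenvalues must lie in [-1/2, 1]")
  TRUE
})

#' EnsembleModel: conformers with population weights
#'
#' A set of conformers sharing one alignment tensor, with population weights
#' on the probability simplex. Conformers are assumed to be superposed into a
#' common molecular frame (see [superposeConformers()]).
#'
#' @slot conformers list of [Conformer-class] objects.
#' @slot weights numeric populations, each >= 0, summing to 1.
#' @seealso [ensembleModel()], [multiConformerFit()], [optimizePopulations()]
#' @exportClass EnsembleModel
setClass("EnsembleModel",
         slots = c(conformers = "list", weights = "numeric"))

setValidity("EnsembleModel", function(object) {
  if (length(object@conformers) != length(object@weights))
    return("conformers and weights must have equal length")
  if (!all(vapply(object@conformers, is, logical(1), "Conformer")))
    return("all ensemble members must be Conformer objects")
  w <- object@weights
  if (any(!is.finite(w)) || any(w < -1e-12))
    return("weights must be finite and >= 0")
  if (abs(sum(w) - 1) > 1e-9)
    return("weights must sum to 1 (within 1e-9)")
  TRUE
})

#' TensorFit: result of an alignment-tensor least-squares fit
#'
#' @slot tensor [SaupeTensor-class].
#' @slot dCalc named numeric of back-calculated RDCs, Hz.
#' @slot conditionNumber numeric, condition number of the 5-column
#'   direction-cosine design matrix.
#' @seealso [svdFit()], [multiConformerFit()]
#' @exportClass TensorFit
setClass("TensorFit",
         slots = c(tensor = "SaupeTensor", dCalc = "numeric",
                   conditionNumber = "numeric"))

#' PopulationFit: tensor fit with optimized conformer populations
#'
#' @slot weights optimized population weights (simplex).
#' @slot objective final value of the error-normalized sum of squares
#'   \eqn{\sum_i ((D_{calc,i}-D_{exp,i})/\Delta D_i)^2}.
#' @slot converged logical, optimizer convergence flag.
#' @seealso [optimizePopulations()]
#' @exportClass PopulationFit
setClass("PopulationFit", contains = "TensorFit",
         slots = c(weights = "numeric", objective = "numeric",
                   converged = "logical"))

#' QualityReport: agreement statistics for one structural model
#'
#' Per-coupling and aggregate agreement between back-calculated and
#' experimental RDCs: the Cornilescu quality factor Q, the per-coupling
#' error-normalized squared deviations \eqn{\chi_i^2}, the aggregate quality
#' factor \eqn{n/\chi^2}, and the outlier set (couplings whose deviation
#' strictly exceeds the maximum error estimate, \eqn{\chi_i^2 > 1}).
#'
#' @slot n integer, number of evaluated couplings.
#' @slot dExp,dCalc,dErr named numeric vectors, Hz.
#' @slot qFactor numeric Cornilescu Q.
#' @slot chi2 named numeric per-coupling \eqn{\chi_i^2}.
#' @slot nOverChi2 numeric; \code{Inf} for a perfect fit.
#' @slot outliers character vector_ids with \eqn{\chi_i^2 > 1}.
#' @slot outlierCount integer.
#' @seealso [qualityReport()], [cornilescuQ()], [nOverChi2()]
#' @exportClass QualityReport
setClass("QualityReport",
         slots = c(n = "integer", dExp = "numeric", dCalc = "numeric",
                   dErr = "numeric", qFactor = "numeric", chi2 = "numeric",
                   nOverChi2 = "numeric", outliers = "character",
                   outlierCount = "integer"))

setValidity("QualityReport", function(object) {
  if (object@outlierCount != sum(object@chi2 > 1))
    return("outlierCount must equal |{i : chi2_i > 1}|")
  if (is.finite(object@nOverChi2) && object@nOverChi2 < 1 &&
      object@outlierCount < 1L)
    return("nOverChi2 < 1 requires at least one outlier")
  TRUE
})

setClassUnion("QualityReportOrNULL", c("QualityReport", "NULL"))
setClassUnion("SaupeTensorOrNULL", c("SaupeTensor", "NULL"))

#' CandidateResult: one scored candidate configuration
#'
#' A candidate is falsified as soon as a single coupling lies outside its
#' maximum error estimate: because the per-coupling errors are ~3-sigma
#' bounds, one outlier suffices to reject the structural model.
#'
#' @slot configId integer running number (NA when unmatched).
#' @slot descriptor character stereodescriptor string (or candidate name).
#' @slot mode character, one of "single", "multi", "ensemble",
#'   "evaluate-only".
#' @slot quality [QualityReport-class] or NULL for failed candidates.
#' @slot tensor [SaupeTensor-class] or NULL (e.g. externally averaged input).
#' @slot falsified logical; \code{outlierCount >= 1}.
#' @slot failure character error message when evaluation failed, else NA.
#' @seealso [rankCandidates()], [runPipeline()]
#' @exportClass CandidateResult
setClass("CandidateResult",
         slots = c(configId = "integer", descriptor = "character",
                   mode = "character", quality = "QualityReportOrNULL",
                   tensor = "SaupeTensorOrNULL", falsified = "logical",
                   failure = "character"))

#' RdcTimeSeries: per-frame back-calculated RDCs
#'
#' @slot values numeric frames x vectors matrix, Hz; column names are
#'   vector_ids, every frame covers the same vector set.
#' @seealso [rdcTimeSeries()], [averageRdc()]
#' @exportClass RdcTimeSeries
setClass("RdcTimeSeries", slots = c(values = "matrix"))

setValidity("RdcTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v) || is.null(colnames(v)))
    return("values must be a numeric matrix with vector_id column names")
  if (anyDuplicated(colnames(v))) return("duplicate vector_id columns")
  TRUE
})

#' DihedralPopulation: state populations of a torsion angle
#'
#' @slot angles numeric per-frame dihedral angles, degrees in (-180, 180].
#' @slot breaks,counts histogram of the retained angles.
#' @slot states named list of c(lo, hi] angle intervals.
#' @slot fractions numeric state fractions, >= 0, summing to 1.
#' @seealso [dihedralPopulation()]
#' @exportClass DihedralPopulation
setClass("DihedralPopulation",
         slots = c(angles = "numeric", breaks = "numeric", counts = "integer",
                   states = "list", fractions = "numeric"))

setValidity("DihedralPopulation", function(object) {
  f <- object@fractions
  if (any(f < -1e-12)) return("state fractions must be >= 0")
  if (length(f) > 0L && abs(sum(f) - 1) > 1e-9)
    return("state fractions must sum to 1 (within 1e-9)")
  TRUE
})
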