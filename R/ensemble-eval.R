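#' Construct an RdcTimeSeries
#'
#' @param values numeric frames x vectors matrix with vector_id column
#'   names, Hz; or a long data.frame with columns \code{frame, vector_id,
#'   d_hz}.
#' @return an [RdcTimeSeries-class].
#' @export
rdcTimeSeries <- function(values) {
  if (is.data.frame(values)) {
    need <- c("frame", "vector_id", "d_hz")
    if (!all(need %in% names(values)))
      .err("format", "long-format series needs columns %s",
           paste(need, collapse = ", "))
    ids <- unique(values$vector_id)
    fr <- sort(unique(values$frame))
    m <- matrix(NA_real_, length(fr), length(ids),
                dimnames = list(NULL, ids))
    m[cbind(match(values$frame, fr), match(values$vector_id, ids))] <-
      values$d_hz
    if (anyNA(m))
      .err("validation", "every frame must cover the same vector_id set")
    values <- m
  }
  new("RdcTimeSeries", values = values)
}

#' Read/write a per-frame RDC series (long-format CSV)
#'
#' Columns: \code{frame, vector_id, d_hz}.
#' @param path file path.
#' @param series an [RdcTimeSeries-class] (write).
#' @return read: an [RdcTimeSeries-class]; write: invisibly \code{path}.
#' @export
readRdcSeries <- function(path) {
  rdcTimeSeries(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readRdcSeries
#' @export
writeRdcSeries <- function(series, path) {
  v <- series@values
  long <- data.frame(frame = rep(seq_len(nrow(v)), ncol(v)),
                     vector_id = rep(colnames(v), each = nrow(v)),
                     d_hz = as.vector(v))
  long <- long[order(long$frame, match(long$vector_id, colnames(v))), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname accessors
setMethod("seriesValues", "RdcTimeSeries", function(object) object@values)

setMethod("show", "RdcTimeSeries", function(object) {
  cat(sprintf("RdcTimeSeries: %d frames x %d vectors\n",
              nrow(object@values), ncol(object@values)))
})

#' Arithmetically average per-frame RDCs
#'
#' The trajectory-evaluation protocol: per-vector unweighted arithmetic mean
#' of the back-calculated RDCs over retained frames, after discarding an
#' initial equilibration segment. When the series carries a frame interval
#' the skip can be derived with [framesToSkip()].
#'
#' @param series an [RdcTimeSeries-class].
#' @param skip number of initial frames to discard (default 0).
#' @return named numeric vector of mean RDCs, Hz, one per vector_id.
#' @export
averageRdc <- function(series, skip = 0L) {
  v <- series@values
  if (skip >= nrow(v))
    .err("empty_average", "skip (%d) leaves no frames of %d", skip, nrow(v))
  colMeans(v[(skip + 1L):nrow(v), , drop = FALSE])
}

#' Equilibration discard expressed in frames
#'
#' @param equilibration time to discard, ps (default 1000 ps = 1 ns).
#' @param frameInterval time between frames, ps.
#' @return integer frame count, \code{ceiling(equilibration/frameInterval)}.
#' @export
framesToSkip <- function(equilibration = 1000, frameInterval) {
  if (!is.finite(frameInterval) || frameInterval <= 0)
    .err("invalid_input", "frameInterval must be positive; set skip explicitly")
  as.integer(ceiling(equilibration / frameInterval))
}

#' Trajectory-averaged RDCs under a fixed tensor
#'
#' Back-calculates RDCs frame by frame (fixed alignment tensor) and averages
#' arithmetically; equal to [averageRdc()] applied to the per-frame series,
#' which is also returned.
#'
#' @param traj a [Trajectory-class].
#' @param pairs data.frame with \code{atom_c}, \code{atom_h}.
#' @param tensor a [SaupeTensor-class].
#' @param skip initial frames to discard.
#' @param effectiveR optional fixed effective C-H distance, Angstrom.
#' @return list with \code{mean} (named numeric, Hz) and \code{series}
#'   (an [RdcTimeSeries-class]).
#' @export
ensembleRdcFromTrajectory <- function(traj, pairs, tensor, skip = 0L,
                                      effectiveR = NULL) {
  stopifnot(is(traj, "Trajectory"))
  perFrame <- t(vapply(traj@frames, function(f)
    forwardRdc(extractVectors(f, pairs, effectiveR = effectiveR), tensor),
    numeric(nrow(pairs))))
  if (nrow(pairs) == 1L) perFrame <- matrix(perFrame, ncol = 1L)
  colnames(perFrame) <- if ("vector_id" %in% names(pairs)) pairs$vector_id
    else paste0(pairs$atom_c, "-", pairs$atom_h)
  series <- rdcTimeSeries(perFrame)
  list(mean = averageRdc(series, skip = skip), series = series)
}

#' Conformer populations from a dihedral angle
#'
#' Computes the chosen torsion for every retained frame, classifies frames
#' into user-defined angle states, and histograms the distribution. This is
#' how a minor conformation reveals itself in a constrained-dynamics
#' ensemble: a secondary mode in the torsion distribution whose fractional
#' occupancy is its population.
#'
#' @param traj a [Trajectory-class].
#' @param atoms character(4) atom labels of the torsion.
#' @param states named list of \code{c(lo, hi)} intervals in degrees,
#'   interpreted as (lo, hi]; must be disjoint and cover (-180, 180].
#' @param skip initial frames to discard.
#' @param binWidth histogram bin width, degrees (default 5).
#' @return a [DihedralPopulation-class].
#' @export
dihedralPopulation <- function(traj, atoms, states, skip = 0L, binWidth = 5) {
  stopifnot(is(traj, "Trajectory"), length(atoms) == 4L)
  iv <- do.call(rbind, lapply(states, function(s) sort(as.numeric(s))))
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (abs(iv[1, 1] + 180) > 1e-9 || abs(iv[nrow(iv), 2] - 180) > 1e-9 ||
      (nrow(iv) > 1 && any(abs(iv[-1, 1] - iv[-nrow(iv), 2]) > 1e-9)))
    .err("validation",
         "state intervals must be disjoint and cover (-180, 180]")
  if (skip >= length(traj@frames))
    .err("empty_average", "skip leaves no frames")
  ang <- vapply(traj@frames[(skip + 1L):length(traj@frames)], function(f)
    dihedralAngle(f, atoms[1], atoms[2], atoms[3], atoms[4]), numeric(1))
  stateOf <- vapply(ang, function(a)
    which(a > iv[, 1] - 1e-12 & a <= iv[, 2])[1L], integer(1))
  frac <- as.numeric(tabulate(stateOf, nbins = length(states))) / length(ang)
  frac <- frac[order(o)]  # back to user order
  names(frac) <- names(states)
  breaks <- seq(-180, 180, by = binWidth)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE, right = TRUE)
  new("DihedralPopulation", angles = ang, breaks = h$breaks,
      counts = as.integer(h$counts), states = states, fractions = frac)
}

#' @rdname accessors
setMethod("stateFractions", "DihedralPopulation",
          function(object) object@fractions)

setMethod("show", "DihedralPopulation", function(object) {
  cat(sprintf("DihedralPopulation over %d frames\n", length(object@angles)))
  for (i in seq_along(object@fractions))
    cat(sprintf("  %s: %.3f\n",
                if (!is.null(names(object@fractions)))
                  names(object@fractions)[i] else paste0("state", i),
                object@fractions[i]))
})
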