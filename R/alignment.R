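.saupeMatrixFromComponents <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

#' Construct a Saupe alignment tensor
#'
#' @param sxx,syy,sxy,sxz,syz the five independent elements (dimensionless);
#'   \eqn{S_{zz} = -S_{xx} - S_{yy}} by tracelessness.
#' @return a [SaupeTensor-class].
#' @examples
#' saupeTensor(1e-4, -2e-4, 0, 3e-5, 0)
#' @export
saupeTensor <- function(sxx, syy, sxy = 0, sxz = 0, syz = 0) {
  new("SaupeTensor", components = c(sxx = sxx, syy = syy, sxy = sxy,
                                    sxz = sxz, syz = syz))
}

#' @rdname saupeTensor
#' @param m symmetric traceless 3 x 3 matrix.
#' @export
saupeTensorFromMatrix <- function(m) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9)))
    .err("validation", "matrix must be symmetric")
  if (abs(sum(diag(m))) > 1e-9 * max(1, max(abs(m))))
    .err("validation", "matrix must be traceless")
  saupeTensor(m[1, 1], m[2, 2], m[1, 2], m[1, 3], m[2, 3])
}

#' @rdname accessors
setMethod("tensorComponents", "SaupeTensor", function(object) object@components)

#' @rdname accessors
setMethod("saupeMatrix", "SaupeTensor", function(object) {
  m <- .saupeMatrixFromComponents(object@components)
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  m
})

# Eigenvalues ordered |Axx| <= |Ayy| <= |Azz|.
#' @rdname accessors
setMethod("tensorEigenvalues", "SaupeTensor", function(object) {
  ev <- eigen(saupeMatrix(object), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[order(abs(ev))]
  setNames(ev, c("Axx", "Ayy", "Azz"))
})

# Axial component Da = Azz/2; rhombicity R = (2/3)(Axx - Ayy)/Azz
# (PALES-style conventions on the |.|-ordered eigenvalues).
#' @rdname accessors
setMethod("axialComponent", "SaupeTensor",
          function(object) unname(tensorEigenvalues(object)["Azz"]) / 2)

#' @rdname accessors
setMethod("rhombicity", "SaupeTensor", function(object) {
  ev <- tensorEigenvalues(object)
  unname((2 / 3) * (ev["Axx"] - ev["Ayy"]) / ev["Azz"])
})

# Generalized degree of order: sqrt(2/3 sum_ij S_ij^2).
#' @rdname accessors
setMethod("generalizedOrder", "SaupeTensor", function(object)
  sqrt(2 / 3 * sum(saupeMatrix(object)^2)))

setMethod("show", "SaupeTensor", function(object) {
  s <- object@components
  ev <- tensorEigenvalues(object)
  cat("SaupeTensor\n")
  cat(sprintf("  (sxx, syy, sxy, sxz, syz) = (%.3e, %.3e, %.3e, %.3e, %.3e)\n",
              s[1], s[2], s[3], s[4], s[5]))
  cat(sprintf("  eigenvalues |Axx|<=|Ayy|<=|Azz|: %.3e, %.3e, %.3e\n",
              ev[1], ev[2], ev[3]))
  cat(sprintf("  Da = %.3e, rhombicity = %.3f, GDO = %.3e\n",
              axialComponent(object), rhombicity(object),
              generalizedOrder(object)))
})

#' Dipolar interaction constant
#'
#' \eqn{D_{max} = -\mu_0 \hbar \gamma_I \gamma_J / (8\pi^2 r^3)} in Hz for an
#' internuclear distance r in Angstrom. The leading minus is this package's
#' fixed sign convention, so that \eqn{D_i = D_{max} (e^T S e)}; the fitted
#' tensor absorbs any global sign, so the convention does not affect
#' configuration discrimination, but it is fixed for cross-tool
#' comparability. For a C-H bond at 1.09 Angstrom the magnitude is about
#' 23.3 kHz.
#'
#' @param r internuclear distance(s), Angstrom (> 0).
#' @param gammaI,gammaJ gyromagnetic ratios, rad s^-1 T^-1 (default 1H, 13C;
#'   CODATA 2018).
#' @return Hz (vectorized over \code{r}).
#' @examples
#' dmax(1.09)
#' @export
dmax <- function(r, gammaI = .GAMMA_H, gammaJ = .GAMMA_C) {
  if (any(!is.finite(r)) || any(r <= 0))
    .err("invalid_input", "internuclear distance must be positive")
  -.MU0 * .HBAR * gammaI * gammaJ / (8 * pi^2 * (r * 1e-10)^3)
}

# n x 5 direction-cosine design matrix: row i is
# dmax_i * [ex^2 - ez^2, ey^2 - ez^2, 2 ex ey, 2 ex ez, 2 ey ez],
# so that A %*% c(sxx, syy, sxy, sxz, syz) = dmax_i * e^T S e.
.designMatrix <- function(vectors) {
  e <- as.matrix(vectors[, c("x", "y", "z")])
  dm <- dmax(vectors$r)
  dm * cbind(e[, 1]^2 - e[, 3]^2, e[, 2]^2 - e[, 3]^2,
             2 * e[, 1] * e[, 2], 2 * e[, 1] * e[, 3], 2 * e[, 2] * e[, 3])
}

.solveDesign <- function(A, dExp, weights = NULL, ids = NULL) {
  if (nrow(A) < 5L)
    .err("underdetermined",
         "tensor fit needs >= 5 usable couplings, got %d", nrow(A))
  Aw <- A; dw <- dExp
  if (!is.null(weights)) {
    if (length(weights) != nrow(A) || any(weights < 0))
      .err("validation", "weights must be non-negative, one per coupling")
    sw <- sqrt(weights)
    Aw <- A * sw
    dw <- dExp * sw
  }
  sv <- svd(Aw)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < 5L)
    .err("singular_geometry",
         "design matrix rank %d < 5: vector geometry does not determine the tensor",
         rank)
  x <- sv$v %*% ((t(sv$u) %*% dw) / sv$d)
  dCalc <- drop(A %*% x)
  names(dCalc) <- ids
  new("TensorFit",
      tensor = saupeTensor(x[1], x[2], x[3], x[4], x[5]),
      dCalc = dCalc, conditionNumber = sv$d[1] / sv$d[5])
}

#' Back-calculate RDCs from a tensor
#'
#' \eqn{D_i = D_{max}(r_i) \, e_i^T S e_i} for each bond vector, preserving
#' input order. Even under inversion of e (RDCs cannot distinguish a vector
#' from its negative).
#'
#' @param vectors bond-vector table from [extractVectors()].
#' @param tensor a [SaupeTensor-class].
#' @return named numeric vector of RDCs, Hz.
#' @export
forwardRdc <- function(vectors, tensor) {
  stopifnot(is(tensor, "SaupeTensor"))
  if (nrow(vectors) == 0L) .err("invalid_input", "no bond vectors supplied")
  setNames(drop(.designMatrix(vectors) %*% tensor@components),
           vectors$vector_id)
}

#' Fit an alignment tensor by singular value decomposition
#'
#' Determines the five Saupe tensor elements from >= 5 measured RDCs by
#' linear least squares on the direction-cosine design matrix, solved via
#' SVD. Unweighted by default; pass \code{weights = 1/dErr^2} for
#' inverse-variance weighting.
#'
#' @param vectors bond-vector table from [extractVectors()].
#' @param dExp experimental RDCs, Hz, aligned with \code{vectors} by index.
#' @param weights optional per-coupling least-squares weights.
#' @return a [TensorFit-class] (tensor, back-calculated RDCs, design-matrix
#'   condition number).
#' @seealso [multiConformerFit()], [qualityReport()]
#' @export
svdFit <- function(vectors, dExp, weights = NULL) {
  if (nrow(vectors) != length(dExp))
    .err("validation", "vectors and dExp must align by index")
  .solveDesign(.designMatrix(vectors), dExp, weights, ids = vectors$vector_id)
}

#' Single-tensor fit over a conformer ensemble
#'
#' Fits one shared alignment tensor to a population-weighted conformer
#' ensemble: each design-matrix row is the population-weighted average of the
#' per-conformer rows (row averaging precedes any error weighting), then the
#' system is solved as in [svdFit()]. Conformers must already share a common
#' frame (see [superposeConformers()]).
#'
#' @param ensemble an [EnsembleModel-class].
#' @param pairs data.frame with \code{atom_c}, \code{atom_h} (and optionally
#'   \code{vector_id}).
#' @param dExp experimental RDCs, Hz.
#' @param weights optional per-coupling least-squares weights.
#' @param effectiveR optional fixed effective C-H distance, Angstrom.
#' @return a [TensorFit-class].
#' @export
multiConformerFit <- function(ensemble, pairs, dExp, weights = NULL,
                              effectiveR = NULL) {
  stopifnot(is(ensemble, "EnsembleModel"))
  validObject(ensemble)
  rows <- lapply(seq_along(ensemble@conformers), function(k) {
    v <- extractVectors(ensemble@conformers[[k]], pairs,
                        effectiveR = effectiveR)
    ensemble@weights[k] * .designMatrix(v)
  })
  A <- Reduce(`+`, rows)
  ids <- if ("vector_id" %in% names(pairs)) pairs$vector_id else
    paste0(pairs$atom_c, "-", pairs$atom_h)
  if (nrow(A) != length(dExp))
    .err("validation", "pairs and dExp must align by index")
  .solveDesign(A, dExp, weights, ids = ids)
}

#' Construct an EnsembleModel
#'
#' @param confs list of [Conformer-class] objects (already superposed).
#' @param weights populations on the simplex; default uniform.
#' @return an [EnsembleModel-class].
#' @export
ensembleModel <- function(confs, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(confs), length(confs))
  new("EnsembleModel", conformers = confs, weights = weights)
}

#' @rdname accessors
setMethod("conformers", "EnsembleModel", function(object) object@conformers)
#' @rdname accessors
setMethod("populationWeights", "EnsembleModel", function(object) object@weights)

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d conformers, weights (%s)\n",
              length(object@conformers),
              paste(sprintf("%.3f", object@weights), collapse = ", ")))
})

#' @rdname accessors
setMethod("fittedTensor", "TensorFit", function(object) object@tensor)
#' @rdname accessors
setMethod("dCalc", "TensorFit", function(object) object@dCalc)
#' @rdname accessors
setMethod("conditionNumber", "TensorFit", function(object) object@conditionNumber)
#' @rdname accessors
setMethod("populationWeights", "PopulationFit", function(object) object@weights)

setMethod("show", "TensorFit", function(object) {
  cat(sprintf("TensorFit over %d couplings (condition number %.2f)\n",
              length(object@dCalc), object@conditionNumber))
  show(object@tensor)
})

setMethod("show", "PopulationFit", function(object) {
  cat(sprintf("PopulationFit: weights (%s), objective %.4g, %s\n",
              paste(sprintf("%.3f", object@weights), collapse = ", "),
              object@objective,
              if (object@converged) "converged" else "NOT converged"))
  callNextMethod()
})

#' Boltzmann population weights
#'
#' \eqn{w_i \propto \exp(-(E_i - E_{min})/RT)}, normalized to 1.
#'
#' @param energies relative energies, kcal/mol.
#' @param temperature Kelvin (> 0); the default 300 K matches the usual
#'   simulation bath temperature.
#' @return numeric weights summing to 1.
#' @examples
#' boltzmannWeights(c(0, 1, 2), 300)
#' @export
boltzmannWeights <- function(energies, temperature = 300) {
  if (any(!is.finite(energies)))
    .err("invalid_input", "energies must be finite")
  if (length(energies) < 1L || !is.finite(temperature) || temperature <= 0)
    .err("invalid_input", "need >= 1 energy and temperature > 0")
  w <- exp(-(energies - min(energies)) / (.R_KCAL * temperature))
  w / sum(w)
}

#' Keep conformers within an energy window
#'
#' Retains conformers with \eqn{E - E_{min}} strictly below the window
#' (default 6.0 kcal/mol, the usual cutoff for collecting low-energy
#' conformers from a force-field search).
#'
#' @param confs list of [Conformer-class] objects, all carrying energies.
#' @param window kcal/mol.
#' @return filtered list.
#' @export
energyWindowFilter <- function(confs, window = 6.0) {
  en <- vapply(confs, function(cf) cf@energy, numeric(1))
  if (any(is.na(en)))
    .err("validation", "all conformers must carry an energy")
  confs[en - min(en) < window]
}

#' Optimize conformer populations within a single-tensor fit
#'
#' Finds populations on the simplex minimizing the error-normalized sum of
#' squares \eqn{\sum_i ((D_{calc,i} - D_{exp,i})/\Delta D_i)^2}, where for
#' every candidate weight vector the shared tensor is refit by
#' [multiConformerFit()] (nested optimization, inverse-variance weighted).
#' The simplex is parameterized by softmax; optimization is Nelder-Mead from
#' the uniform-weight starting point, so the result is deterministic. On a
#' flat objective (e.g. duplicated conformers) the uniform initialization is
#' returned.
#'
#' @param confs list of >= 2 superposed [Conformer-class] objects.
#' @param pairs data.frame with \code{atom_c}, \code{atom_h}.
#' @param dExp experimental RDCs, Hz (>= 5 usable).
#' @param dErr per-coupling maximum error estimates, Hz (> 0).
#' @param maxit iteration cap (default 1e5).
#' @param reltol relative convergence tolerance on the objective.
#' @param effectiveR optional fixed effective C-H distance, Angstrom.
#' @return a [PopulationFit-class]. Non-convergence within the iteration cap
#'   is reported via the \code{converged} flag (best-so-far is returned) and
#'   a warning.
#' @export
optimizePopulations <- function(confs, pairs, dExp, dErr, maxit = 1e5,
                                reltol = 1e-10, effectiveR = NULL) {
  if (length(confs) < 2L)
    .err("invalid_input", "population optimization needs >= 2 conformers")
  if (any(dErr <= 0)) .err("validation", "dErr must be > 0")
  k <- length(confs)
  lsw <- 1 / dErr^2
  # per-conformer design rows are weight-independent; precompute once
  designs <- lapply(confs, function(cf)
    .designMatrix(extractVectors(cf, pairs, effectiveR = effectiveR)))
  ids <- if ("vector_id" %in% names(pairs)) pairs$vector_id else
    paste0(pairs$atom_c, "-", pairs$atom_h)
  refit <- function(w) {
    A <- Reduce(`+`, Map(`*`, as.list(w), designs))
    .solveDesign(A, dExp, lsw, ids = ids)
  }
  objective <- function(z) {
    w <- exp(z - max(z)); w <- w / sum(w)
    fit <- refit(w)
    sum(((fit@dCalc - dExp) / dErr)^2)
  }
  opt <- stats::optim(rep(0, k), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0L)
    warning("population optimizer did not converge; returning best-so-far")
  w <- exp(opt$par - max(opt$par)); w <- w / sum(w)
  fit <- refit(w)
  new("PopulationFit", tensor = fit@tensor, dCalc = fit@dCalc,
      conditionNumber = fit@conditionNumber, weights = w,
      objective = opt$value, converged = opt$convergence == 0L)
}

#' Export a tensor report
#'
#' Writes the five tensor components, eigenvalues, axial component,
#' rhombicity, generalized degree of order and (when available) the fit
#' condition number as JSON.
#'
#' @param x a [SaupeTensor-class] or [TensorFit-class].
#' @param path output JSON path.
#' @return invisibly, the report list.
#' @export
writeTensorReport <- function(x, path) {
  tensor <- if (is(x, "TensorFit")) x@tensor else x
  rep <- list(components = as.list(tensor@components),
              eigenvalues = as.list(tensorEigenvalues(tensor)),
              Da = axialComponent(tensor),
              rhombicity = rhombicity(tensor),
              gdo = generalizedOrder(tensor))
  if (is(x, "TensorFit")) rep$condition_number <- x@conditionNumber
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}
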