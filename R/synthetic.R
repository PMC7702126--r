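#' Rigid fused-ring test scaffold
#'
#' Builds a deterministic trans-fused bicyclic (decalin-like) scaffold of two
#' chair six-rings with idealized geometry: C-C ~1.53 Angstrom, C-H 1.09
#' Angstrom, tetrahedral H placement (axial/equatorial on the 8 CH2 carbons,
#' one H on each of the 2 bridgeheads). Its 18 C-H vectors sit in general
#' position and span all five degrees of freedom of the alignment tensor,
#' which makes the scaffold a stand-in for the rigid polycyclic cores whose
#' RDCs the package analyses.
#'
#' @param templateId template name; only "decalin" is defined.
#' @return a [Conformer-class].
#' @examples
#' tmpl <- makeTemplate()
#' nrow(chPairs(tmpl))  # 18
#' @export
makeTemplate <- function(templateId = "decalin") {
  if (!identical(templateId, "decalin"))
    .err("invalid_input", "unknown template id \"%s\"", templateId)
  ringA <- rbind(c(1.25, 0.72, 0.25), c(1.25, -0.72, -0.25),
                 c(0, -1.44, 0.25), c(-1.25, -0.72, -0.25),
                 c(-1.25, 0.72, 0.25), c(0, 1.44, -0.25))
  # trans-fusion: second ring by inversion through the C1-C2 bond midpoint
  m <- c(1.25, 0, 0)
  ringB <- t(2 * m - t(ringA[3:6, ]))
  cpos <- rbind(ringA, ringB)
  rownames(cpos) <- paste0("C", 1:10)
  labels <- paste0("C", 1:10)
  coords <- cpos
  elements <- rep("C", 10)
  halfTet <- (109.4712206 / 2) * pi / 180
  for (i in 1:10) {
    d2 <- rowSums((cpos - matrix(cpos[i, ], 10, 3, byrow = TRUE))^2)
    nb <- which(d2 > 1e-9 & d2 < 1.7^2)
    bonds <- lapply(nb, function(j) .normalize(cpos[j, ] - cpos[i, ]))
    if (length(nb) == 2L) {
      u <- -.normalize(bonds[[1]] + bonds[[2]])
      v <- .normalize(c(bonds[[1]][2] * bonds[[2]][3] -
                          bonds[[1]][3] * bonds[[2]][2],
                        bonds[[1]][3] * bonds[[2]][1] -
                          bonds[[1]][1] * bonds[[2]][3],
                        bonds[[1]][1] * bonds[[2]][2] -
                          bonds[[1]][2] * bonds[[2]][1]))
      for (s in c(A = 1, B = -1)) {
        h <- cpos[i, ] + 1.09 * (cos(halfTet) * u +
                                   s * sin(halfTet) * v)
        labels <- c(labels, sprintf("H%d%s", i, names(which(c(A = 1, B = -1) == s))))
        coords <- rbind(coords, h)
        elements <- c(elements, "H")
      }
    } else {
      h <- cpos[i, ] - 1.09 * .normalize(Reduce(`+`, bonds))
      labels <- c(labels, sprintf("H%d", i))
      coords <- rbind(coords, h)
      elements <- c(elements, "H")
    }
  }
  conformer(labels, elements = elements, coords = coords,
            name = "template:decalin", energy = 0)
}

#' Random alignment tensor of realistic magnitude
#'
#' Draws a symmetric traceless tensor (5 independent normal deviates) and
#' scales it so the largest back-calculated |RDC| on the default template
#' falls in \code{targetMaxD} (default 26-32 Hz, the span typical of
#' one-bond C-H RDCs in weakly aligning polymer gels). Reproducible per
#' seed.
#'
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param targetMaxD numeric range, Hz, for the maximum |RDC| on
#'   \code{template}.
#' @param template a [Conformer-class] used for the scaling (default
#'   [makeTemplate()]).
#' @return a [SaupeTensor-class].
#' @export
randomTensor <- function(seed = NULL, targetMaxD = c(26, 32),
                         template = makeTemplate()) {
  .withSeed(seed, {
    # draw at the 1e-4 scale typical of weak alignment, then rescale
    comps <- stats::rnorm(5, sd = 1e-4)
    raw <- saupeTensor(comps[1], comps[2], comps[3], comps[4], comps[5])
    v <- extractVectors(template, chPairs(template))
    m <- max(abs(forwardRdc(v, raw)))
    target <- stats::runif(1, targetMaxD[1], targetMaxD[2])
    s <- comps * target / m
    saupeTensor(s[1], s[2], s[3], s[4], s[5])
  })
}

.localNormal <- function(conf, cLabel) {
  pc <- .atomXYZ(conf, cLabel, "perturbation")
  isC <- conf@elements != "H"
  d2 <- rowSums((conf@coords - matrix(pc, nrow(conf@coords), 3,
                                      byrow = TRUE))^2)
  nb <- which(isC & d2 > 1e-9 & d2 < 1.7^2)
  if (length(nb) >= 2L) {
    b1 <- .normalize(conf@coords[nb[1], ] - pc)
    b2 <- .normalize(conf@coords[nb[2], ] - pc)
    .normalize(c(b1[2] * b2[3] - b1[3] * b2[2],
                 b1[3] * b2[1] - b1[1] * b2[3],
                 b1[1] * b2[2] - b1[2] * b2[1]))
  } else c(0, 0, 1)
}

.rotationMatrix <- function(axis, angleDeg) {
  a <- .normalize(axis)
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Reorient selected C-H vectors of a candidate structure
#'
#' Emulates wrong diastereomer candidates: epimerization at a center
#' reorients the C-H vectors around it while leaving the rest of the
#' scaffold untouched. Each spec entry names one C-H pair and an operation:
#' \code{"reflect"} mirrors the H through the local plane of the carbon's
#' heavy-atom bonds (axial <-> equatorial), \code{"tilt"} reorients the C-H
#' vector by exactly \code{angle} degrees (rotation about an axis
#' perpendicular to the bond, or about an explicit \code{axis} given as two
#' atom labels). All unnamed atoms are bit-identical to the input.
#'
#' @param conf a [Conformer-class].
#' @param spec list of entries \code{list(atom_c=, atom_h=, op="reflect")}
#'   or \code{list(atom_c=, atom_h=, op="tilt", angle=, axis=)}; an empty
#'   list is the identity.
#' @return a perturbed [Conformer-class].
#' @export
perturbCandidate <- function(conf, spec) {
  coords <- conf@coords
  for (e in spec) {
    ic <- match(e$atom_c, conf@labels)
    ih <- match(e$atom_h, conf@labels)
    if (is.na(ic) || is.na(ih))
      .err("lookup", "unknown pair %s-%s", e$atom_c, e$atom_h)
    v <- coords[ih, ] - coords[ic, ]
    if (identical(e$op, "reflect")) {
      n <- .localNormal(conf, e$atom_c)
      v <- v - 2 * sum(v * n) * n
    } else if (identical(e$op, "tilt")) {
      axis <- if (!is.null(e$axis)) {
        .atomXYZ(conf, e$axis[2], "tilt axis") -
          .atomXYZ(conf, e$axis[1], "tilt axis")
      } else {
        # default axis is perpendicular to the C-H bond (in the local
        # plane), so the stated angle is exactly the reorientation of the
        # C-H vector
        n <- .localNormal(conf, e$atom_c)
        ax <- c(v[2] * n[3] - v[3] * n[2], v[3] * n[1] - v[1] * n[3],
                v[1] * n[2] - v[2] * n[1])
        if (sqrt(sum(ax^2)) < 1e-9) ax <- n
        ax
      }
      v <- drop(.rotationMatrix(axis, e$angle) %*% v)
    } else .err("invalid_input", "unknown perturbation op \"%s\"", e$op)
    coords[ih, ] <- coords[ic, ] + v
  }
  initialize(conf, coords = coords,
             name = paste0(conf@name, if (length(spec)) "*" else ""))
}

#' Generate a synthetic coupling dataset
#'
#' Forward-calculates RDCs for a structure (or a population-weighted
#' ensemble under one shared tensor) and adds measurement noise consistent
#' with per-coupling maximum error estimates: the errors are ~3-sigma
#' bounds, so gaussian noise uses sigma = d_err/3; uniform noise has support
#' +-d_err. The default error profile cycles through {0.3, 0.5, 1.0, 1.5,
#' 5.0} Hz, mimicking the spread of experimental maximum error estimates.
#'
#' @param x a [Conformer-class] or [EnsembleModel-class].
#' @param tensor a [SaupeTensor-class].
#' @param noise "none", "gaussian" (sigma = dErr/3) or "uniform"
#'   (+-dErr).
#' @param dErr per-coupling maximum error estimates, Hz; recycled; default
#'   the cycling profile above.
#' @param seed integer seed for the noise draw.
#' @param pairs C-H pairs (default [chPairs()] of the (first) conformer).
#' @param name dataset name.
#' @return a [CouplingDataset-class] (all records usable, group "CH").
#' @export
generateObservations <- function(x, tensor,
                                 noise = c("none", "gaussian", "uniform"),
                                 dErr = NULL, seed = NULL, pairs = NULL,
                                 name = "synthetic") {
  noise <- match.arg(noise)
  first <- if (is(x, "EnsembleModel")) x@conformers[[1L]] else x
  if (is.null(pairs)) pairs <- chPairs(first)
  dTrue <- if (is(x, "EnsembleModel")) {
    Reduce(`+`, lapply(seq_along(x@conformers), function(k)
      x@weights[k] *
        forwardRdc(extractVectors(x@conformers[[k]], pairs), tensor)))
  } else forwardRdc(extractVectors(x, pairs), tensor)
  n <- length(dTrue)
  if (is.null(dErr)) dErr <- c(0.3, 0.5, 1.0, 1.5, 5.0)
  dErr <- rep_len(dErr, n)
  eps <- .withSeed(seed, switch(noise,
    none = rep(0, n),
    gaussian = stats::rnorm(n, 0, dErr / 3),
    uniform = stats::runif(n, -dErr, dErr)))
  couplingDataset(data.frame(
    vector_id = pairs$vector_id, atom_c = pairs$atom_c,
    atom_h = pairs$atom_h, j_iso_hz = NA_real_, t_aniso_hz = NA_real_,
    d_exp_hz = unname(dTrue) + eps, d_err_hz = dErr, group = "CH",
    use_in_fit = TRUE, stringsAsFactors = FALSE), name = name)
}

#' Two-state (or k-state) Markov jump trajectory
#'
#' Emulates conformational exchange: frames jump between template
#' conformers following a Markov chain whose stationary distribution is the
#' requested population vector (at each step the state is redrawn from the
#' stationary distribution with probability \code{switchProb}, else kept).
#' Optional small random rigid-body rotation jitter per frame. Reproducible
#' per seed.
#'
#' @param states list of [Conformer-class] objects (identical atom sets).
#' @param stationary population weights, >= 0, summing to 1.
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed.
#' @param switchProb per-step probability of redrawing the state
#'   (default 0.2).
#' @param jitterSd sd of the per-frame rotation jitter angle, degrees
#'   (default 0 = none).
#' @param frameInterval time between frames, ps (carried on the result).
#' @return a [Trajectory-class].
#' @export
generateJumpTrajectory <- function(states, stationary, nFrames, seed = NULL,
                                   switchProb = 0.2, jitterSd = 0,
                                   frameInterval = NA_real_) {
  if (length(states) != length(stationary) || any(stationary < 0) ||
      abs(sum(stationary) - 1) > 1e-9)
    .err("validation", "stationary must be a probability vector over states")
  if (nFrames < 1L) .err("invalid_input", "nFrames must be >= 1")
  .withSeed(seed, {
    k <- length(states)
    st <- integer(nFrames)
    st[1L] <- sample.int(k, 1L, prob = stationary)
    if (nFrames > 1L) for (t in 2:nFrames) {
      st[t] <- if (stats::runif(1) < switchProb)
        sample.int(k, 1L, prob = stationary) else st[t - 1L]
    }
    frames <- lapply(seq_len(nFrames), function(t) {
      cf <- states[[st[t]]]
      if (jitterSd > 0) {
        ax <- stats::rnorm(3)
        ang <- stats::rnorm(1, 0, jitterSd)
        ctr <- colMeans(cf@coords)
        rot <- .rotationMatrix(ax, ang)
        newc <- sweep(sweep(cf@coords, 2, ctr) %*% t(rot), 2, ctr, "+")
        cf <- initialize(cf, coords = `dimnames<-`(newc,
                                                   dimnames(cf@coords)))
      }
      cf
    })
    trajectory(frames, frameInterval = frameInterval)
  })
}

#' Build a complete configuration-discrimination scenario
#'
#' Convenience generator tying the pieces together: a random tensor on the
#' default template, a synthetic coupling dataset observed from the true
#' structure, and decoy candidates whose C-H vectors are tilted away from
#' the truth (30 degrees on 3 vectors each by default, emulating
#' epimer-scale geometry changes).
#'
#' @param seed integer seed driving tensor and noise.
#' @param noise noise mode for [generateObservations()].
#' @param nDecoys number of perturbed candidates (default 3).
#' @param tiltAngle degrees each decoy vector is tilted (default 30).
#' @param nTilt number of vectors tilted per decoy (default 3).
#' @return list with \code{dataset} ([CouplingDataset-class]),
#'   \code{candidates} (named list of [Conformer-class], first one the
#'   truth), \code{trueName}, \code{tensor}.
#' @examples
#' scn <- simulateScenario(seed = 1, noise = "none")
#' res <- runPipeline(scn$candidates, scn$dataset, mode = "single")
#' res$table$descriptor[1]  # "true"
#' @export
simulateScenario <- function(seed = 1L, noise = "gaussian", nDecoys = 3L,
                             tiltAngle = 30, nTilt = 3L) {
  tmpl <- makeTemplate()
  tensor <- randomTensor(seed = seed, template = tmpl)
  ds <- generateObservations(tmpl, tensor, noise = noise,
                             seed = seed + 500000L,
                             name = sprintf("scenario seed %d", seed))
  pairs <- chPairs(tmpl)
  cands <- list(true = tmpl)
  for (k in seq_len(nDecoys)) {
    rows <- ((k - 1L) * nTilt + seq_len(nTilt) - 1L) %% nrow(pairs) + 1L
    spec <- lapply(rows, function(i)
      list(atom_c = pairs$atom_c[i], atom_h = pairs$atom_h[i],
           op = "tilt", angle = tiltAngle))
    cands[[paste0("decoy", k)]] <- perturbCandidate(tmpl, spec)
  }
  list(dataset = ds, candidates = cands, trueName = "true", tensor = tensor)
}

#' Write a scenario to disk
#'
#' Writes the coupling CSV, one XYZ per candidate, and a
#' \code{scenario.json} manifest.
#'
#' @param scn result of [simulateScenario()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
writeScenario <- function(scn, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCouplingTable(scn$dataset, file.path(dir, "couplings.csv"))
  for (nm in names(scn$candidates))
    writeXYZ(scn$candidates[[nm]], file.path(dir, paste0(nm, ".xyz")))
  manifest <- list(true_candidate = scn$trueName,
                   candidates = names(scn$candidates),
                   tensor = as.list(tensorComponents(scn$tensor)),
                   couplings = "couplings.csv")
  jsonlite::write_json(manifest, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
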