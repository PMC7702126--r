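#' Construct a Conformer
#'
#' @param labels unique atom labels.
#' @param elements element symbols (defaults to the leading letters of each
#'   label).
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param name conformer name.
#' @param energy relative energy, kcal/mol (NA when unknown).
#' @return a [Conformer-class].
#' @examples
#' conformer(c("C1", "H1"), coords = rbind(c(0, 0, 0), c(0, 0, 1.09)))
#' @export
conformer <- function(labels, elements = gsub("[0-9].*$", "", labels),
                      coords, name = "conformer", energy = NA_real_) {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  new("Conformer", labels = as.character(labels),
      elements = as.character(elements), coords = coords,
      name = name, energy = as.numeric(energy))
}

#' Construct a Trajectory
#'
#' @param frames list of [Conformer-class] objects with identical atom
#'   labels/order.
#' @param frameInterval time between frames in ps (NA when unknown).
#' @return a [Trajectory-class].
#' @export
trajectory <- function(frames, frameInterval = NA_real_) {
  new("Trajectory", frames = frames, frameInterval = as.numeric(frameInterval))
}

#' @rdname accessors
setMethod("atomLabels", "Conformer", function(object) object@labels)
#' @rdname accessors
setMethod("atomCoords", "Conformer", function(object) object@coords)
#' @rdname accessors
setMethod("conformerEnergy", "Conformer", function(object) object@energy)
#' @rdname accessors
setMethod("frames", "Trajectory", function(object) object@frames)
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(object) length(object@frames))

setMethod("show", "Conformer", function(object) {
  cat(sprintf("Conformer \"%s\": %d atoms (%s)%s\n", object@name,
              length(object@labels),
              paste(names(sort(table(object@elements), decreasing = TRUE)),
                    collapse = ","),
              if (is.na(object@energy)) "" else
                sprintf(", E = %.2f kcal/mol", object@energy)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms%s\n", length(object@frames),
              length(object@frames[[1L]]@labels),
              if (is.na(object@frameInterval)) "" else
                sprintf(", %.1f ps/frame", object@frameInterval)))
})

.atomXYZ <- function(conf, label, context = "atom lookup") {
  i <- match(label, conf@labels)
  if (is.na(i)) .err("lookup", "%s: atom \"%s\" not found in conformer \"%s\"",
                     context, label, conf@name)
  conf@coords[i, ]
}

#' Extract internuclear C-H unit vectors
#'
#' Returns the unit vector from carbon to proton and the internuclear
#' distance for each requested pair, in input order, as a bond-vector table.
#' These direction cosines (in the molecular frame) are what enter the
#' dipolar interaction.
#'
#' @param conf a [Conformer-class].
#' @param pairs data.frame with columns \code{atom_c}, \code{atom_h} and
#'   optionally \code{vector_id} (default \code{"C-H"} paste).
#' @param effectiveR optional fixed effective C-H distance in Angstrom used
#'   in place of the coordinate distance (vibrationally averaged effective
#'   bond lengths differ from equilibrium geometry); the unit vector still
#'   comes from the coordinates.
#' @return data.frame with columns \code{vector_id, x, y, z, r} (unit-vector
#'   components and distance in Angstrom).
#' @examples
#' cf <- conformer(c("C1", "H1"), coords = rbind(c(0, 0, 0), c(0, 0, 1.09)))
#' extractVectors(cf, data.frame(atom_c = "C1", atom_h = "H1"))
#' @export
extractVectors <- function(conf, pairs, effectiveR = NULL) {
  stopifnot(is(conf, "Conformer"))
  ids <- if ("vector_id" %in% names(pairs)) pairs$vector_id else
    paste0(pairs$atom_c, "-", pairs$atom_h)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    pc <- .atomXYZ(conf, pairs$atom_c[i],
                   context = sprintf("pair %s", ids[i]))
    ph <- .atomXYZ(conf, pairs$atom_h[i],
                   context = sprintf("pair %s", ids[i]))
    v <- ph - pc
    r <- sqrt(sum(v^2))
    if (r < 0.5 || r > 2.0)
      .err("validation", "pair %s: C-H distance %.3f A outside (0.5, 2.0)",
           ids[i], r)
    c(v / r, r)
  })
  m <- do.call(rbind, out)
  data.frame(vector_id = ids, x = m[, 1], y = m[, 2], z = m[, 3],
             r = if (is.null(effectiveR)) m[, 4] else rep(effectiveR, nrow(m)),
             stringsAsFactors = FALSE)
}

#' Signed dihedral angle
#'
#' Torsion a1-a2-a3-a4 with the IUPAC sign convention (positive clockwise
#' when viewed from a2 towards a3), in degrees in (-180, 180].
#'
#' @param conf a [Conformer-class].
#' @param a1,a2,a3,a4 atom labels.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(conf, a1, a2, a3, a4) {
  p <- lapply(c(a1, a2, a3, a4), function(a) .atomXYZ(conf, a, "dihedral"))
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    .err("undefined_torsion", "collinear atoms: torsion %s-%s-%s-%s undefined",
         a1, a2, a3, a4)
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  y <- sum(m1 * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Effective dipolar vector of a fast-rotating methyl group
#'
#' A methyl rotating fast about its local three-fold axis averages the
#' dipolar interaction of its three C-H bonds onto the rotation axis, scaled
#' by \eqn{P_2(\cos\beta) = (3\cos^2\beta - 1)/2} where \eqn{\beta} is the
#' angle between a C-H bond and the axis (-1/3 for ideal tetrahedral
#' geometry). The effective RDC is \code{scale} times the RDC of a virtual
#' coupling along the axis.
#'
#' @param conf a [Conformer-class] containing the methyl protons.
#' @param cMethyl label of the methyl carbon.
#' @param axisNeighbor label of the heavy atom the methyl is bonded to.
#' @param hLabels optional labels of the methyl protons; by default all H
#'   atoms within 1.3 Angstrom of \code{cMethyl}.
#' @return list with \code{vector} (one-row bond-vector table along the
#'   axis, r = mean C-H distance) and \code{scale} (mean
#'   \eqn{P_2(\cos\beta)} over the protons).
#' @export
methylEffectiveVector <- function(conf, cMethyl, axisNeighbor,
                                  hLabels = NULL) {
  pc <- .atomXYZ(conf, cMethyl, "methyl axis")
  pn <- .atomXYZ(conf, axisNeighbor, "methyl axis")
  axis <- .normalize(pc - pn)
  if (is.null(hLabels)) {
    d2 <- rowSums((conf@coords -
                     matrix(pc, nrow(conf@coords), 3, byrow = TRUE))^2)
    hLabels <- conf@labels[conf@elements == "H" & d2 > 1e-12 & d2 < 1.3^2]
  }
  if (length(hLabels) == 0L)
    .err("lookup", "no methyl protons found on %s", cMethyl)
  cosb <- vapply(hLabels, function(h) {
    sum(.normalize(.atomXYZ(conf, h, "methyl proton") - pc) * axis)
  }, numeric(1))
  rs <- vapply(hLabels, function(h)
    sqrt(sum((.atomXYZ(conf, h, "methyl proton") - pc)^2)), numeric(1))
  list(vector = data.frame(vector_id = paste0(cMethyl, "-axis"),
                           x = axis[1], y = axis[2], z = axis[3],
                           r = mean(rs), stringsAsFactors = FALSE),
       scale = mean((3 * cosb^2 - 1) / 2))
}

#' Identify one-bond C-H pairs from geometry
#'
#' Finds all C-H pairs within a bonding distance cutoff; convenient for
#' synthetic scaffolds where the pair list is implied by the structure.
#'
#' @param conf a [Conformer-class].
#' @param cutoff maximum C-H distance in Angstrom (default 1.2).
#' @return pairs data.frame (\code{vector_id, atom_c, atom_h}).
#' @export
chPairs <- function(conf, cutoff = 1.2) {
  ci <- which(conf@elements == "C")
  hi <- which(conf@elements == "H")
  out <- list()
  for (i in ci) for (j in hi) {
    if (sqrt(sum((conf@coords[i, ] - conf@coords[j, ])^2)) <= cutoff)
      out[[length(out) + 1L]] <-
        data.frame(vector_id = paste0(conf@labels[i], "-", conf@labels[j]),
                   atom_c = conf@labels[i], atom_h = conf@labels[j],
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Superpose conformers onto a common frame
#'
#' Least-squares (Kabsch) rigid-body superposition of each conformer onto a
#' reference, using a named atom subset (default: all heavy atoms). A shared
#' molecular frame is a precondition of the single-tensor multi-conformer
#' fit.
#'
#' @param confs list of [Conformer-class] objects with identical labels.
#' @param reference index of the reference conformer (default 1).
#' @param subset atom labels used for the fit; default all non-H atoms.
#' @return list of superposed [Conformer-class] objects.
#' @export
superposeConformers <- function(confs, reference = 1L, subset = NULL) {
  ref <- confs[[reference]]
  if (is.null(subset)) subset <- ref@labels[ref@elements != "H"]
  idx <- match(subset, ref@labels)
  if (anyNA(idx)) .err("lookup", "subset atom(s) not found")
  q <- ref@coords[idx, , drop = FALSE]
  qc <- colMeans(q)
  lapply(confs, function(cf) {
    p <- cf@coords[match(subset, cf@labels), , drop = FALSE]
    pc <- colMeans(p)
    h <- t(sweep(p, 2, pc)) %*% sweep(q, 2, qc)
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    newc <- sweep(cf@coords, 2, pc) %*% t(rot)
    newc <- sweep(newc, 2, qc, "+")
    initialize(cf, coords = `dimnames<-`(newc, dimnames(cf@coords)))
  })
}
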