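# Shared helpers: random geometry, rotations, small oracles.

randomUnitVectors <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# bond-vector table from raw unit vectors at a fixed C-H distance
bondTable <- function(units, r = 1.09) {
  data.frame(vector_id = paste0("v", seq_len(nrow(units))),
             x = units[, 1], y = units[, 2], z = units[, 3], r = r,
             stringsAsFactors = FALSE)
}

rotateConformer <- function(cf, rot) {
  xyz <- atomCoords(cf) %*% t(rot)
  conformer(atomLabels(cf), elements = cf@elements, coords = xyz,
            name = cf@name, energy = conformerEnergy(cf))
}

# sum of squared residuals of a candidate 5-vector against data
ssrOf <- function(comps, vectors, dExp) {
  s <- saupeTensor(comps[1], comps[2], comps[3], comps[4], comps[5])
  sum((forwardRdc(vectors, s) - dExp)^2)
}

# the three printed back-calculated columns of the embedded coupling table
rd1CalcColumns <- function() {
  rec <- couplingRecords(rd1CouplingTable())
  list(mdoc = setNames(rec$d_calc_mdoc, rec$vector_id),
       svd_sc = setNames(rec$d_calc_svd_sc, rec$vector_id),
       svd_mc = setNames(rec$d_calc_svd_mc, rec$vector_id))
}

# two-state ensemble used by population-recovery checks: the template plus
# a ring-flip-scale reorientation (40 degrees on 8 vectors)
twoStateConformers <- function() {
  tmpl <- makeTemplate()
  pr <- chPairs(tmpl)
  flip <- perturbCandidate(tmpl, lapply(1:8, function(i)
    list(atom_c = pr$atom_c[i], atom_h = pr$atom_h[i],
         op = "tilt", angle = 40)))
  list(major = tmpl, minor = flip, pairs = pr)
}
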