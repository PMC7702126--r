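test_that("the dipolar interaction constant has the right scale and sign", {
  d <- dmax(1.09)
  # closed form with CODATA constants, evaluated independently by hand
  expect_equal(abs(d), 23328.18, tolerance = 1e-5)
  expect_lt(d, 0)
  expect_equal(dmax(2.18) / dmax(1.09), 1 / 8, tolerance = 1e-9)
  expect_error(dmax(0), class = "rdcrank_invalid_input")
  expect_error(dmax(-1), class = "rdcrank_invalid_input")
})

test_that("forward RDCs obey the axial closed form and inversion symmetry", {
  v <- bondTable(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(forwardRdc(v, saupeTensor(0, 0))), c(0, 0, 0))
  s <- 1e-3
  ax <- saupeTensor(-s / 2, -s / 2)  # szz = s
  expect_equal(unname(forwardRdc(v, ax))[1], dmax(1.09) * s,
               tolerance = 1e-12)
  set.seed(14)
  u <- randomUnitVectors(12)
  S <- saupeTensor(2e-4, -1e-4, 5e-5, -3e-5, 8e-5)
  expect_equal(forwardRdc(bondTable(u), S), forwardRdc(bondTable(-u), S))
})

test_that("the Saupe matrix is symmetric, traceless and bounded", {
  set.seed(4)
  for (i in 1:20) {
    S <- randomTensor(seed = i)
    m <- saupeMatrix(S)
    expect_equal(m, t(m))
    expect_lt(abs(sum(diag(m))), 1e-12)
    ev <- tensorEigenvalues(S)
    expect_true(all(ev >= -0.5 & ev <= 1))
    expect_true(all(diff(abs(ev)) >= -1e-15))
  }
  expect_error(saupeTensorFromMatrix(diag(c(1, 1, 1)) * 1e-4),
               class = "rdcrank_validation")
})

test_that("SVD fitting interpolates at n = 5 and recovers known tensors", {
  set.seed(101)
  truth <- saupeTensor(3e-4, -1.2e-4, 6e-5, -9e-5, 2e-5)
  v5 <- bondTable(randomUnitVectors(5))
  d5 <- forwardRdc(v5, truth)
  fit5 <- svdFit(v5, d5)
  expect_lt(max(abs(dCalc(fit5) - d5)), 1e-9)

  v20 <- bondTable(randomUnitVectors(20))
  d20 <- forwardRdc(v20, truth)
  fit20 <- svdFit(v20, d20)
  expect_lt(max(abs(tensorComponents(fittedTensor(fit20)) -
                      tensorComponents(truth))), 1e-9)
  expect_gt(conditionNumber(fit20), 1)
})

test_that("the SVD solution beats a brute-force grid around the optimum", {
  set.seed(7)
  v <- bondTable(randomUnitVectors(9))
  truth <- saupeTensor(2e-4, -1e-4, 4e-5, -6e-5, 9e-5)
  d <- forwardRdc(v, truth) + rnorm(9, 0, 1.0)
  fit <- svdFit(v, d)
  comps <- tensorComponents(fittedTensor(fit))
  ssrFit <- ssrOf(comps, v, d)
  grid <- expand.grid(rep(list(c(-1, 0, 1)), 5))
  step <- 0.2 * pmax(abs(comps), 1e-5)
  for (g in seq_len(nrow(grid))) {
    cand <- comps + unlist(grid[g, ]) * step
    expect_gte(ssrOf(cand, v, d) + 1e-12, ssrFit)
  }
})

test_that("degenerate coupling geometries are rejected with diagnostics", {
  set.seed(2)
  v4 <- bondTable(randomUnitVectors(4))
  expect_error(svdFit(v4, rep(1, 4)), class = "rdcrank_underdetermined")
  vSame <- bondTable(matrix(rep(c(0, 0, 1), 6), 6, 3, byrow = TRUE))
  expect_error(svdFit(vSame, rep(1, 6)), "rank",
               class = "rdcrank_singular_geometry")
})

test_that("fits are frame-covariant", {
  set.seed(19)
  tmpl <- makeTemplate()
  pr <- chPairs(tmpl)
  truth <- randomTensor(seed = 55, template = tmpl)
  d <- forwardRdc(extractVectors(tmpl, pr), truth) + rnorm(nrow(pr), 0, 0.5)
  fit0 <- svdFit(extractVectors(tmpl, pr), d)
  rot <- randomRotation()
  fitR <- svdFit(extractVectors(rotateConformer(tmpl, rot), pr), d)
  expect_equal(saupeMatrix(fittedTensor(fitR)),
               rot %*% saupeMatrix(fittedTensor(fit0)) %*% t(rot),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(dCalc(fitR), dCalc(fit0), tolerance = 1e-9)
  expect_equal(generalizedOrder(fittedTensor(fitR)),
               generalizedOrder(fittedTensor(fit0)), tolerance = 1e-12)
})

test_that("ensemble fits degenerate correctly to single-conformer fits", {
  tmpl <- makeTemplate()
  ts <- twoStateConformers()
  pr <- ts$pairs
  set.seed(31)
  d <- forwardRdc(extractVectors(tmpl, pr),
                  randomTensor(seed = 3)) + rnorm(nrow(pr), 0, 0.4)
  single <- svdFit(extractVectors(tmpl, pr), d)

  same <- multiConformerFit(ensembleModel(list(tmpl, tmpl), c(0.4, 0.6)),
                            pr, d)
  expect_equal(tensorComponents(fittedTensor(same)),
               tensorComponents(fittedTensor(single)), tolerance = 1e-9)

  first <- multiConformerFit(ensembleModel(list(tmpl, ts$minor), c(1, 0)),
                             pr, d)
  expect_equal(dCalc(first), dCalc(single), tolerance = 1e-9)

  # splitting one conformer into identical halves changes nothing
  ens2 <- multiConformerFit(ensembleModel(list(tmpl, ts$minor),
                                          c(0.7, 0.3)), pr, d)
  ens3 <- multiConformerFit(ensembleModel(list(tmpl, tmpl, ts$minor),
                                          c(0.35, 0.35, 0.3)), pr, d)
  expect_equal(tensorComponents(fittedTensor(ens3)),
               tensorComponents(fittedTensor(ens2)), tolerance = 1e-9)
})

test_that("a two-conformer forward model round-trips through the fit", {
  ts <- twoStateConformers()
  S <- randomTensor(seed = 12)
  ens <- ensembleModel(list(ts$major, ts$minor), c(0.7, 0.3))
  ds <- generateObservations(ens, S, noise = "none")
  rec <- couplingRecords(ds)
  fit <- multiConformerFit(ens, ts$pairs, rec$d_exp_hz)
  expect_lt(max(abs(dCalc(fit) - rec$d_exp_hz)), 1e-9)
})

test_that("Boltzmann weights follow the closed form", {
  expect_equal(boltzmannWeights(c(1, 1, 1)), rep(1 / 3, 3))
  rt <- 1.987204259e-3 * 300
  expect_equal(boltzmannWeights(c(0, rt * log(2)), 300), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  en <- c(0, 1, 2)
  w <- exp(-en / rt)
  expect_equal(boltzmannWeights(en, 300), w / sum(w), tolerance = 1e-12)
  expect_error(boltzmannWeights(c(0, NA)), class = "rdcrank_invalid_input")
  expect_error(boltzmannWeights(0, temperature = 0),
               class = "rdcrank_invalid_input")
})

test_that("the energy window keeps conformers strictly below the cutoff", {
  mk <- function(e) conformer("C1", coords = matrix(0, 1, 3), energy = e)
  confs <- lapply(c(0, 3, 7), mk)
  expect_length(energyWindowFilter(confs, 6), 2L)
  expect_length(energyWindowFilter(lapply(c(1, 1, 1), mk), 6), 3L)
  expect_length(energyWindowFilter(confs, 0), 0L)
  expect_length(energyWindowFilter(lapply(c(0, 0, 5), mk), 1e-9), 2L)
  expect_error(energyWindowFilter(list(mk(0), mk(NA))),
               class = "rdcrank_validation")
})

test_that("population optimization recovers generating weights", {
  ts <- twoStateConformers()
  S <- randomTensor(seed = 77)
  ens <- ensembleModel(list(ts$major, ts$minor), c(0.9, 0.1))
  ds <- generateObservations(ens, S, noise = "none")
  rec <- couplingRecords(ds)
  fit <- optimizePopulations(list(ts$major, ts$minor), ts$pairs,
                             rec$d_exp_hz, rec$d_err_hz)
  expect_true(fit@converged)
  expect_equal(populationWeights(fit), c(0.9, 0.1), tolerance = 0.01)

  # the optimum beats a 0.05-step grid on the simplex
  lsw <- 1 / rec$d_err_hz^2
  gridObj <- vapply(seq(0, 1, by = 0.05), function(w1) {
    g <- multiConformerFit(ensembleModel(list(ts$major, ts$minor),
                                         c(w1, 1 - w1)),
                           ts$pairs, rec$d_exp_hz, weights = lsw)
    sum(((dCalc(g) - rec$d_exp_hz) / rec$d_err_hz)^2)
  }, numeric(1))
  expect_lte(fit@objective, min(gridObj) + 1e-9)
})

test_that("a flat population objective returns the uniform start", {
  tmpl <- makeTemplate()
  pr <- chPairs(tmpl)
  set.seed(40)
  d <- forwardRdc(extractVectors(tmpl, pr), randomTensor(seed = 8))
  fit <- optimizePopulations(list(tmpl, tmpl), pr, d, rep(1, length(d)))
  expect_equal(populationWeights(fit), c(0.5, 0.5), tolerance = 1e-3)
  expect_error(optimizePopulations(list(tmpl), pr, d, rep(1, length(d))),
               class = "rdcrank_invalid_input")
})

test_that("tensor reports serialize the derived quantities", {
  S <- randomTensor(seed = 5)
  tmp <- withr::local_tempfile(fileext = ".json")
  rep <- writeTensorReport(S, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$gdo, generalizedOrder(S), tolerance = 1e-12)
  expect_equal(unlist(back$components), tensorComponents(S),
               tolerance = 1e-12, ignore_attr = TRUE)
})
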