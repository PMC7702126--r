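test_that("the template scaffold determines all five tensor components", {
  tmpl <- makeTemplate()
  pr <- chPairs(tmpl)
  expect_gte(nrow(pr), 15L)
  v <- extractVectors(tmpl, pr)
  expect_equal(v$r, rep(1.09, nrow(v)), tolerance = 1e-9)
  expect_equal(rowSums(as.matrix(v[, c("x", "y", "z")])^2),
               rep(1, nrow(v)), tolerance = 1e-10)
  # independent rank oracle on the design matrix
  A <- RDCrank:::.designMatrix(v)
  expect_equal(qr(A)$rank, 5L)
  set.seed(1)
  vr <- extractVectors(rotateConformer(tmpl, randomRotation()), pr)
  expect_equal(qr(RDCrank:::.designMatrix(vr))$rank, 5L)
  expect_error(makeTemplate("helix"), class = "rdcrank_invalid_input")
})

test_that("random tensors are reproducible and realistically scaled", {
  tmpl <- makeTemplate()
  v <- extractVectors(tmpl, chPairs(tmpl))
  for (seed in 1:8) {
    S <- randomTensor(seed = seed)
    expect_equal(saupeMatrix(S), t(saupeMatrix(S)))
    expect_lt(abs(sum(diag(saupeMatrix(S)))), 1e-15)
    m <- max(abs(forwardRdc(v, S)))
    expect_gte(m, 20); expect_lte(m, 40)
  }
  expect_identical(tensorComponents(randomTensor(seed = 3)),
                   tensorComponents(randomTensor(seed = 3)))
})

test_that("candidate perturbation touches only the named vectors", {
  tmpl <- makeTemplate()
  pr <- chPairs(tmpl)
  expect_identical(atomCoords(perturbCandidate(tmpl, list())),
                   atomCoords(tmpl))
  one <- perturbCandidate(tmpl, list(list(atom_c = pr$atom_c[3],
                                          atom_h = pr$atom_h[3],
                                          op = "reflect")))
  changed <- atomCoords(one) != atomCoords(tmpl)
  expect_identical(unname(rowSums(changed) > 0),
                   atomLabels(tmpl) == pr$atom_h[3])
  v0 <- extractVectors(tmpl, pr)
  v1 <- extractVectors(one, pr)
  expect_gt(sum(abs(v1[3, c("x", "y", "z")] - v0[3, c("x", "y", "z")])), 0.1)
  expect_equal(v1[-3, ], v0[-3, ], tolerance = 1e-12)
  expect_equal(v1$r[3], v0$r[3], tolerance = 1e-9)
  expect_error(perturbCandidate(tmpl, list(list(atom_c = "C99",
                                                atom_h = "H1",
                                                op = "reflect"))),
               class = "rdcrank_lookup")
})

test_that("strong perturbations degrade the fit against true data", {
  scn <- simulateScenario(seed = 41, noise = "none", nDecoys = 1,
                          tiltAngle = 90, nTilt = 3)
  res <- runPipeline(scn$candidates, scn$dataset, mode = "single")
  tab <- res$table
  expect_lt(tab$n_over_chi2[tab$descriptor == "decoy1"],
            tab$n_over_chi2[tab$descriptor == "true"])
})

test_that("observation noise follows the declared error model", {
  tmpl <- makeTemplate()
  S <- randomTensor(seed = 13)
  pr <- chPairs(tmpl)
  exact <- generateObservations(tmpl, S, noise = "none")
  expect_equal(couplingRecords(exact)$d_exp_hz,
               unname(forwardRdc(extractVectors(tmpl, pr), S)),
               tolerance = 1e-12)
  # default error profile cycles through the published spread
  expect_setequal(unique(couplingRecords(exact)$d_err_hz),
                  c(0.3, 0.5, 1.0, 1.5, 5.0))

  # gaussian mode: pooled noise sd within 5% of d_err/3
  dTrue <- forwardRdc(extractVectors(tmpl, pr), S)
  errs <- numeric(0)
  for (seed in 1:556) {
    g <- generateObservations(tmpl, S, noise = "gaussian", dErr = 3,
                              seed = seed)
    errs <- c(errs, couplingRecords(g)$d_exp_hz - unname(dTrue))
  }
  expect_equal(sd(errs), 1, tolerance = 0.05)

  # uniform mode: bounded support
  u <- generateObservations(tmpl, S, noise = "uniform", seed = 5)
  recU <- couplingRecords(u)
  expect_true(all(abs(recU$d_exp_hz - unname(dTrue)) <= recU$d_err_hz))
  # reproducibility
  expect_identical(
    couplingRecords(generateObservations(tmpl, S, noise = "gaussian",
                                         seed = 99)),
    couplingRecords(generateObservations(tmpl, S, noise = "gaussian",
                                         seed = 99)))
})

test_that("jump trajectories realize the requested stationary law", {
  tmpl <- makeTemplate()
  ts <- twoStateConformers()
  single <- generateJumpTrajectory(list(tmpl), 1, nFrames = 10, seed = 1)
  expect_true(all(vapply(frames(single), function(f)
    identical(atomCoords(f), atomCoords(tmpl)), logical(1))))
  one <- generateJumpTrajectory(list(ts$major, ts$minor), c(0.9, 0.1),
                                nFrames = 1, seed = 8)
  expect_equal(nFrames(one), 1L)
  expect_error(generateJumpTrajectory(list(tmpl), c(0.5, 0.5), 10),
               class = "rdcrank_validation")

  traj <- generateJumpTrajectory(list(ts$major, ts$minor), c(0.9, 0.1),
                                 nFrames = 4000, seed = 2024)
  isMinor <- vapply(frames(traj), function(f)
    identical(atomCoords(f), atomCoords(ts$minor)), logical(1))
  expect_lt(abs(mean(isMinor) - 0.10), 0.02)
})

test_that("scenario export writes couplings, structures and a manifest", {
  scn <- simulateScenario(seed = 10, nDecoys = 1)
  dir <- withr::local_tempdir()
  writeScenario(scn, dir)
  expect_true(file.exists(file.path(dir, "couplings.csv")))
  expect_true(file.exists(file.path(dir, "true.xyz")))
  expect_true(file.exists(file.path(dir, "decoy1.xyz")))
  man <- jsonlite::read_json(file.path(dir, "scenario.json"))
  expect_equal(man$true_candidate, "true")
  back <- readCouplingTable(file.path(dir, "couplings.csv"))
  expect_identical(couplingRecords(back), couplingRecords(scn$dataset))
})
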