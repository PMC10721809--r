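test_that("shock multiplier follows the piecewise dip-rebound-plateau shape", {
  p <- shockProfile("2020-03", "2020-04", nadirDrop = 0.67,
                    plateauDrop = 0.13, recoveryRate = 0.8)
  ## identity before onset
  expect_equal(shockMultiplier(p, c("2017-01", "2019-12", "2020-02")),
               c(1, 1, 1))
  ## nadir multiplier is 1 - A, mid-descent halfway down
  expect_equal(shockMultiplier(p, "2020-04"), 0.33)
  expect_equal(shockMultiplier(p, "2020-03"), 1 - 0.67 / 2)
  ## monotone convergence from 1 - A toward the 1 - B asymptote
  post <- shockMultiplier(p, ymSeq("2020-05", "2024-12"))
  expect_true(all(diff(post) >= 0))
  expect_true(all(post <= 0.87 + 1e-12))
  expect_true(all(post[1:24] < 0.87))        # approach is strict early on
  expect_equal(shockMultiplier(p, "2100-01"), 0.87, tolerance = 1e-6)
  ## negative plateauDrop models exceedance above baseline
  pe <- shockProfile(plateauDrop = -0.1, recoveryRate = 2)
  expect_gt(shockMultiplier(pe, "2021-12"), 1)
})

test_that("shock profile validity rejects out-of-range parameters", {
  expect_error(shockProfile(nadirDrop = 1.3), "nadirDrop")
  expect_error(shockProfile(plateauDrop = -1), "plateauDrop")
  expect_error(shockProfile(recoveryRate = -1), "recoveryRate")
  expect_error(shockProfile("2020-05", "2020-03"), "nadir")
})

test_that("identical config and seed give byte-identical panels", {
  cfg <- simConfig(nEntities = 4)
  a <- simulatePanel(cfg, seed = 7)
  b <- simulatePanel(cfg, seed = 7)
  expect_identical(panelCounts(a$panel), panelCounts(b$panel))
  expect_identical(a$truth, b$truth)
  c <- simulatePanel(cfg, seed = 8)
  expect_false(identical(panelCounts(a$panel), panelCounts(c$panel)))
})

test_that("per-entity substreams make an entity's counts independent of panel size", {
  cfg2 <- simConfig(nEntities = 2)
  cfg5 <- simConfig(nEntities = 5)
  a <- simulatePanel(cfg2, seed = 3)
  b <- simulatePanel(cfg5, seed = 3)
  expect_identical(panelCounts(a$panel)["E002", ],
                   panelCounts(b$panel)["E002", ])
})

test_that("replicate draws recover the planted mean (no-shock Poisson)", {
  cfg <- simConfig(nEntities = 1, startMonth = "2017-01",
                   endMonth = "2017-03",
                   baselineLogMean = c(log(120), log(120)),
                   trendPerYear = c(0, 0), seasonalAmplitude = c(0, 0),
                   shock = shockProfile(nadirDrop = 0, plateauDrop = 0))
  reps <- vapply(1:1000, function(s)
    panelCounts(simulatePanel(cfg, seed = s)$panel)[1, 2], 1.0)
  truth <- simulatePanel(cfg, seed = 1)$truth
  mu <- plantedMean(truth, "E001", "2017-02")
  se <- sqrt(mu / 1000)
  expect_lt(abs(mean(reps) - mu), 3 * se)
})

test_that("negative-binomial panels have the closed-form variance", {
  ## theta = 5, mean 100: Var = mu + mu^2/theta = 2100
  cfg <- simConfig(nEntities = 1, startMonth = "2017-01",
                   endMonth = "2017-02",
                   baselineLogMean = c(log(100), log(100)),
                   trendPerYear = c(0, 0), seasonalAmplitude = c(0, 0),
                   dispersionFamily = "negbin", negbinSize = 5,
                   shock = shockProfile(nadirDrop = 0, plateauDrop = 0))
  reps <- vapply(1:1000, function(s)
    panelCounts(simulatePanel(cfg, seed = s)$panel)[1, 1], 1.0)
  ## sampling error of s^2 from the exact 4th moment of NB(mu=100, size=5)
  k <- 0:5000
  pk <- dnbinom(k, mu = 100, size = 5)
  m4 <- sum((k - 100)^4 * pk)
  seVar <- sqrt((m4 - 2100^2) / 1000)
  expect_lt(abs(var(reps) - 2100), 4 * seVar)
})

test_that("planted nadir depth is non-increasing in severity rank", {
  sim <- simulatePanel(simConfig(nEntities = 10, severity = TRUE,
                                 baselineLogMean = c(6, 6.5)), seed = 2)
  tr <- sim$truth[order(sim$truth$severity_rank), ]
  expect_true(all(diff(tr$nadirDrop[!duplicated(tr$severity_rank)]) < 0))
  expect_true(all(diff(tr$plateauDrop[!duplicated(tr$severity_rank)]) < 0))
})

test_that("panels violating the mean floor are rejected", {
  cfg <- simConfig(nEntities = 1, baselineLogMean = c(log(20), log(20)),
                   trendPerYear = c(0, 0), seasonalAmplitude = c(0, 0),
                   shock = shockProfile(nadirDrop = 0.67))
  ## 20 * 0.33 = 6.6 < floor 15 at the nadir
  expect_error(simulatePanel(cfg, seed = 1), "floor")
})

test_that("panel CSV and truth JSON round-trip", {
  sim <- simulatePanel(simConfig(nEntities = 3, endMonth = "2018-12"),
                       seed = 4)
  csv <- tempfile(fileext = ".csv")
  writePanelCsv(sim$panel, csv)
  back <- readPanel(csv)
  expect_identical(panelCounts(back), panelCounts(sim$panel))
  expect_identical(entityCategories(back), entityCategories(sim$panel))

  js <- tempfile(fileext = ".json")
  writeTruthJson(sim$truth, js)
  obj <- jsonlite::read_json(js)
  expect_named(obj, sim$truth$entity_id)
  expect_equal(obj$E001$beta0, sim$truth$beta0[1])
})
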