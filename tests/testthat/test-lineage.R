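test_that("fate calls combine position and apical contact", {
  tb <- data.frame(cell_id = sprintf("c%d", 1:5),
                   z_um = c(5, 30, 5, 16, 30),
                   apical_contact = c(TRUE, FALSE, FALSE, NA, TRUE))
  fc <- assignFate(tb, vzMax = 16)
  expect_equal(fc$fate, c("P", "N", "unassigned", "unassigned", "P"))
  expect_equal(fc$basis[1], "both")
  expect_equal(fc$basis[5], "apical_contact")   # deep nucleus, apical process
  ## missing flag: position-only fallback
  fc2 <- assignFate(data.frame(z_um = c(5, 30, 16)), vzMax = 16)
  expect_equal(fc2$fate, c("P", "N", "unassigned"))
  expect_true(all(fc2$basis == "position"))
})

## constructed division scenarios: tree with one division at t = 36, two
## daughters whose table rows we control
.divScenario <- function(y2, z2, apical2, lastFrame = 45, z1 = 5,
                         apical1 = TRUE) {
  nodes <- data.frame(id = c("m", "d1", "d2"), parent = c(NA, "m", "m"),
                      birth = c(32, 36, 36), divTime = c(36, NA, NA),
                      mode = c("PP", NA, NA), fate = c("P", "P", "P"))
  tree <- new("LineageTree", nodes = nodes, founderId = "m", cloneId = "t",
              condition = "control")
  tt <- seq(36, lastFrame)
  cells <- rbind(
    data.frame(cell_id = "t_d1", time_hpf = tt, x_um = 0, y_um = 0, z_um = z1,
               apical_contact = apical1),
    data.frame(cell_id = "t_d2", time_hpf = tt, x_um = 0, y_um = y2,
               z_um = z2, apical_contact = apical2))
  list(tree = tree, cells = cells)
}

test_that("track-based division classification follows the spatial rules", {
  ## daughters 5 um apart, same DV level, both progenitors -> PP
  s <- .divScenario(y2 = 5, z2 = 5, apical2 = TRUE)
  expect_equal(classifyDivisions(s$tree, s$cells)$mode, "PP")
  ## daughters 30 um apart, one VZ one MZ -> PN
  s <- .divScenario(y2 = 10, z2 = 33, apical2 = FALSE)
  expect_equal(classifyDivisions(s$tree, s$cells)$mode, "PN")
  ## both in the mantle zone, in contact, same level -> NN
  s <- .divScenario(y2 = 5, z2 = 30, apical2 = FALSE, z1 = 30,
                    apical1 = FALSE)
  expect_equal(classifyDivisions(s$tree, s$cells)$mode, "NN")
  ## daughter tracked only 2 h -> no fate ascribed
  s <- .divScenario(y2 = 5, z2 = 5, apical2 = TRUE, lastFrame = 38)
  r <- classifyDivisions(s$tree, s$cells)
  expect_equal(r$mode, "unassigned")
  expect_equal(r$reason, "tracked_under_min_hours")
  ## contradictory: in contact but opposite fates
  s <- .divScenario(y2 = 5, z2 = 5, apical2 = FALSE, z1 = 5, apical1 = TRUE)
  r <- classifyDivisions(s$tree, s$cells)
  expect_equal(r$mode, "unassigned")
  expect_equal(r$reason, "contradictory_configuration")
})

test_that("raising the fate-exclusion window never adds assigned modes", {
  ds <- simulateDataset(simulationConfig(nFounders = 60, seed = 44))
  nAssigned <- vapply(c(0, 2, 3, 5, 8), function(h) {
    d <- classifyDivisions(ds$trees, ds$cells, minTrackedAfter = h)
    sum(d$mode != "unassigned")
  }, numeric(1))
  expect_true(all(diff(nAssigned) <= 0))
})

test_that("proliferative capacity: degenerate, closed-form and printed counts", {
  ## no divisions -> 100% non-dividing
  cfg0 <- simulationConfig(nFounders = 10, divisionProbPerFrame = 0, seed = 1)
  ds0 <- simulateDataset(cfg0)
  pc0 <- proliferativeCapacity(ds0$trees, window = c(32, 45))
  expect_equal(pc0$dividing_fraction, 0)
  ## survival closed form: founder-only cohort, dividing fraction is
  ## 1 - (1-p)^13
  p <- 0.056
  cfg <- simulationConfig(nFounders = 500, initialCellsProbs = c("1" = 1),
                          divisionProbPerFrame = p, seed = 19)
  ds <- simulateDataset(cfg)
  pc <- proliferativeCapacity(ds$trees, window = c(32, 45))
  q <- 1 - (1 - p)^13
  expect_lt(abs(pc$dividing_fraction - q), 3 * sqrt(q * (1 - q) / 500))
  ## printed tallies: 48 dividing of 90 -> 53%
  pcCounts <- proliferativeCapacity(counts = c(dividing = 48, total = 90))
  expect_equal(round(100 * pcCounts$dividing_fraction), 53)
  expect_error(proliferativeCapacity(list()), "empty")
})

test_that("endpoint composition rule counts PP, PN and paired NN", {
  ## {P=3, N=0}: all divisions symmetric proliferative
  cl <- data.frame(x_um = 0, y_um = c(0, 5, 10), z_um = 5,
                   apical_contact = TRUE)
  r <- inferDivisionModesEndpoint(cl)
  expect_equal(unname(r$counts), c(3L, 0L, 0L))
  expect_equal(unname(r$percentages["PP"]), 100)
  ## {P=0, N=2} paired in contact at the same level: one NN division
  cl2 <- data.frame(x_um = 0, y_um = c(0, 5), z_um = 25,
                    apical_contact = FALSE)
  r2 <- inferDivisionModesEndpoint(cl2)
  expect_equal(unname(r2$counts), c(0L, 0L, 1L))
  expect_equal(unname(r2$percentages["NN"]), 100)
  ## {P=2, N=1}: odd neuron count blocks NN
  cl3 <- data.frame(x_um = 0, y_um = c(0, 5, 10), z_um = c(5, 5, 30),
                    apical_contact = c(TRUE, TRUE, FALSE))
  r3 <- inferDivisionModesEndpoint(cl3)
  expect_equal(unname(r3$counts), c(2L, 1L, 0L))
  ## two distant neurons at different DV levels: no NN pair
  cl4 <- data.frame(x_um = 0, y_um = c(0, 30), z_um = c(22, 36),
                    apical_contact = FALSE)
  expect_equal(unname(inferDivisionModesEndpoint(cl4)$counts["NN"]), 0L)
  ## even_all alternative attributes all even neurons to NN
  r5 <- inferDivisionModesEndpoint(cl4, nnRule = "even_all")
  expect_equal(unname(r5$counts), c(0L, 0L, 1L))
  ## founder discounting restores the progenitor consumed by an NN division
  r6 <- inferDivisionModesEndpoint(cl2, founders = 1L)
  expect_equal(unname(r6$counts), c(0L, 0L, 1L))
  expect_error(inferDivisionModesEndpoint(cl2[0, ]), "empty")
})

test_that("division-mode shares reproduce printed percentages", {
  shares <- divisionModeShares(c(PP = 19, PN = 28, NN = 1))
  expect_equal(unname(shares), c(40, 58, 2))
  full <- divisionModeShares(c(PP = 19, PN = 28, NN = 1), digits = NULL)
  expect_equal(sum(full), 100)
  expect_error(divisionModeShares(c(PP = 0, PN = 0)), "no divisions")
})

test_that("sister analysis reports concordance, synchrony and delay", {
  ## divisions at 34.5 and 37 hpf: asynchronous, 2.5 h apart
  s <- sisterAnalysis(makeSisterTree(34.5, 37), t0 = 32)
  expect_equal(s$concordance, "same")
  expect_equal(s$synchrony, "asynchronous")
  expect_equal(s$delay_hours, 2.5)
  ## both divide at 34.5: synchronous, delay 0
  s2 <- sisterAnalysis(makeSisterTree(34.5, 34.5), t0 = 32)
  expect_equal(s2$synchrony, "synchronous")
  expect_equal(s2$delay_hours, 0)
  ## neither divides: same behavior, synchrony undefined
  s3 <- sisterAnalysis(makeSisterTree(NA, NA), t0 = 32)
  expect_equal(s3$concordance, "same")
  expect_true(is.na(s3$synchrony))
  ## one divides: different proliferative behavior
  expect_equal(sisterAnalysis(makeSisterTree(35, NA), t0 = 32)$concordance,
               "different")
  ## mode concordance
  expect_equal(sisterAnalysis(makeSisterTree(34, 36, c("PP", "PN")),
                              t0 = 32)$mode_concordance, "different")
  ## restricted to two-cell clones
  expect_error(sisterAnalysis(makeSmallTree(), t0 = 40), "two-cell")
})

test_that("clone growth bookkeeping and branching expectation", {
  ## two-cell clone, both divide once -> 4 cells at tf
  g <- cloneGrowth(list(makeSisterTree(35, 38)), atTimes = c(32, 45))
  expect_equal(unname(g$per_clone[1, ]), c(2, 4))
  g2 <- cloneGrowth(list(makeSisterTree(NA, NA)), atTimes = c(32, 45))
  expect_equal(unname(g2$per_clone[1, ]), c(2, 2))
  expect_equal(length(g$violations), 0L)
  ## asymmetric-only lineages keep a single progenitor, so divisions are
  ## Binomial(13, p) and E[cells at tf] = 1 + 13 p
  p <- 0.08
  cfg <- simulationConfig(nFounders = 500, initialCellsProbs = c("1" = 1),
                          divisionProbPerFrame = p,
                          modeProbs = c(PP = 0, PN = 1, NN = 0), seed = 27)
  ds <- simulateDataset(cfg)
  sizes <- vapply(ds$trees, nCells, numeric(1), at = 45)
  expected <- 1 + 13 * p
  se <- sqrt(13 * p * (1 - p) / 500)
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("mode time-course regression matches closed-form least squares", {
  ## constant 100% PP: slope 0, R^2 0 by convention
  d <- data.frame(time = rep(33:40, each = 3), mode = "PP")
  tc <- modeTimecourse(d)
  expect_equal(tc$regression$slope[1], 0)
  expect_equal(tc$regression$r_squared[1], 0)
  ## alternating 100%/0% PP bins: compare against hand-computed least squares
  d2 <- data.frame(time = c(33, 33, 34, 34, 35, 35, 36, 36),
                   mode = c("PP", "PP", "PN", "PN", "PP", "PP", "PN", "PN"))
  tc2 <- modeTimecourse(d2)
  x <- c(33.5, 34.5, 35.5, 36.5); y <- c(1, 0, 1, 0)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tc2$regression$slope[1], beta)
  expect_equal(tc2$bins$PP_fraction, y)
  ## single bin: flagged sparse, slope undefined
  tc3 <- modeTimecourse(data.frame(time = c(33.1, 33.4), mode = c("PP", "PN")))
  expect_true(tc3$sparse)
  expect_true(is.na(tc3$regression$slope[1]))
  expect_error(modeTimecourse(data.frame(time = 1, mode = "unassigned")),
               "no assigned")
})

test_that("tree validity catches malformed lineages", {
  nodes <- data.frame(id = c("a", "b"), parent = c("b", "a"),
                      birth = c(0, 1), divTime = c(1, NA),
                      mode = c("PP", NA), fate = c("P", "P"))
  expect_error(new("LineageTree", nodes = nodes, founderId = "a",
                   cloneId = "x", condition = "control"))
  nodes2 <- data.frame(id = c("a", "b"), parent = c(NA, "a"),
                       birth = c(0, 1), divTime = c(1, NA),
                       mode = c("PP", NA), fate = c("P", "P"))
  expect_error(new("LineageTree", nodes = nodes2, founderId = "a",
                   cloneId = "x", condition = "control"),
               "binary")
})
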