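test_that("degenerate recombination gives pure red manipulated founders", {
  cfg <- simulationConfig(
    nFounders = 50, copyNumberProbs = c("1" = 1),
    recombinationProbs = c(farred = 0, yfp = 0, turquoise = 0, tdtomato = 1),
    redManipulatedFraction = 1, seed = 4)
  fd <- simulateRecombination(cfg)
  expect_true(all(fd$r == 1 & fd$g == 0 & fd$b == 0))
  expect_true(all(fd$condition == "manipulated"))
  expect_false(any(fd$unrecombined))
})

test_that("two-copy recombination matches the exhaustive enumeration", {
  probs <- c(farred = 0, yfp = 1/3, turquoise = 1/3, tdtomato = 1/3)
  cfg <- simulationConfig(nFounders = 3000, copyNumberProbs = c("2" = 1),
                          recombinationProbs = probs, seed = 8)
  fd <- simulateRecombination(cfg)
  truthDist <- enumerateTwoCopyColors(as.list(probs))
  key <- paste(round(fd$r, 6), round(fd$g, 6), round(fd$b, 6), sep = ",")
  expect_true(all(key %in% names(truthDist)))  # support is exactly enumerable
  for (k in names(truthDist)) {
    p <- truthDist[[k]]
    se <- sqrt(p * (1 - p) / nrow(fd))
    expect_lt(abs(mean(key == k) - p), 3 * se)
  }
  ## vertices and edge midpoints only
  expect_true(all(sort(unique(round(fd$r, 6))) %in% c(0, 0.5, 1)))
})

test_that("recombination is reproducible under the seed and validates config", {
  cfg <- simulationConfig(nFounders = 1000, seed = 123)
  expect_identical(simulateRecombination(cfg), simulateRecombination(cfg))
  expect_error(simulationConfig(copyNumberProbs = c("1" = 0, "2" = 0)),
               "zero weight")
})

test_that("deterministic doubling: mode (1,0,0) with certain division", {
  ## synchronous sisters: with certain division every frame, the sister
  ## delay must be zero for the doubling to be exact
  cfg <- simulationConfig(nFounders = 1, divisionProbPerFrame = 1,
                          modeProbs = c(PP = 1, PN = 0, NN = 0),
                          initialCellsProbs = c("1" = 1),
                          sisterDelayMean = 0, sisterDelaySD = 0,
                          tStart = 32, tEnd = 34, seed = 1)
  tree <- simulateClone(cfg, data.frame(founder_id = "f1",
                                        condition = "control"), seed = 1)
  expect_equal(nCells(tree), 4L)          # 2 frames of certain doubling
  ev <- divisionEvents(tree)
  expect_equal(nrow(ev), 3L)
  expect_true(all(ev$mode == "PP"))
  expect_true(all(treeNodes(tree)$fate == "P"))
})

test_that("no divisions happen when the division probability is zero", {
  cfg <- simulationConfig(divisionProbPerFrame = 0,
                          initialCellsProbs = c("1" = 1), seed = 2)
  tree <- simulateClone(cfg, data.frame(founder_id = "f1",
                                        condition = "control"), seed = 2)
  expect_equal(nCells(tree, at = 45), 1L)
  expect_equal(nrow(divisionEvents(tree)), 0L)
})

test_that("cell count conservation: terminal cells = founders + divisions", {
  cfg <- simulationConfig(nFounders = 60, seed = 31)
  ds <- simulateDataset(cfg)
  for (tree in ds$trees) {
    nd <- treeNodes(tree)
    expect_equal(nCells(tree, at = 45), 1L + sum(!is.na(nd$divTime)))
  }
})

test_that("drawn division-mode frequencies converge to the configured rates", {
  cfg <- simulationConfig(nFounders = 500,
                          modeProbs = c(PP = 0.4, PN = 0.58, NN = 0.02),
                          seed = 55)
  ds <- simulateDataset(cfg)
  ## modes drawn in the observation window (pre-window divisions belong to
  ## the deterministic initial composition)
  modes <- do.call(rbind, lapply(ds$trees, divisionEvents))
  modes <- modes[modes$time >= 32, ]
  n <- nrow(modes)
  for (m in c("PP", "PN", "NN")) {
    p <- cfg@modeProbs[[m]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(modes$mode == m) - p), 3 * se)
  }
})

test_that("PP share per hour bin has no time trend under constant rates", {
  cfg <- simulationConfig(nFounders = 800, seed = 77,
                          modeProbs = c(PP = 0.5, PN = 0.5, NN = 0))
  ds <- simulateDataset(cfg)
  modes <- do.call(rbind, lapply(ds$trees, divisionEvents))
  tc <- modeTimecourse(modes[modes$time >= 32, ])
  reg <- tc$regression[tc$regression$mode == "PP", ]
  expect_gt(reg$p_value, 0.05)
})

test_that("rendering honors noise, fate-position coupling and determinism", {
  cfg <- simulationConfig(nFounders = 12, channelNoiseSD = 0, seed = 14)
  ds <- simulateDataset(cfg)
  ## zero noise: measured color equals the founder's true color exactly
  tr <- ds$truth[match(ds$cells$cell_id, ds$truth$cell_id), ]
  rec <- !ds$cells$unrecombined
  expect_equal(ds$cells$r_mean[rec], tr$true_r[rec])
  expect_equal(ds$cells$g_mean[rec], tr$true_g[rec])
  ## all-P rows carry apical contact
  pRows <- tr$fate == "P"
  expect_true(all(ds$cells$apical_contact[pRows]))
  ## neurons sit in the mantle zone from one frame after birth
  nLater <- tr$fate == "N" & ds$cells$time_hpf > tr$birth_hpf
  expect_true(all(ds$cells$z_um[nLater] > 16))
  ## identical config + seed => byte-identical tables
  ds2 <- simulateDataset(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeCellTable(ds$cells, f1); writeCellTable(ds2$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## clone labels withheld from the cell table, present in ground truth
  expect_false("clone_id" %in% names(ds$cells))
  expect_true("clone_id" %in% names(ds$truth))
})

test_that("rendering rejects times outside the window and warns on empty input", {
  cfg <- simulationConfig(nFounders = 2, seed = 3)
  ds <- simulateDataset(cfg)
  expect_error(renderCellTable(ds$trees, cfg, atTimes = c(10, 32)),
               "within")
  expect_warning(out <- renderCellTable(list(), cfg), "empty")
  expect_equal(nrow(out$cells), 0L)
})

test_that("initial clone sizes follow the configured composition", {
  cfg <- simulationConfig(nFounders = 600, seed = 91)
  ds <- simulateDataset(cfg)
  n0 <- vapply(ds$trees, nCells, numeric(1), at = 32)
  expect_true(all(n0 %in% 1:3))
  p2 <- cfg@initialCellsProbs[["2"]]
  expect_lt(abs(mean(n0 == 2) - p2), 3 * sqrt(p2 * (1 - p2) / 600))
})
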