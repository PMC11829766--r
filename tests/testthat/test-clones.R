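test_that("contact components merge and split clones as expected", {
  tb <- makeCellTable(3)            # 5 um apart, same color
  cs <- callClones(tb)
  expect_equal(nrow(cloneSummary(cs)), 1L)
  expect_equal(cloneSummary(cs)$n_cells, 3L)
  ## same color but out of contact -> two singletons
  tb2 <- makeCellTable(2); tb2$y_um <- c(0, 50)
  cs2 <- callClones(tb2)
  expect_equal(nrow(cloneSummary(cs2)), 2L)
  ## different color identity, touching -> still two clones
  tb3 <- makeCellTable(2)
  tb3[2, c("r_mean", "g_mean", "b_mean")] <- c(0.8, 0.1, 0.1)
  expect_equal(nrow(cloneSummary(callClones(tb3))), 2L)
  ## empty input -> empty output
  expect_equal(nrow(cloneSummary(callClones(tb[0, ]))), 0L)
})

test_that("clone numbering follows mediolateral then dorsoventral order", {
  tb <- makeCellTable(4)
  tb$y_um <- c(100, 100, 0, 0); tb$z_um <- c(30, 30, 5, 5)
  tb$apical_contact <- tb$z_um < 16
  cs <- callClones(tb)
  cl <- cloneSummary(cs)
  expect_equal(cl$clone_id, c("b1_c001", "b1_c002"))
  expect_equal(cl$ml_centroid, c(0, 100))  # left to right
})

test_that("clone partition is a true partition and row-order invariant", {
  ds <- simulateDataset(simulationConfig(nFounders = 40, seed = 21))
  sub <- ds$cells[ds$cells$time_hpf == 32, ]
  cs <- callClones(sub)
  asg <- cloneAssignments(cs)
  expect_true(all(!is.na(asg$clone_id[!asg$unrecombined])))
  expect_true(all(table(asg$cell_id) == 1L))
  ## shuffled rows give the identical cell -> clone mapping
  set.seed(9)
  cs2 <- callClones(sub[sample(nrow(sub)), ])
  m1 <- setNames(asg$clone_id, asg$cell_id)
  asg2 <- cloneAssignments(cs2)
  expect_identical(m1[asg2$cell_id], setNames(asg2$clone_id, asg2$cell_id))
})

test_that("zero-noise clone calling recovers the ground-truth partition exactly", {
  ds <- simulateDataset(simulationConfig(nFounders = 80, channelNoiseSD = 0,
                                         seed = 13))
  sub <- ds$cells[ds$cells$time_hpf == 32, ]
  cs <- callClones(sub)
  asg <- cloneAssignments(cs)
  truthClone <- ds$truth$clone_id[match(asg$cell_id, ds$truth$cell_id)]
  keep <- !is.na(asg$clone_id)
  pa <- partitionAgreement(asg$clone_id[keep], truthClone[keep])
  expect_equal(pa$rand, 1)
  expect_equal(pa$adjusted_rand, 1)
})

test_that("shrinking the contact distance only refines the partition", {
  ds <- simulateDataset(simulationConfig(nFounders = 30, seed = 6))
  sub <- ds$cells[ds$cells$time_hpf == 36, ]
  big <- cloneAssignments(callClones(sub, dContact = 15))
  small <- cloneAssignments(callClones(sub, dContact = 6))
  keep <- !is.na(big$clone_id) & !is.na(small$clone_id)
  ## every small-d clone is contained in exactly one big-d clone
  splitMap <- tapply(big$clone_id[keep], small$clone_id[keep],
                     function(x) length(unique(x)))
  expect_true(all(splitMap == 1L))
})

test_that("traceability filter keeps 1-3 cell progenitor-domain clones", {
  tb <- makeCellTable(6)
  ## clone A: two cells in VZ; clone B: four cells (too large)
  tb$y_um <- c(0, 5, 100, 105, 110, 115)
  cs <- callClones(tb)
  freq <- classifyFrequency(cloneAssignments(cs)$region_index)
  freq$frequency_class <- "rare"
  out <- filterTraceable(cs, freq)
  expect_equal(cloneSummary(out)$n_cells, 2L)
  expect_equal(attr(out, "dropped")$reason, "size")
  ## mantle-zone clone is dropped from the traceable set
  tbMZ <- makeCellTable(2); tbMZ$z_um <- 30; tbMZ$apical_contact <- FALSE
  csMZ <- callClones(tbMZ)
  outMZ <- filterTraceable(csMZ, freq)
  expect_equal(nrow(cloneSummary(outMZ)), 0L)
  expect_equal(attr(outMZ, "dropped")$reason, "outside_progenitor_domain")
})

test_that("frequent-color clones are kept only when isolated", {
  tb <- makeCellTable(4)
  tb$y_um <- c(0, 5, 20, 25)   # two same-color clones 20 um apart
  cs <- callClones(tb)
  expect_equal(nrow(cloneSummary(cs)), 2L)
  freq <- data.frame(region = cloneSummary(cs)$region_index[1],
                     frequency_class = "frequent")
  out <- filterTraceable(cs, freq)   # isolation radius 24 um
  expect_equal(nrow(cloneSummary(out)), 0L)
  expect_true(all(attr(out, "dropped")$reason == "frequent_not_isolated"))
  ## far apart -> both kept
  tb$y_um <- c(0, 5, 100, 105)
  out2 <- filterTraceable(callClones(tb), freq)
  expect_equal(nrow(cloneSummary(out2)), 2L)
})

test_that("clone linking matches identities across timepoints", {
  ds <- simulateDataset(simulationConfig(nFounders = 40, seed = 33))
  cs1 <- callClones(ds$cells[ds$cells$time_hpf == 32, ])
  cs2 <- callClones(ds$cells[ds$cells$time_hpf == 36, ])
  links <- linkClones(cs1, cs2)
  ok <- links[links$flag == "ok", ]
  ## linked pairs agree with the ground-truth lineage for >= 95% of clones
  truthOf <- function(cs, ids) {
    asg <- cloneAssignments(cs)
    vapply(ids, function(id) {
      cell <- asg$cell_id[!is.na(asg$clone_id) & asg$clone_id == id][1]
      ds$truth$clone_id[ds$truth$cell_id == cell]
    }, character(1))
  }
  agree <- truthOf(cs1, ok$clone_t1) == truthOf(cs2, ok$clone_t2)
  expect_gte(mean(agree), 0.95)
  expect_gte(nrow(ok) / nrow(links), 0.9)
})

test_that("dropout clones are reported unmatched, not force-linked", {
  tb1 <- makeCellTable(4)
  tb1$y_um <- c(0, 5, 100, 105)
  tb1[3:4, c("r_mean", "g_mean", "b_mean")] <-
    rep(c(0.8, 0.1, 0.1), each = 2)
  tb2 <- tb1[1:2, ]; tb2$time_hpf <- 36
  links <- linkClones(callClones(tb1), callClones(tb2))
  expect_equal(sort(links$flag), c("ok", "unmatched"))
})

test_that("pair-counting agreement matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  a <- sample(letters[1:6], 150, replace = TRUE)
  b <- sample(1:5, 150, replace = TRUE)
  expect_equal(partitionAgreement(a, b)$adjusted_rand,
               mclust::adjustedRandIndex(a, b))
  expect_equal(partitionAgreement(a, a)$rand, 1)
})
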