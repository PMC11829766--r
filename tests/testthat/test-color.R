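test_that("normalizeRGB projects measurements onto the simplex", {
  expect_equal(unlist(normalizeRGB(2, 2, 2)), c(r = 1/3, g = 1/3, b = 1/3))
  expect_equal(unlist(normalizeRGB(10, 0, 0)), c(r = 1, g = 0, b = 0))
  expect_equal(unlist(normalizeRGB(1, 2, 1)), c(r = 0.25, g = 0.5, b = 0.25))
  expect_error(normalizeRGB(0, 0, 0), "unclassifiable")
  expect_error(normalizeRGB(-1, 1, 1), "nonnegative")
  expect_true(is.na(normalizeRGB(0, 0, 0, onZero = "na")$r))
})

test_that("simplex vertices and barycenter land in the expected regions", {
  idx <- assignColorIdentity(c(1, 0, 0, 1/3), c(0, 1, 0, 1/3),
                             c(0, 0, 1, 1/3))
  ## three distinct corner regions
  expect_length(unique(idx[1:3]), 3L)
  ## barycenter: located by the brute-force oracle
  tris <- oracleTriangles()
  k <- oracleLocate(1/3, 1/3, tris)
  rv <- regionVertices()
  vr <- rv[rv$region == idx[4], c("r", "g")]
  expect_equal(sort(paste(vr$r, vr$g)),
               sort(paste(tris[[k]]$v[, 1], tris[[k]]$v[, 2])))
})

test_that("partition has exactly 25 regions and matches the geometric oracle", {
  set.seed(42)
  m <- matrix(rexp(30000), ncol = 3)
  m <- m / rowSums(m)
  idx <- assignColorIdentity(m[, 1], m[, 2], m[, 3])
  expect_true(all(idx >= 0 & idx <= 24))
  expect_identical(sort(unique(idx)), 0:24)
  ## every interior point agrees with brute-force point-in-triangle location
  tris <- oracleTriangles()
  rv <- regionVertices()
  triKey <- vapply(tris, function(t)
    paste(sort(paste(t$v[, 1], t$v[, 2])), collapse = ";"), character(1))
  regKey <- vapply(0:24, function(rg) {
    v <- rv[rv$region == rg, c("r", "g")]
    paste(sort(paste(v$r, v$g)), collapse = ";")
  }, character(1))
  sub <- m[1:2000, , drop = FALSE]
  ok <- vapply(seq_len(nrow(sub)), function(i) {
    k <- oracleLocate(sub[i, 1], sub[i, 2], tris)
    if (is.na(k)) return(TRUE)  # boundary point: covered below
    regKey[assignColorIdentity(sub[i, 1], sub[i, 2], sub[i, 3]) + 1L] ==
      triKey[k]
  }, logical(1))
  expect_true(all(ok))
})

test_that("grid-line and lattice points get exactly one region, upward for lattice", {
  ## points on interior grid lines
  online <- rbind(c(0.2, 0.5, 0.3), c(0.37, 0.2, 0.43), c(0.2, 0.2, 0.6))
  idx <- assignColorIdentity(online[, 1], online[, 2], online[, 3])
  expect_false(anyNA(idx))
  ## lattice points map to upward triangles (first 15 indices)
  lat <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.4, 0.4, 0.2),
               c(0.2, 0.8, 0), c(0.6, 0, 0.4))
  li <- assignColorIdentity(lat[, 1], lat[, 2], lat[, 3])
  expect_true(all(li <= 14))
  ## and each assigned triangle is incident to the lattice point
  rv <- regionVertices()
  for (i in seq_len(nrow(lat))) {
    v <- rv[rv$region == li[i], ]
    expect_true(any(abs(v$r - lat[i, 1]) < 1e-9 & abs(v$g - lat[i, 2]) < 1e-9))
  }
})

test_that("color identity is invariant to intensity scaling", {
  set.seed(7)
  m <- matrix(rexp(900), ncol = 3)
  base <- assignColorIdentity(normalizeRGB(m[, 1], m[, 2], m[, 3]))
  for (k in c(0.01, 3, 1e4)) {
    sc <- assignColorIdentity(normalizeRGB(k * m[, 1], k * m[, 2], k * m[, 3]))
    expect_identical(sc, base)
  }
})

test_that("frequency classes follow the frequent/rare thresholds", {
  counts <- c(`0` = 12, `5` = 2, `10` = 5, `20` = 81)
  cls <- classifyFrequency(counts)
  expect_equal(cls$frequency_class[cls$region == 0], "frequent")   # 12%
  expect_equal(cls$frequency_class[cls$region == 5], "rare")       # 2%
  expect_equal(cls$frequency_class[cls$region == 10], "intermediate")  # 5%
  expect_equal(sum(cls$fraction), 1)
  expect_error(classifyFrequency(numeric(0)), "empty")
})

test_that("red-condition classification follows the 5%/1% clone thresholds", {
  mk <- function(redFrac) data.frame(r_mean = redFrac, g_mean = (1 - redFrac) / 2,
                                     b_mean = (1 - redFrac) / 2)
  expect_equal(classifyRedCondition(mk(0.06))$condition, "red")
  expect_equal(classifyRedCondition(mk(0.005))$condition, "nonred")
  expect_equal(classifyRedCondition(mk(0.03))$condition, "excluded")
  expect_error(classifyRedCondition(data.frame(r_mean = 0, g_mean = 0,
                                               b_mean = 0)),
               "no classifiable")
  ## raw-mean alternative stays available
  raw <- classifyRedCondition(mk(0.06), method = "raw")
  expect_equal(raw$condition, "red")
})
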