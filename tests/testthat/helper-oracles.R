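## Independent oracles used across the suite.

## Brute-force point-in-triangle location on the ternary simplex: the 25
## triangles are constructed here from first principles (edge split into 5,
## upward and downward unit triangles) and a point is located by barycentric
## containment, independently of the floor arithmetic in the package.
oracleTriangles <- function() {
  tris <- list()
  for (i in 0:4) for (j in 0:(4 - i)) {
    tris[[length(tris) + 1]] <- list(
      up = TRUE, i = i, j = j,
      v = rbind(c(i, j), c(i + 1, j), c(i, j + 1)) / 5)
  }
  for (i in 0:3) for (j in 0:(3 - i)) {
    tris[[length(tris) + 1]] <- list(
      up = FALSE, i = i, j = j,
      v = rbind(c(i + 1, j), c(i, j + 1), c(i + 1, j + 1)) / 5)
  }
  tris
}

.baryContains <- function(p, v, tol = 1e-9) {
  a <- v[1, ]; b <- v[2, ]; c <- v[3, ]
  den <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (p[1] - c[1]) + (c[1] - b[1]) * (p[2] - c[2])) / den
  l2 <- ((c[2] - a[2]) * (p[1] - c[1]) + (a[1] - c[1]) * (p[2] - c[2])) / den
  l3 <- 1 - l1 - l2
  all(c(l1, l2, l3) > tol)
}

## strict-interior location: returns the list index of the unique containing
## triangle, or NA on a boundary point
oracleLocate <- function(r, g, tris = oracleTriangles()) {
  for (k in seq_along(tris))
    if (.baryContains(c(r, g), tris[[k]]$v)) return(k)
  NA_integer_
}

## exhaustive enumeration of 2-copy recombination outcomes for given per-copy
## outcome probabilities (names farred/yfp/turquoise/tdtomato); returns the
## distinct simplex colors and their probabilities (recombined-only average)
enumerateTwoCopyColors <- function(probs) {
  axes <- list(farred = NULL, tdtomato = c(1, 0, 0), yfp = c(0, 1, 0),
               turquoise = c(0, 0, 1))
  nm <- names(probs)
  out <- list()
  for (a in nm) for (b in nm) {
    pr <- probs[[a]] * probs[[b]]
    if (pr == 0) next
    rec <- Filter(Negate(is.null), axes[c(a, b)])
    key <- if (!length(rec)) "unrecombined" else
      paste(round(Reduce(`+`, rec) / length(rec), 6), collapse = ",")
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + pr
  }
  out
}

## closed-form Welch test from summaries, written independently for
## cross-checking welchFromSummary against constructed raw data
exactMoments <- function(n, mean, sd) {
  x <- scale(seq_len(n))[, 1]
  mean + sd * x / sqrt(sum(x^2) / (n - 1))
}
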