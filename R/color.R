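## Color model: normalized-RGB ternary simplex, the 25-region partition,
## frequency classes and red/non-red clone conditions.

#' Default color-classification thresholds
#'
#' Thresholds used throughout the color module: color identities occupying
#' more than `frequentMin` of the cells are "frequent", those below `rareMax`
#' are "rare"; clones with a mean red fraction above `redMin` are "red",
#' below `nonredMax` "nonred", anything in between is excluded.
#'
#' @param frequentMin lower bound (exclusive) of the frequent class, default 0.10.
#' @param rareMax upper bound (exclusive) of the rare class, default 0.025.
#' @param redMin lower bound (exclusive) of the red condition, default 0.05.
#' @param nonredMax upper bound (exclusive) of the non-red condition, default 0.01.
#' @return named list of thresholds (class `ColorThresholds`).
#' @examples
#' colorThresholds()
#' @export
colorThresholds <- function(frequentMin = 0.10, rareMax = 0.025,
                            redMin = 0.05, nonredMax = 0.01) {
  stopifnot(rareMax >= 0, rareMax < frequentMin, frequentMin <= 1,
            nonredMax >= 0, nonredMax < redMin, redMin <= 1)
  structure(list(frequentMin = frequentMin, rareMax = rareMax,
                 redMin = redMin, nonredMax = nonredMax),
            class = "ColorThresholds")
}

#' Normalize RGB channel means onto the ternary simplex
#'
#' Divides each channel by the channel sum, so that r + g + b = 1. Rows whose
#' channels are all zero cannot be placed on the simplex.
#'
#' @param r,g,b nonnegative channel intensities (vectors of equal length),
#'   or `r` may be a matrix/data.frame with columns r, g, b.
#' @param onZero what to do with all-zero rows: `"error"` (default) or
#'   `"na"` to return NA coordinates.
#' @return data.frame with columns `r`, `g`, `b` summing to 1 per row.
#' @examples
#' normalizeRGB(1, 2, 1)
#' @export
normalizeRGB <- function(r, g = NULL, b = NULL, onZero = c("error", "na")) {
  onZero <- match.arg(onZero)
  if (is.null(g)) {
    m <- as.data.frame(r)
    r <- m[[1]]; g <- m[[2]]; b <- m[[3]]
  }
  if (any(c(r, g, b) < 0, na.rm = TRUE))
    stop("channel intensities must be nonnegative")
  s <- r + g + b
  zero <- !is.na(s) & s <= 0
  if (any(zero)) {
    if (onZero == "error")
      stop("unclassifiable measurement: all channels zero")
    s[zero] <- NA_real_
  }
  data.frame(r = r / s, g = g / s, b = b / s)
}

## Region bookkeeping: the simplex edge is split into 5 equal intervals,
## giving 15 upward and 10 downward unit triangles. Upward triangle (i, j)
## has vertices (i,j), (i+1,j), (i,j+1) in units of 1/5 of (r, g); downward
## (i, j) has vertices (i+1,j), (i,j+1), (i+1,j+1). Indices are 0-based:
## upward triangles first (row-major in i then j), then downward.
.N_SUB <- 5L

.regionTable <- function() {
  up <- do.call(rbind, lapply(0:(.N_SUB - 1L), function(i)
    if (i <= .N_SUB - 1L)
      data.frame(i = i, j = 0:(.N_SUB - 1L - i), up = TRUE)))
  down <- do.call(rbind, lapply(0:(.N_SUB - 2L), function(i)
    data.frame(i = i, j = 0:(.N_SUB - 2L - i), up = FALSE)))
  out <- rbind(up, down)
  out$region <- seq_len(nrow(out)) - 1L
  out
}

.regionIndexFromIJ <- function(i, j, up) {
  n <- .N_SUB
  ifelse(up,
         i * n - (i * (i - 1L)) %/% 2L + j,
         (n * (n + 1L)) %/% 2L + i * (n - 1L) - (i * (i - 1L)) %/% 2L + j)
}

#' Assign ternary coordinates to one of the 25 color identities
#'
#' Partitions the normalized-RGB 2-simplex into a triangular grid with each
#' edge divided into 5 equal intervals, i.e. 15 upward plus 10 downward unit
#' triangles = 25 regions. A point with floors `i = floor(5r)`, `j = floor(5g)`,
#' `k = floor(5b)` lies in a downward triangle iff `i + j + k == 3`, otherwise
#' in the upward triangle `(i, j)`. Intervals are half-open, the upper simplex
#' boundary is closed, and grid lattice points are assigned to an upward
#' triangle, so every simplex point maps to exactly one region.
#'
#' @param r,g,b ternary coordinates (each in \[0, 1\], summing to 1 per row),
#'   or `r` may be a matrix/data.frame with columns r, g, b as returned by
#'   [normalizeRGB()].
#' @return integer vector of region indices in \[0, 24\] (NA in, NA out).
#' @examples
#' assignColorIdentity(normalizeRGB(c(2, 10, 1), c(2, 0, 2), c(2, 0, 1)))
#' @export
assignColorIdentity <- function(r, g = NULL, b = NULL) {
  if (is.null(g)) {
    m <- as.data.frame(r)
    r <- m[[1]]; g <- m[[2]]; b <- m[[3]]
  }
  ok <- !is.na(r) & !is.na(g) & !is.na(b)
  if (any(abs(r[ok] + g[ok] + b[ok] - 1) > 1e-6))
    stop("ternary coordinates must sum to 1")
  if (any(c(r[ok], g[ok], b[ok]) < -1e-9) || any(c(r[ok], g[ok], b[ok]) > 1 + 1e-9))
    stop("ternary coordinates must lie in [0, 1]")
  eps <- 1e-9
  i <- floor(.N_SUB * r + eps)
  j <- floor(.N_SUB * g + eps)
  k <- floor(.N_SUB * b + eps)
  s <- i + j + k
  ## lattice points (all coordinates on the grid): closed upper boundary,
  ## assigned to an upward triangle incident to the vertex
  lat <- ok & s >= .N_SUB
  i[lat] <- pmin(i[lat], .N_SUB - 1L)
  j[lat] <- pmin(j[lat], .N_SUB - 1L - i[lat])
  up <- s != (.N_SUB - 2L)   # s == 3 -> downward
  up[lat] <- TRUE
  out <- rep(NA_integer_, length(r))
  out[ok] <- as.integer(.regionIndexFromIJ(i[ok], j[ok], up[ok]))
  out
}

#' Vertices of the 25 ternary regions
#'
#' Coordinates of each region's triangle on the simplex, mainly for plotting
#' ternary diagrams and for cross-checking the partition.
#'
#' @return data.frame with columns `region`, `vertex` (1:3), `r`, `g`, `b`.
#' @export
regionVertices <- function() {
  tab <- .regionTable()
  n <- .N_SUB
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(rw) {
    i <- tab$i[rw]; j <- tab$j[rw]
    v <- if (tab$up[rw])
      rbind(c(i, j), c(i + 1L, j), c(i, j + 1L))
    else
      rbind(c(i + 1L, j), c(i, j + 1L), c(i + 1L, j + 1L))
    data.frame(region = tab$region[rw], vertex = 1:3,
               r = v[, 1] / n, g = v[, 2] / n)
  }))
  out$b <- 1 - out$r - out$g
  out
}

#' Classify color identities by frequency
#'
#' Color identities occupying more than `frequentMin` (default 10%) of the
#' classified cells are "frequent"; identities below `rareMax` (default 2.5%)
#' are "rare"; the rest are "intermediate". Rare identities are the ones whose
#' clones are unambiguous enough to trace.
#'
#' @param counts named vector or table of cell counts per region index, or an
#'   integer vector of region indices (then tabulated internally).
#' @param thresholds a [colorThresholds()] list.
#' @return data.frame with `region`, `count`, `fraction`, `frequency_class`.
#' @examples
#' classifyFrequency(c(`0` = 12, `7` = 2, `20` = 86))
#' @export
classifyFrequency <- function(counts, thresholds = colorThresholds()) {
  if (is.null(names(counts))) counts <- table(counts)
  counts <- counts[!is.na(names(counts))]
  total <- sum(counts)
  if (length(counts) == 0L || total <= 0)
    stop("empty region counts")
  frac <- as.numeric(counts) / total
  cls <- ifelse(frac > thresholds$frequentMin, "frequent",
                ifelse(frac < thresholds$rareMax, "rare", "intermediate"))
  data.frame(region = as.integer(names(counts)), count = as.numeric(counts),
             fraction = frac, frequency_class = cls)
}

#' Classify a clone as red, non-red, or excluded
#'
#' In functional multicolor designs the manipulated construct co-expresses
#' with the red fluorophore, so clones are compared by their red content:
#' a clone whose mean red fraction exceeds `redMin` (default 5%) is "red",
#' one below `nonredMax` (default 1%) is "nonred"; clones in between are
#' excluded from the comparison.
#'
#' @param cells data.frame of clone members with columns `r_mean`, `g_mean`,
#'   `b_mean` (or `r`, `g`, `b`).
#' @param thresholds a [colorThresholds()] list.
#' @param method `"normalized"` (default): mean over cells of R/(R+G+B),
#'   illumination-invariant; `"raw"`: mean red channel relative to the summed
#'   mean channels.
#' @return list with `condition` ("red", "nonred" or "excluded"),
#'   `red_fraction`, and `n_cells` used.
#' @examples
#' classifyRedCondition(data.frame(r_mean = 6, g_mean = 47, b_mean = 47))
#' @export
classifyRedCondition <- function(cells, thresholds = colorThresholds(),
                                 method = c("normalized", "raw")) {
  method <- match.arg(method)
  nm <- if (all(c("r_mean", "g_mean", "b_mean") %in% names(cells)))
    c("r_mean", "g_mean", "b_mean") else c("r", "g", "b")
  if (nrow(cells) < 1L) stop("clone must have at least one cell")
  r <- cells[[nm[1]]]; g <- cells[[nm[2]]]; b <- cells[[nm[3]]]
  s <- r + g + b
  ok <- !is.na(s) & s > 0
  if (!any(ok)) stop("no classifiable cells in clone (all channels zero)")
  redFrac <- if (method == "normalized") mean(r[ok] / s[ok]) else
    mean(r[ok]) / mean(s[ok])
  condition <- if (redFrac > thresholds$redMin) "red"
  else if (redFrac < thresholds$nonredMax) "nonred"
  else "excluded"
  list(condition = condition, red_fraction = redFrac, n_cells = sum(ok))
}
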