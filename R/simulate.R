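## Synthetic multicolor clone generator: recombination outcomes, stochastic
## lineage trees, and rendering to annotated cell tables with ground truth.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.RGB_OUTCOME <- rbind(tdtomato = c(1, 0, 0),
                      yfp = c(0, 1, 0),
                      turquoise = c(0, 0, 1))

#' Simulate multicolor recombination outcomes of labelled founders
#'
#' Each founder carries a number of transgene copies drawn from the configured
#' copy-number distribution; each copy independently recombines to one of the
#' spectrally distinct fluorophores (tdTomato -> R, YFP -> G, mTurquoise -> B)
#' or stays in the unrecombined far-red default state. The founder's true
#' color is the average of its recombined copies on the RGB simplex; founders
#' with no recombined copy are flagged `unrecombined` (they carry no simplex
#' color and are excluded by downstream color classification). In functional
#' (zebrabow2.0-style) designs, a configurable fraction of founders carrying
#' at least one tdTomato copy is labelled as genetically manipulated.
#'
#' @param config a [SimulationConfig-class].
#' @param n number of founders (default `nFounders` from the config).
#' @param seed seed (default the config seed; `NULL` uses the current RNG
#'   state, as [simulateDataset()] does internally).
#' @return data.frame with one row per founder: `founder_id`, `copies`,
#'   true simplex color `r`, `g`, `b` (NA when unrecombined), `unrecombined`,
#'   `has_red`, and `condition` ("control" or "manipulated").
#' @examples
#' cfg <- simulationConfig(nFounders = 5, seed = 7)
#' simulateRecombination(cfg)
#' @export
simulateRecombination <- function(config, n = NULL, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(n)) n <- config@nFounders
  if (n < 1) stop("n must be >= 1")
  .withSeed(seed, {
    copyCounts <- as.integer(names(config@copyNumberProbs))
    copies <- copyCounts[sample.int(length(copyCounts), n, replace = TRUE,
                                    prob = config@copyNumberProbs)]
    outNames <- names(config@recombinationProbs)
    res <- lapply(copies, function(k) {
      oc <- sample(outNames, k, replace = TRUE,
                   prob = config@recombinationProbs)
      rec <- oc[oc != "farred"]
      if (length(rec) == 0L)
        list(col = c(NA_real_, NA_real_, NA_real_), red = FALSE, unrec = TRUE)
      else
        list(col = colMeans(.RGB_OUTCOME[rec, , drop = FALSE]),
             red = any(rec == "tdtomato"), unrec = FALSE)
    })
    col <- do.call(rbind, lapply(res, `[[`, "col"))
    hasRed <- vapply(res, `[[`, logical(1), "red")
    unrec <- vapply(res, `[[`, logical(1), "unrec")
    manipulated <- hasRed & config@redManipulatedFraction > 0 &
      runif(n) < config@redManipulatedFraction
    data.frame(founder_id = sprintf("f%04d", seq_len(n)),
               copies = copies,
               r = col[, 1], g = col[, 2], b = col[, 3],
               unrecombined = unrec, has_red = hasRed,
               condition = ifelse(manipulated, "manipulated", "control"))
  })
}

## truncated-at-zero normal sister delay, discretized to the time grid
.drawSisterDelay <- function(config) {
  m <- config@sisterDelayMean; s <- config@sisterDelaySD
  if (s == 0) d <- max(0, m)
  else {
    d <- -1
    for (it in 1:1000) { d <- rnorm(1, m, s); if (d >= 0) break }
    if (d < 0) d <- 0
  }
  unit <- config@frameInterval / (if (config@halfFrameJitter) 2 else 1)
  round(d / unit) * unit
}

#' Simulate the lineage of one labelled clone
#'
#' Grows a stochastic lineage tree on the imaging time grid. Progenitors
#' divide in each frame with probability `divisionProbPerFrame`; every
#' division draws a mode from `modeProbs` (PP: two progenitors, PN: one
#' progenitor and one neuron, NN: two neurons). Neurons never divide. When
#' both daughters of a division are progenitors, the second sister's division
#' is offset from the first by a delay drawn from the configured truncated
#' normal (so sister divisions are asynchronous by a controlled amount, and a
#' sister whose delayed division would fall beyond the imaging window does not
#' divide). Clones enter the observation window with one to three cells
#' according to `initialCellsProbs`; pre-window divisions are symmetric
#' proliferative, mirroring a progenitor pool that expanded before
#' neurogenesis onset.
#'
#' @param config a [SimulationConfig-class].
#' @param founder one-row data.frame as returned by [simulateRecombination()]
#'   (only `founder_id` and `condition` are used here).
#' @param seed seed (`NULL`, the default, uses the current RNG state).
#' @return a [LineageTree-class].
#' @examples
#' cfg <- simulationConfig(seed = 3)
#' fd <- simulateRecombination(cfg, n = 1)
#' simulateClone(cfg, fd, seed = 3)
#' @export
simulateClone <- function(config, founder, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(seed, .simulateCloneImpl(config, founder))
}

.simulateCloneImpl <- function(config, founder) {
  step <- config@frameInterval
  t0 <- config@tStart; tf <- config@tEnd
  p <- config@divisionProbPerFrame
  condition <- if (!is.null(founder$condition)) founder$condition[1] else "control"
  mp <- if (condition == "manipulated" && length(config@modeProbsRed))
    config@modeProbsRed else config@modeProbs

  ids <- character(); parent <- character(); birth <- numeric()
  divTime <- numeric(); mode <- character(); fate <- character()
  counter <- 0L
  addCell <- function(par, b, f) {
    counter <<- counter + 1L
    id <- sprintf("c%03d", counter)
    ids[counter] <<- id; parent[counter] <<- par
    birth[counter] <<- b; divTime[counter] <<- NA_real_
    mode[counter] <<- NA_character_; fate[counter] <<- f
    id
  }
  setDivision <- function(id, t, m) {
    i <- match(id, ids); divTime[i] <<- t; mode[i] <<- m
  }
  ## first allowed division frame is minTime; Inf = never divides in window
  drawDivTime <- function(b, minTime = NULL) {
    if (p <= 0) return(Inf)
    first <- max(b + step, if (is.null(minTime)) -Inf else minTime)
    t <- first + rgeom(1L, p) * step
    if (t > tf) Inf else t
  }
  drawMode <- function() sample(c("PP", "PN", "NN"), 1L, prob = mp)

  ## pending divisions: named vector id -> division time
  pending <- list()
  schedule <- function(id, t) if (is.finite(t)) pending[[id]] <<- t

  ## a PP sibling pair: first sister divides per the frame process, the
  ## second at the first sister's time plus the sister delay
  linkSisters <- function(idA, idB, minTime = NULL) {
    ord <- sample(c(idA, idB))
    bA <- birth[match(ord[1], ids)]
    tA <- drawDivTime(bA, minTime)
    if (is.finite(tA)) {
      schedule(ord[1], tA)
      tB <- tA + .drawSisterDelay(config)
      if (tB <= tf) schedule(ord[2], tB)
    }
  }

  ## initial composition at tStart
  n0sup <- as.integer(names(config@initialCellsProbs))
  n0 <- n0sup[sample.int(length(n0sup), 1L, prob = config@initialCellsProbs)]
  minT <- t0 + step  # keep the drawn t0 composition intact
  if (n0 == 1L) {
    fid <- addCell(NA_character_, t0, "P")
    schedule(fid, drawDivTime(t0, minT))
  } else if (n0 == 2L) {
    fid <- addCell(NA_character_, t0 - 2 * step, "P")
    setDivision(fid, t0 - step, "PP")
    a <- addCell(fid, t0 - step, "P")
    b <- addCell(fid, t0 - step, "P")
    linkSisters(a, b, minT)
  } else {
    fid <- addCell(NA_character_, t0 - 3 * step, "P")
    setDivision(fid, t0 - 2 * step, "PP")
    a <- addCell(fid, t0 - 2 * step, "P")
    b <- addCell(fid, t0 - 2 * step, "P")
    setDivision(a, t0 - step, "PP")
    a1 <- addCell(a, t0 - step, "P")
    a2 <- addCell(a, t0 - step, "P")
    linkSisters(a1, a2, minT)
    schedule(b, drawDivTime(birth[match(b, ids)], minT))
  }

  while (length(pending)) {
    tNext <- min(unlist(pending))
    id <- names(pending)[which.min(unlist(pending))]
    pending[[id]] <- NULL
    m <- drawMode()
    setDivision(id, tNext, m)
    if (m == "PP") {
      d1 <- addCell(id, tNext, "P"); d2 <- addCell(id, tNext, "P")
      linkSisters(d1, d2)
    } else if (m == "PN") {
      d1 <- addCell(id, tNext, "P"); addCell(id, tNext, "N")
      schedule(d1, drawDivTime(tNext))
    } else {
      addCell(id, tNext, "N"); addCell(id, tNext, "N")
    }
  }

  nodes <- data.frame(id = ids, parent = parent, birth = birth,
                      divTime = divTime, mode = mode, fate = fate)
  new("LineageTree", nodes = nodes, founderId = nodes$id[1],
      cloneId = if (!is.null(founder$founder_id)) founder$founder_id[1] else "clone",
      condition = condition)
}

## ---- LineageTree methods ----------------------------------------------

.aliveAt <- function(nodes, t) {
  nodes$birth <= t + 1e-9 & (is.na(nodes$divTime) | nodes$divTime > t + 1e-9)
}

#' @rdname nCells
#' @export
setMethod("nCells", "LineageTree", function(x, at = NULL) {
  nd <- x@nodes
  if (is.null(at)) sum(is.na(nd$divTime)) else sum(.aliveAt(nd, at))
})

#' @rdname divisionEvents
#' @export
setMethod("divisionEvents", "LineageTree", function(x) {
  nd <- x@nodes
  div <- nd[!is.na(nd$divTime), , drop = FALSE]
  if (nrow(div) == 0L)
    return(data.frame(mother = character(), time = numeric(),
                      mode = character(), daughter1 = character(),
                      daughter2 = character(), cloneId = character(),
                      condition = character()))
  kids <- split(nd$id[!is.na(nd$parent)], nd$parent[!is.na(nd$parent)])
  data.frame(mother = div$id, time = div$divTime, mode = div$mode,
             daughter1 = vapply(kids[div$id], `[`, character(1), 1L),
             daughter2 = vapply(kids[div$id], `[`, character(1), 2L),
             cloneId = x@cloneId, condition = x@condition,
             row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("treeNodes", "LineageTree", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("founderId", "LineageTree", function(x) x@founderId)

#' @rdname accessors
#' @export
setMethod("cloneCondition", "LineageTree", function(x) x@condition)

setMethod("show", "LineageTree", function(object) {
  nd <- object@nodes
  cat(sprintf("LineageTree %s (%s): %d cells, %d divisions, %d terminal (%s)\n",
              object@cloneId, object@condition, nrow(nd),
              sum(!is.na(nd$divTime)), sum(is.na(nd$divTime)),
              paste(sprintf("%d %s", table(nd$fate[is.na(nd$divTime)]),
                            names(table(nd$fate[is.na(nd$divTime)]))),
                    collapse = ", ")))
  invisible(NULL)
})

## ---- rendering ---------------------------------------------------------

## Deterministic within-clone layout. Cells occupy 5-um lateral lanes in
## creation order (sisters are adjacent, hence in contact). Progenitors sit
## apically (z = 5 um) with apical contact; neurons translocate to the mantle
## zone one frame after the division that created them. Neuron depths are
## staggered so that only NN sister pairs form mutually-nearest contacting
## pairs at the same dorsoventral level.
.layoutTree <- function(tree, config, yCenter, xCenter) {
  nd <- tree@nodes
  n <- nrow(nd)
  vzMax <- config@vzFraction * config@tissueHeight
  y <- yCenter + 5 * (seq_len(n) - 1L)
  z <- rep(5, n)
  isN <- nd$fate == "N"
  if (any(isN)) {
    ## distinguish NN sisters (parent mode NN) from PN-born neurons
    pmode <- nd$mode[match(nd$parent, nd$id)]
    nnChild <- isN & !is.na(pmode) & pmode == "NN"
    pnIdx <- which(isN & !nnChild)
    if (length(pnIdx))
      z[pnIdx] <- vzMax + 4 + 8 * ((seq_along(pnIdx) - 1L) %% 3L)
    nnIdx <- which(nnChild)
    if (length(nnIdx)) {
      par <- nd$parent[nnIdx]
      pairLevel <- (match(par, unique(par)) - 1L) %% 3L
      z[nnIdx] <- vzMax + 6 + 8 * pairLevel
    }
  }
  data.frame(id = nd$id, x = xCenter, y = y, z = z)
}

#' Render lineage trees to an annotated cell table with ground truth
#'
#' Materializes a set of simulated clones as the per-cell, per-timepoint
#' table an imaging analysis would start from: 3-D positions, measured RGB
#' channel means (true clone color plus independent Gaussian channel noise,
#' clipped at zero), apical-contact flags, and embryo/boundary identifiers.
#' Progenitors lie in the ventricular zone with apical contact; neurons lie
#' in the mantle zone without apical contact, appearing there one frame after
#' the division that created them. Cells of one clone are placed within
#' contact distance of their neighbours while distinct clones are separated
#' by `cloneSpacing`. Clone labels are withheld from the cell table and
#' reported in the ground-truth sidecar.
#'
#' @param trees list of [LineageTree-class] objects.
#' @param config the [SimulationConfig-class] used to simulate them.
#' @param atTimes timepoints (hpf) to render; default every frame from
#'   `tStart` to `tEnd`.
#' @param founders optional data.frame from [simulateRecombination()] matching
#'   the trees (for true colors and flags); if omitted, all clones render as a
#'   neutral color.
#' @param clonesPerBoundary,boundariesPerEmbryo how trees are distributed
#'   over boundaries and embryos.
#' @param seed seed for the measurement noise (`NULL`: current RNG state).
#' @return list with `cells` (the cell table: cell_id, time_hpf, x_um, y_um,
#'   z_um, r_mean, g_mean, b_mean, apical_contact, embryo_id, boundary_id,
#'   unrecombined) and `truth` (per-cell ground truth keyed by cell_id).
#' @export
renderCellTable <- function(trees, config, atTimes = NULL, founders = NULL,
                            clonesPerBoundary = 8L, boundariesPerEmbryo = 3L,
                            seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(trees) == 0L) {
    warning("no trees to render; returning empty tables")
    return(list(cells = data.frame(), truth = data.frame()))
  }
  if (is.null(atTimes))
    atTimes <- seq(config@tStart, config@tEnd, by = config@frameInterval)
  if (any(atTimes < config@tStart - 1e-9 | atTimes > config@tEnd + 1e-9))
    stop("atTimes must lie within [tStart, tEnd]")
  .withSeed(seed, {
    cellRows <- vector("list", length(trees))
    truthRows <- vector("list", length(trees))
    for (ti in seq_along(trees)) {
      tree <- trees[[ti]]
      nd <- tree@nodes
      bi <- (ti - 1L) %/% clonesPerBoundary
      ei <- bi %/% boundariesPerEmbryo
      boundaryId <- sprintf("e%02d_b%d", ei + 1L,
                            bi %% boundariesPerEmbryo + 1L)
      embryoId <- sprintf("e%02d", ei + 1L)
      ci <- ti - 1L - bi * clonesPerBoundary
      lay <- .layoutTree(tree, config, yCenter = 30 + ci * config@cloneSpacing,
                         xCenter = 50)
      fd <- if (!is.null(founders)) founders[ti, ] else
        data.frame(r = 1 / 3, g = 1 / 3, b = 1 / 3, unrecombined = FALSE)
      trueCol <- if (isTRUE(fd$unrecombined)) c(0, 0, 0) else
        c(fd$r, fd$g, fd$b)
      cellIds <- paste0(tree@cloneId, "_", nd$id)
      perTime <- lapply(atTimes, function(t) {
        alive <- .aliveAt(nd, t)
        if (!any(alive)) return(NULL)
        idx <- which(alive)
        zt <- lay$z[idx]
        ## newborn neurons still sit apically, endfoot attached, for their
        ## birth frame; they translocate to the mantle zone one frame later
        newborn <- nd$fate[idx] == "N" & abs(nd$birth[idx] - t) < 1e-9
        zt[newborn] <- 5
        apical <- nd$fate[idx] == "P" | newborn
        data.frame(cell_id = cellIds[idx], time_hpf = t,
                   x_um = lay$x[idx], y_um = lay$y[idx], z_um = zt,
                   r_mean = trueCol[1], g_mean = trueCol[2],
                   b_mean = trueCol[3],
                   apical_contact = apical,
                   embryo_id = embryoId, boundary_id = boundaryId,
                   unrecombined = isTRUE(fd$unrecombined))
      })
      cellRows[[ti]] <- do.call(rbind, perTime)
      truthRows[[ti]] <- data.frame(
        cell_id = cellIds,
        clone_id = tree@cloneId,
        parent_id = ifelse(is.na(nd$parent), NA_character_,
                           paste0(tree@cloneId, "_", nd$parent)),
        birth_hpf = nd$birth, division_hpf = nd$divTime,
        division_mode = nd$mode, fate = nd$fate,
        condition = tree@condition,
        true_r = trueCol[1], true_g = trueCol[2], true_b = trueCol[3],
        unrecombined = isTRUE(fd$unrecombined))
    }
    cells <- do.call(rbind, cellRows)
    if (config@channelNoiseSD > 0) {
      nr <- nrow(cells)
      for (col in c("r_mean", "g_mean", "b_mean"))
        cells[[col]] <- pmax(0, cells[[col]] +
                               rnorm(nr, 0, config@channelNoiseSD))
    }
    rownames(cells) <- NULL
    list(cells = cells, truth = do.call(rbind, truthRows))
  })
}

#' Simulate a complete multicolor clonal dataset
#'
#' Convenience wrapper running [simulateRecombination()], [simulateClone()]
#' per founder, and [renderCellTable()] under the single configured seed.
#'
#' @param config a [SimulationConfig-class].
#' @param atTimes timepoints to render (default every frame).
#' @param ... further arguments passed to [renderCellTable()].
#' @return list with `config`, `founders`, `trees`, `cells`, `truth`.
#' @examples
#' ds <- simulateDataset(simulationConfig(nFounders = 4, seed = 11))
#' head(ds$cells)
#' @export
simulateDataset <- function(config, atTimes = NULL, ...) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withr::with_seed(as.integer(config@seed), {
    founders <- simulateRecombination(config, seed = NULL)
    trees <- lapply(seq_len(nrow(founders)), function(i)
      simulateClone(config, founders[i, ], seed = NULL))
    rt <- renderCellTable(trees, config, atTimes = atTimes,
                          founders = founders, seed = NULL, ...)
    list(config = config, founders = founders, trees = trees,
         cells = rt$cells, truth = rt$truth)
  })
}
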