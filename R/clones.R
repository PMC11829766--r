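## Clone calling: connected components of the "same color identity and in
## close contact" graph, traceability filters, and linking across timepoints.

#' Call clones from a single-timepoint cell table
#'
#' Cells falling in the same ternary color identity (RGB subdivision) and in
#' close spatial contact are considered clonally related: clones are the
#' connected components of the graph joining cells with equal region index at
#' centroid distance at most `dContact`. Clones are numbered per boundary by
#' mediolateral position (left to right), then dorsoventral position, and the
#' clone id is the boundary id plus that ordinal. Cells flagged
#' `unrecombined`, or with all channels zero, are left unassigned.
#'
#' @param cells cell table (see [readCellTable()]) from one timepoint;
#'   multiple boundaries are processed independently.
#' @param dContact contact distance in micrometers (default 12, about one
#'   nuclear diameter).
#' @param axes names of the coordinate columns used for distances; the second
#'   and third are interpreted as the mediolateral and dorsoventral axes for
#'   clone numbering.
#' @return a [CloneSet-class].
#' @examples
#' ds <- simulateDataset(simulationConfig(nFounders = 6, seed = 2))
#' cs <- callClones(ds$cells[ds$cells$time_hpf == 32, ])
#' cloneSummary(cs)
#' @export
callClones <- function(cells, dContact = 12,
                       axes = c("x_um", "y_um", "z_um")) {
  if (dContact <= 0) stop("dContact must be > 0")
  if (is.null(cells) || nrow(cells) == 0L) {
    empty <- data.frame(cell_id = character(), clone_id = character(),
                        region_index = integer())
    return(new("CloneSet", cells = empty,
               clones = data.frame(clone_id = character(),
                                   embryo_id = character(),
                                   boundary_id = character(),
                                   region_index = integer(),
                                   n_cells = integer(),
                                   ml_centroid = numeric(),
                                   dv_centroid = numeric()),
               dContact = dContact))
  }
  if (length(unique(cells$time_hpf)) > 1L)
    stop("callClones expects cells from a single timepoint")
  if (!"boundary_id" %in% names(cells)) cells$boundary_id <- "b1"
  if (!"embryo_id" %in% names(cells)) cells$embryo_id <- "e1"
  cells <- cells[order(cells$cell_id), , drop = FALSE]  # row-order invariance
  s <- cells$r_mean + cells$g_mean + cells$b_mean
  classifiable <- s > 0 &
    !(("unrecombined" %in% names(cells)) & isTRUE_vec(cells$unrecombined))
  tern <- normalizeRGB(cells$r_mean, cells$g_mean, cells$b_mean, onZero = "na")
  region <- rep(NA_integer_, nrow(cells))
  region[classifiable] <- assignColorIdentity(tern[classifiable, , drop = FALSE])
  cells$region_index <- region
  cells$clone_id <- NA_character_

  cloneRows <- list()
  for (bid in unique(cells$boundary_id)) {
    sel <- which(cells$boundary_id == bid & !is.na(region))
    if (!length(sel)) next
    sub <- cells[sel, , drop = FALSE]
    comp <- .contactComponents(sub[, axes, drop = FALSE],
                               sub$region_index, dContact)
    mlc <- tapply(sub[[axes[2]]], comp, mean)
    dvc <- tapply(sub[[axes[3]]], comp, mean)
    ord <- order(mlc, dvc)
    newNum <- match(comp, as.integer(names(mlc)[ord]))
    cid <- sprintf("%s_c%03d", bid, newNum)
    cells$clone_id[sel] <- cid
    cloneRows[[bid]] <- data.frame(
      clone_id = sprintf("%s_c%03d", bid, seq_along(ord)),
      embryo_id = sub$embryo_id[1], boundary_id = bid,
      region_index = as.integer(tapply(sub$region_index, comp, `[`, 1L))[ord],
      n_cells = as.integer(table(comp))[ord],
      ml_centroid = as.numeric(mlc[ord]), dv_centroid = as.numeric(dvc[ord]))
  }
  clones <- if (length(cloneRows)) do.call(rbind, cloneRows) else
    data.frame(clone_id = character(), embryo_id = character(),
               boundary_id = character(), region_index = integer(),
               n_cells = integer(), ml_centroid = numeric(),
               dv_centroid = numeric())
  rownames(clones) <- NULL
  rownames(cells) <- NULL
  new("CloneSet", cells = cells, clones = clones, dContact = dContact)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

## connected components of the same-region contact graph; returns an integer
## component label per row
.contactComponents <- function(pos, region, dContact) {
  n <- nrow(pos)
  if (n == 1L) return(1L)
  m <- as.matrix(pos)
  edges <- NULL
  d2 <- dContact^2
  for (i in seq_len(n - 1L)) {
    dx <- sweep(m[(i + 1):n, , drop = FALSE], 2, m[i, ])
    near <- rowSums(dx^2) <= d2 + 1e-9
    same <- region[(i + 1):n] == region[i]
    hit <- which(near & same)
    if (length(hit)) edges <- rbind(edges, cbind(i, i + hit))
  }
  if (is.null(edges)) return(seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  igraph::components(g)$membership
}

#' @rdname accessors
#' @export
setMethod("cloneAssignments", "CloneSet", function(x) x@cells)

#' @rdname accessors
#' @export
setMethod("cloneSummary", "CloneSet", function(x) x@clones)

setMethod("show", "CloneSet", function(object) {
  cat(sprintf("CloneSet: %d clones over %d cells (%d unassigned), dContact = %g um\n",
              nrow(object@clones), nrow(object@cells),
              sum(is.na(object@cells$clone_id)), object@dContact))
  invisible(NULL)
})

#' Filter clones to the traceable subset
#'
#' Applies the traceability criteria used when selecting clones at the start
#' of a time-lapse: keep clones of `minCells` to `maxCells` cells whose
#' members all lie in the progenitor domain (apical contact, or dorsoventral
#' position within the ventricular-zone band). Clones with a frequent color
#' identity are kept only when isolated, i.e. when no other clone of the same
#' identity lies within `isolationRadius` (default twice the contact
#' distance); otherwise same-colored neighbours cannot be told apart and all
#' of them are dropped.
#'
#' @param cloneSet a [CloneSet-class] from [callClones()].
#' @param frequency data.frame from [classifyFrequency()] (region ->
#'   frequency_class); regions absent from it are treated as rare.
#' @param minCells,maxCells clone size window (defaults 1 and 3).
#' @param vzMax dorsoventral extent of the ventricular zone in micrometers
#'   (progenitor-domain test; default 16, i.e. 0.4 x 40 um).
#' @param requireProgenitorDomain require all members in the progenitor
#'   domain (default TRUE).
#' @param isolationRadius isolation radius for frequent colors.
#' @return a filtered [CloneSet-class]; dropped clones and their reasons are
#'   available in `attr(, "dropped")`.
#' @export
filterTraceable <- function(cloneSet, frequency = NULL, minCells = 1L,
                            maxCells = 3L, vzMax = 16,
                            requireProgenitorDomain = TRUE,
                            isolationRadius = 2 * cloneSet@dContact) {
  cl <- cloneSet@clones
  cells <- cloneSet@cells
  if (nrow(cl) == 0L) return(cloneSet)
  freqClass <- rep("rare", nrow(cl))
  if (!is.null(frequency)) {
    m <- match(cl$region_index, frequency$region)
    freqClass[!is.na(m)] <- frequency$frequency_class[m[!is.na(m)]]
  }
  reason <- rep(NA_character_, nrow(cl))
  sizeOk <- cl$n_cells >= minCells & cl$n_cells <= maxCells
  reason[!sizeOk] <- "size"
  if (requireProgenitorDomain) {
    prog <- vapply(cl$clone_id, function(id) {
      mem <- cells[!is.na(cells$clone_id) & cells$clone_id == id, ,
                   drop = FALSE]
      apical <- if ("apical_contact" %in% names(mem))
        isTRUE_vec(mem$apical_contact) else rep(FALSE, nrow(mem))
      all(apical | mem$z_um <= vzMax + 1e-9)
    }, logical(1))
    reason[is.na(reason) & !prog] <- "outside_progenitor_domain"
  }
  isFrequent <- freqClass == "frequent"
  if (any(isFrequent)) {
    for (i in which(isFrequent)) {
      others <- which(cl$region_index == cl$region_index[i] &
                        cl$boundary_id == cl$boundary_id[i] &
                        seq_len(nrow(cl)) != i)
      if (length(others)) {
        d <- sqrt((cl$ml_centroid[others] - cl$ml_centroid[i])^2 +
                    (cl$dv_centroid[others] - cl$dv_centroid[i])^2)
        if (any(d <= isolationRadius))
          reason[i] <- "frequent_not_isolated"
      }
    }
  }
  keep <- is.na(reason)
  dropped <- data.frame(clone_id = cl$clone_id[!keep],
                        reason = reason[!keep])
  cellsOut <- cells
  cellsOut$clone_id[!cellsOut$clone_id %in% cl$clone_id[keep]] <- NA_character_
  out <- new("CloneSet", cells = cellsOut,
             clones = cl[keep, , drop = FALSE], dContact = cloneSet@dContact)
  attr(out, "dropped") <- dropped
  out
}

#' Link clones between two timepoints
#'
#' Matches clones of the same boundary and color identity across two
#' timepoints by greedy nearest-centroid (mediolateral/dorsoventral)
#' assignment, so the same clone keeps one identifier across the experiment.
#' A match whose two best candidates are equidistant within `tol` is flagged
#' ambiguous and left unassigned rather than guessed.
#'
#' @param cloneSet1,cloneSet2 [CloneSet-class] objects from the two
#'   timepoints (same boundaries).
#' @param tol distance tolerance (micrometers) under which two candidate
#'   matches count as ambiguous.
#' @return data.frame with `clone_t1`, `clone_t2` (NA when unmatched),
#'   `distance`, and `flag` ("ok", "ambiguous", "unmatched").
#' @export
linkClones <- function(cloneSet1, cloneSet2, tol = 1e-6) {
  c1 <- cloneSet1@clones; c2 <- cloneSet2@clones
  out <- data.frame(clone_t1 = c1$clone_id, clone_t2 = NA_character_,
                    distance = NA_real_, flag = "unmatched")
  taken <- character()
  ## candidate pairs sorted by distance; greedy one-to-one
  cand <- NULL
  for (i in seq_len(nrow(c1))) {
    j <- which(c2$boundary_id == c1$boundary_id[i] &
                 c2$region_index == c1$region_index[i])
    if (!length(j)) next
    d <- sqrt((c2$ml_centroid[j] - c1$ml_centroid[i])^2 +
                (c2$dv_centroid[j] - c1$dv_centroid[i])^2)
    cand <- rbind(cand, data.frame(i = i, j = j, d = d))
  }
  if (!is.null(cand)) {
    cand <- cand[order(cand$d), , drop = FALSE]
    usedI <- logical(nrow(c1)); usedJ <- logical(nrow(c2))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (usedI[i] || usedJ[j]) next
      ## ambiguity: another free candidate for i at (near) the same distance
      rival <- cand$i == i & !usedJ[cand$j] & cand$j != j &
        abs(cand$d - cand$d[r]) <= tol
      if (any(rival)) {
        out$flag[i] <- "ambiguous"
        usedI[i] <- TRUE
        next
      }
      out$clone_t2[i] <- c2$clone_id[j]
      out$distance[i] <- cand$d[r]
      out$flag[i] <- "ok"
      usedI[i] <- TRUE; usedJ[j] <- TRUE
    }
  }
  out
}

#' Rand-type agreement between two partitions
#'
#' Pair-counting agreement between a called clone partition and a reference
#' (e.g. generator ground truth): the Rand index and its chance-adjusted
#' version (ARI).
#'
#' @param labelsA,labelsB two label vectors over the same cells (NA pairs are
#'   dropped).
#' @return list with `rand`, `adjusted_rand`, and `n` (cells compared).
#' @examples
#' partitionAgreement(c(1, 1, 2, 2), c("a", "a", "b", "c"))
#' @export
partitionAgreement <- function(labelsA, labelsB) {
  keep <- !is.na(labelsA) & !is.na(labelsB)
  a <- as.character(labelsA[keep]); b <- as.character(labelsB[keep])
  n <- length(a)
  if (n < 2L) stop("need at least two jointly labelled cells")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumNij <- sum(comb2(tab))
  sumAi <- sum(comb2(rowSums(tab)))
  sumBj <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  rand <- (total + 2 * sumNij - sumAi - sumBj) / total
  expIdx <- sumAi * sumBj / total
  maxIdx <- (sumAi + sumBj) / 2
  ari <- if (abs(maxIdx - expIdx) < 1e-12) 1 else
    (sumNij - expIdx) / (maxIdx - expIdx)
  list(rand = rand, adjusted_rand = ari, n = n)
}
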