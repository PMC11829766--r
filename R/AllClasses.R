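#' SimulationConfig: parameters of the synthetic multicolor clone generator
#'
#' Holds every generative parameter of the synthetic-data module: transgene
#' recombination, lineage dynamics, tissue geometry, and measurement noise.
#' Construct with [simulationConfig()], which supplies defaults emulating a
#' hindbrain-boundary time-lapse clonal experiment (hourly frames from 32 to
#' 45 hpf).
#'
#' @slot nFounders number of labelled founder cells.
#' @slot copyNumberProbs named probability weights over transgene copy counts
#'   (names are the copy counts, >= 1).
#' @slot recombinationProbs named probabilities of the per-copy recombination
#'   outcome, over \code{farred} (unrecombined default), \code{yfp},
#'   \code{turquoise} and \code{tdtomato}.
#' @slot redManipulatedFraction fraction of founders whose tdTomato outcome
#'   carries the genetic manipulation label (zebrabow2.0-style designs).
#' @slot divisionProbPerFrame probability that a progenitor divides within one
#'   frame interval.
#' @slot modeProbs named probabilities (PP, PN, NN) of the division mode.
#' @slot modeProbsRed optional division-mode probabilities for manipulated
#'   (red) clones; length 0 means same as \code{modeProbs}.
#' @slot sisterDelayMean,sisterDelaySD mean and s.d. (hours) of the delay
#'   between sister-cell divisions, drawn from a normal truncated at 0.
#' @slot tStart,tEnd,frameInterval imaging window and cadence in hpf/hours.
#' @slot initialCellsProbs named probability weights over the number of cells
#'   a clone has at \code{tStart} (pre-window divisions are symmetric
#'   proliferative).
#' @slot vzFraction fraction of the dorsoventral tissue extent occupied by the
#'   ventricular zone (apical side).
#' @slot tissueHeight dorsoventral extent of the neural tube wall, micrometers.
#' @slot cloneSpacing center-to-center spacing of rendered clones, micrometers.
#' @slot channelNoiseSD s.d. of additive Gaussian noise on each normalized
#'   color channel of a measurement.
#' @slot halfFrameJitter logical; allow division times on half-frame steps.
#' @slot seed integer seed making every generator call reproducible.
#'
#' @seealso [simulationConfig()], [simulateDataset()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nFounders = "numeric",
    copyNumberProbs = "numeric",
    recombinationProbs = "numeric",
    redManipulatedFraction = "numeric",
    divisionProbPerFrame = "numeric",
    modeProbs = "numeric",
    modeProbsRed = "numeric",
    sisterDelayMean = "numeric",
    sisterDelaySD = "numeric",
    tStart = "numeric",
    tEnd = "numeric",
    frameInterval = "numeric",
    initialCellsProbs = "numeric",
    vzFraction = "numeric",
    tissueHeight = "numeric",
    cloneSpacing = "numeric",
    channelNoiseSD = "numeric",
    halfFrameJitter = "logical",
    seed = "numeric"
  )
)

.probTol <- 1e-9

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkProb <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      msg <<- c(msg, sprintf("%s must lie in [0, 1]", what))
  }
  if (length(object@nFounders) != 1L || object@nFounders < 1)
    msg <- c(msg, "nFounders must be a single count >= 1")
  if (length(object@copyNumberProbs) == 0L || sum(object@copyNumberProbs) <= 0)
    msg <- c(msg, "invalid config: copy-number distribution has zero weight")
  if (any(object@copyNumberProbs < 0))
    msg <- c(msg, "copyNumberProbs must be nonnegative")
  if (is.null(names(object@copyNumberProbs)) ||
      anyNA(suppressWarnings(as.integer(names(object@copyNumberProbs)))) ||
      any(as.integer(names(object@copyNumberProbs)) < 1))
    msg <- c(msg, "copyNumberProbs must be named by copy counts >= 1")
  if (!identical(sort(names(object@recombinationProbs)),
                 sort(c("farred", "yfp", "turquoise", "tdtomato"))))
    msg <- c(msg, "recombinationProbs needs names farred, yfp, turquoise, tdtomato")
  chkProb(object@recombinationProbs, "recombinationProbs")
  if (abs(sum(object@recombinationProbs) - 1) > 1e-6)
    msg <- c(msg, "recombinationProbs must sum to 1")
  if (!identical(names(object@modeProbs), c("PP", "PN", "NN")))
    msg <- c(msg, "modeProbs needs names PP, PN, NN")
  chkProb(object@modeProbs, "modeProbs")
  if (abs(sum(object@modeProbs) - 1) > .probTol)
    msg <- c(msg, "modeProbs (PP, PN, NN) must sum to 1 within 1e-9")
  if (length(object@modeProbsRed) > 0L) {
    if (!identical(names(object@modeProbsRed), c("PP", "PN", "NN")) ||
        abs(sum(object@modeProbsRed) - 1) > .probTol)
      msg <- c(msg, "modeProbsRed must be named PP, PN, NN and sum to 1")
  }
  chkProb(object@divisionProbPerFrame, "divisionProbPerFrame")
  chkProb(object@redManipulatedFraction, "redManipulatedFraction")
  chkProb(object@vzFraction, "vzFraction")
  if (object@sisterDelaySD < 0) msg <- c(msg, "sisterDelaySD must be >= 0")
  if (object@tEnd <= object@tStart) msg <- c(msg, "tEnd must exceed tStart")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@channelNoiseSD < 0) msg <- c(msg, "channelNoiseSD must be >= 0")
  if (object@tissueHeight <= 0) msg <- c(msg, "tissueHeight must be > 0")
  if (length(msg)) msg else TRUE
})

#' LineageTree: a founder-rooted tree of tracked cells
#'
#' Binary lineage tree of one clone: cell identities, parent links, birth and
#' division times (hpf), division modes and terminal fates. Produced by
#' [simulateClone()] or reconstructed from tracking XML by [readTracksXML()].
#'
#' @slot nodes data.frame with one row per cell: \code{id}, \code{parent}
#'   (\code{NA} for the founder), \code{birth}, \code{divTime} (\code{NA} for
#'   non-dividing cells), \code{mode} (mode of the division this cell
#'   performed) and \code{fate} ("P" or "N").
#' @slot founderId id of the root cell.
#' @slot cloneId label of the clone the tree belongs to.
#' @slot condition "control" or "manipulated" (red, zebrabow2.0-style).
#'
#' @exportClass LineageTree
setClass("LineageTree",
  representation(
    nodes = "data.frame",
    founderId = "character",
    cloneId = "character",
    condition = "character"
  )
)

setValidity("LineageTree", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("id", "parent", "birth", "divTime", "mode", "fate")
  if (!all(need %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated cell ids")
  if (sum(is.na(nd$parent)) != 1L)
    msg <- c(msg, "tree must have exactly one founder (parent NA)")
  kids <- table(nd$parent[!is.na(nd$parent)])
  if (length(kids) && any(kids != 2L))
    msg <- c(msg, "divisions must be binary (every dividing cell has 2 daughters)")
  ## acyclicity + non-decreasing times along root-to-leaf paths
  idx <- match(nd$parent, nd$id)
  if (any(!is.na(nd$parent) & is.na(idx)))
    msg <- c(msg, "parent refers to unknown cell id")
  if (!length(msg)) {
    for (i in seq_len(nrow(nd))) {
      seen <- integer(); j <- i
      while (!is.na(nd$parent[j])) {
        if (j %in% seen) return("cycle in parent links")
        seen <- c(seen, j)
        p <- idx[j]
        if (nd$birth[j] < nd$birth[p] - 1e-9)
          msg <- c(msg, "birth times must be non-decreasing along lineages")
        j <- p
      }
    }
    div <- !is.na(nd$divTime)
    if (any(nd$divTime[div] < nd$birth[div] - 1e-9))
      msg <- c(msg, "division before birth")
    if (any(div & nd$fate != "P"))
      msg <- c(msg, "only progenitors divide")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' CloneSet: clones called at one timepoint
#'
#' Result of [callClones()]: per-cell clone assignments and a per-clone summary
#' for a set of cells observed at a single timepoint.
#'
#' @slot cells input cell table with added \code{region_index} and
#'   \code{clone_id} columns (\code{NA} for unclassifiable cells).
#' @slot clones per-clone summary: \code{clone_id}, \code{embryo_id},
#'   \code{boundary_id}, \code{region_index}, \code{n_cells}, centroid
#'   coordinates.
#' @slot dContact contact distance (micrometers) used to call the clones.
#'
#' @exportClass CloneSet
setClass("CloneSet",
  representation(cells = "data.frame", clones = "data.frame",
                 dContact = "numeric")
)

setValidity("CloneSet", function(object) {
  msg <- character()
  if (!all(c("cell_id", "clone_id", "region_index") %in% names(object@cells)))
    msg <- c(msg, "cells must carry cell_id, clone_id, region_index")
  if (!all(c("clone_id", "n_cells", "region_index") %in% names(object@clones)))
    msg <- c(msg, "clones must carry clone_id, n_cells, region_index")
  assigned <- object@cells$clone_id[!is.na(object@cells$clone_id)]
  if (!all(assigned %in% object@clones$clone_id))
    msg <- c(msg, "cell clone_id not present in clone summary")
  if (length(msg)) msg else TRUE
})
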