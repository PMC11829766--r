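#' Number of cells in a lineage tree
#'
#' @param x a [LineageTree-class].
#' @param at optional time (hpf); if given, counts the cells alive at that
#'   time (a cell is alive from its birth frame until the frame before its
#'   division). Default counts terminal cells.
#' @return integer count.
#' @export
setGeneric("nCells", function(x, at = NULL) standardGeneric("nCells"))

#' Division events of a lineage tree
#'
#' @param x a [LineageTree-class].
#' @return data.frame with one row per division: \code{mother}, \code{time},
#'   \code{mode}, \code{daughter1}, \code{daughter2}, \code{cloneId},
#'   \code{condition}.
#' @export
setGeneric("divisionEvents", function(x) standardGeneric("divisionEvents"))

#' @title Accessors for lineage trees and clone sets
#' @description `treeNodes()` returns the per-cell node table of a tree;
#'   `founderId()` its root id; `cloneCondition()` the clone condition label;
#'   `cloneAssignments()` the per-cell table of a [CloneSet-class] (with
#'   `region_index` and `clone_id`); `cloneSummary()` its per-clone table.
#' @param x a [LineageTree-class] or [CloneSet-class].
#' @return a data.frame or character scalar, see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname accessors
#' @export
setGeneric("founderId", function(x) standardGeneric("founderId"))

#' @rdname accessors
#' @export
setGeneric("cloneCondition", function(x) standardGeneric("cloneCondition"))

#' @rdname accessors
#' @export
setGeneric("cloneAssignments", function(x) standardGeneric("cloneAssignments"))

#' @rdname accessors
#' @export
setGeneric("cloneSummary", function(x) standardGeneric("cloneSummary"))

#' Simulation parameters as a list
#'
#' @param x a [SimulationConfig-class].
#' @return named list of all generator parameters.
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
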