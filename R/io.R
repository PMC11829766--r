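## Readers and writers: tab-delimited cell tables and the spot/link tracking
## XML dialect produced by common Fiji tracking plugins.

.MANDATORY_CELL_COLS <- c("cell_id", "time_hpf", "x_um", "y_um", "z_um",
                          "r_mean", "g_mean", "b_mean")

#' Read an annotated cell table
#'
#' Reads a tab-delimited cell table with the documented header (`cell_id`,
#' `time_hpf`, `x_um`, `y_um`, `z_um`, `r_mean`, `g_mean`, `b_mean`, and
#' optionally `apical_contact`, `embryo_id`, `boundary_id`, `unrecombined`).
#' Missing mandatory columns raise a schema error naming the column; rows
#' with non-numeric coordinates/channels or negative channel values are
#' rejected with their line numbers. A missing `apical_contact` column is
#' tolerated with a warning (fate calls then fall back to position only).
#'
#' @param path file path.
#' @param axisMapping optional named character renaming coordinate columns to
#'   axis roles, e.g. `c(x_um = "ap", y_um = "ml", z_um = "dv")` recorded as
#'   an attribute.
#' @return data.frame of typed cell records.
#' @export
readCellTable <- function(path, axisMapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.MANDATORY_CELL_COLS, names(raw))
  if (length(missing))
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"apical_contact" %in% names(raw))
    warning("apical_contact column absent: fate calls will use position only")
  numCols <- c("time_hpf", "x_um", "y_um", "z_um", "r_mean", "g_mean",
               "b_mean")
  bad <- rep(FALSE, nrow(raw))
  for (cn in numCols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- bad | is.na(v) | !is.finite(v)
    raw[[cn]] <- v
  }
  bad <- bad | raw$r_mean < 0 | raw$g_mean < 0 | raw$b_mean < 0 |
    raw$time_hpf < 0
  if (any(bad))
    stop(sprintf("malformed row(s) at line(s) %s (header is line 1)",
                 paste(which(bad) + 1L, collapse = ", ")))
  if ("apical_contact" %in% names(raw))
    raw$apical_contact <- as.logical(raw$apical_contact)
  if ("unrecombined" %in% names(raw))
    raw$unrecombined <- as.logical(raw$unrecombined)
  if (!is.null(axisMapping)) attr(raw, "axisMapping") <- axisMapping
  raw
}

#' Write a cell table
#'
#' Tab-delimited, with the documented header; the inverse of
#' [readCellTable()].
#'
#' @param cells data.frame of cell records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read lineage trees from tracking XML
#'
#' Imports the spot/link subset of the XML dialect written by common Fiji
#' tracking plugins: `<Spot>` elements carrying `ID`, `FRAME`, `POSITION_X`,
#' `POSITION_Y`, `POSITION_Z`, and `<Edge>` elements carrying
#' `SPOT_SOURCE_ID`/`SPOT_TARGET_ID`. A chain of 1-to-1 linked spots is one
#' cell; a spot with two outgoing links is a division; more than two outgoing
#' links or cyclic links are structural errors.
#'
#' @param path XML file path.
#' @param t0 hpf of frame 0 (default 0).
#' @param frameInterval hours per frame (default 1).
#' @return list with `trees` (list of [LineageTree-class]) and `cells` (one
#'   row per spot: cell_id, time_hpf, x_um, y_um, z_um).
#' @export
readTracksXML <- function(path, t0 = 0, frameInterval = 1) {
  doc <- read_xml(path)
  spots <- xml_find_all(doc, ".//Spot")
  if (length(spots) == 0L) stop("no Spot elements found")
  sp <- data.frame(
    id = xml_attr(spots, "ID"),
    frame = as.numeric(xml_attr(spots, "FRAME")),
    x = as.numeric(xml_attr(spots, "POSITION_X")),
    y = as.numeric(xml_attr(spots, "POSITION_Y")),
    z = as.numeric(xml_attr(spots, "POSITION_Z")))
  if (anyNA(sp)) stop("malformed Spot element (missing attribute)")
  edges <- xml_find_all(doc, ".//Edge")
  ed <- data.frame(source = xml_attr(edges, "SPOT_SOURCE_ID"),
                   target = xml_attr(edges, "SPOT_TARGET_ID"))
  if (nrow(ed) && anyNA(ed)) stop("malformed Edge element")
  if (nrow(ed) && !all(c(ed$source, ed$target) %in% sp$id))
    stop("edge refers to unknown spot")
  nOut <- table(factor(ed$source, levels = sp$id))
  nIn <- table(factor(ed$target, levels = sp$id))
  if (any(nOut > 2L)) stop("structural error: spot with more than 2 outgoing links")
  if (any(nIn > 1L)) stop("structural error: spot with more than 1 incoming link")
  ## cycle check on the spot graph
  if (nrow(ed)) {
    g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                       vertices = data.frame(name = sp$id))
    if (!igraph::is_dag(g)) stop("structural error: cyclic links")
  }
  childOf <- split(ed$target, factor(ed$source, levels = sp$id))
  parentOf <- setNames(ed$source, ed$target)
  roots <- sp$id[!(sp$id %in% ed$target)]
  frameT <- function(fr) t0 + fr * frameInterval
  spIdx <- setNames(seq_len(nrow(sp)), sp$id)

  buildTree <- function(root, treeName) {
    nodes <- list()
    ## walk cell chains: a cell runs from its birth spot to a spot with 0 or
    ## 2 outgoing links
    cellCounter <- 0L
    spotCell <- character(0)  # spot id -> cell id
    queue <- list(list(spot = root, parent = NA_character_))
    while (length(queue)) {
      itm <- queue[[1]]; queue <- queue[-1]
      cellCounter <- cellCounter + 1L
      cid <- sprintf("c%03d", cellCounter)
      s <- itm$spot
      birth <- frameT(sp$frame[spIdx[[s]]])
      repeat {
        spotCell[s] <- cid
        kids <- childOf[[s]]
        if (is.null(kids) || length(kids) == 0L) {
          nodes[[cid]] <- list(id = cid, parent = itm$parent, birth = birth,
                               divTime = NA_real_, mode = NA_character_)
          break
        }
        if (length(kids) == 1L) { s <- kids; next }
        nodes[[cid]] <- list(id = cid, parent = itm$parent, birth = birth,
                             divTime = frameT(sp$frame[spIdx[[kids[1]]]]),
                             mode = NA_character_)
        queue <- c(queue, lapply(kids, function(k)
          list(spot = k, parent = cid)))
        break
      }
    }
    nd <- do.call(rbind, lapply(nodes, function(x)
      data.frame(id = x$id, parent = x$parent, birth = x$birth,
                 divTime = x$divTime, mode = x$mode, fate = "P")))
    nd$fate[!is.na(nd$divTime)] <- "P"
    rownames(nd) <- NULL
    cellsTab <- data.frame(
      cell_id = paste0(treeName, "_", spotCell[sp$id]),
      time_hpf = frameT(sp$frame), x_um = sp$x, y_um = sp$y, z_um = sp$z)
    cellsTab <- cellsTab[!is.na(spotCell[sp$id]), , drop = FALSE]
    list(tree = new("LineageTree", nodes = nd, founderId = nd$id[1],
                    cloneId = treeName, condition = "control"),
         cells = cellsTab)
  }

  res <- lapply(seq_along(roots), function(i)
    buildTree(roots[i], sprintf("track%03d", i)))
  cells <- do.call(rbind, lapply(res, `[[`, "cells"))
  ## keep only spots of each tree
  cells <- cells[grepl("_", cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  list(trees = lapply(res, `[[`, "tree"), cells = cells)
}

#' Write lineage trees as tracking XML
#'
#' Exports trees (plus optional per-frame positions) in the spot/link dialect
#' read by [readTracksXML()]; the round trip preserves tree topology and
#' division times.
#'
#' @param trees list of [LineageTree-class] objects.
#' @param path output path.
#' @param cells optional cell table supplying per-frame positions (matched as
#'   `<cloneId>_<nodeId>`); without it spots are written at the origin.
#' @param t0,frameInterval time mapping as in [readTracksXML()].
#' @return `path`, invisibly.
#' @export
writeTracksXML <- function(trees, path, cells = NULL, t0 = 0,
                           frameInterval = 1) {
  root <- xml_new_root("TrackModel")
  allSpots <- xml_add_child(root, "AllSpots")
  allTracks <- xml_add_child(root, "AllTracks")
  spotId <- 0L
  toFrame <- function(t) as.integer(round((t - t0) / frameInterval))
  for (tree in trees) {
    nd <- tree@nodes
    track <- xml_add_child(allTracks, "Track", name = tree@cloneId)
    lastT <- max(c(nd$birth, nd$divTime), na.rm = TRUE)
    ## per cell, one spot per frame from birth to division (or track end)
    cellSpots <- list()
    for (i in seq_len(nrow(nd))) {
      tEndCell <- if (is.na(nd$divTime[i])) lastT else
        nd$divTime[i] - frameInterval
      tt <- seq(nd$birth[i], max(nd$birth[i], tEndCell), by = frameInterval)
      ids <- integer(length(tt))
      for (k in seq_along(tt)) {
        spotId <- spotId + 1L
        pos <- c(0, 0, 0)
        if (!is.null(cells)) {
          cid <- paste0(tree@cloneId, "_", nd$id[i])
          hit <- cells[cells$cell_id == cid &
                         abs(cells$time_hpf - tt[k]) < 1e-9, , drop = FALSE]
          if (nrow(hit)) pos <- c(hit$x_um[1], hit$y_um[1], hit$z_um[1])
        }
        xml_add_child(allSpots, "Spot", ID = as.character(spotId),
                      FRAME = as.character(toFrame(tt[k])),
                      POSITION_X = format(pos[1]),
                      POSITION_Y = format(pos[2]),
                      POSITION_Z = format(pos[3]))
        ids[k] <- spotId
        if (k > 1L)
          xml_add_child(track, "Edge",
                        SPOT_SOURCE_ID = as.character(ids[k - 1L]),
                        SPOT_TARGET_ID = as.character(ids[k]))
      }
      cellSpots[[nd$id[i]]] <- ids
    }
    for (i in which(!is.na(nd$divTime))) {
      kids <- nd$id[!is.na(nd$parent) & nd$parent == nd$id[i]]
      mother <- cellSpots[[nd$id[i]]]
      for (k in kids)
        xml_add_child(track, "Edge",
                      SPOT_SOURCE_ID = as.character(mother[length(mother)]),
                      SPOT_TARGET_ID = as.character(cellSpots[[k]][1]))
    }
  }
  write_xml(root, path)
  invisible(path)
}
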