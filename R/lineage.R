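## Lineage-level statistics: fate calls, division-mode classification from
## tracks and from endpoint clone composition, sister-cell behavior, clonal
## growth and division-mode time-courses.

#' Assign progenitor/neuron fates from position and apical contact
#'
#' A cell is a progenitor (P) when its nucleus is close to the ventricle and
#' it shows an apical contact, and a neuron (N) when the nucleus is close to
#' the mantle zone without apical contact. An apical contact alone is
#' sufficient for P (radial glia keep their apical process while the nucleus
#' migrates). Conflicting evidence — ventricular-zone position without apical
#' contact — yields "unassigned". When the apical-contact flag is missing the
#' call falls back to position only (basis "position").
#'
#' @param cells cell table with `z_um` (dorsoventral position, 0 at the
#'   ventricle) and optionally `apical_contact`.
#' @param vzMax dorsoventral position of the VZ/MZ dividing line in
#'   micrometers.
#' @return data.frame with `cell_id` (if present), `fate` ("P", "N",
#'   "unassigned") and `basis` ("both", "apical_contact", "position").
#' @examples
#' assignFate(data.frame(z_um = c(5, 30), apical_contact = c(TRUE, FALSE)),
#'            vzMax = 16)
#' @export
assignFate <- function(cells, vzMax = 16) {
  z <- cells$z_um
  hasFlag <- "apical_contact" %in% names(cells) &&
    !all(is.na(cells$apical_contact))
  inVZ <- z < vzMax - 1e-9
  inMZ <- z > vzMax + 1e-9
  if (hasFlag) {
    ap <- cells$apical_contact
    fate <- ifelse(is.na(ap),
                   ifelse(inVZ, "P", ifelse(inMZ, "N", "unassigned")),
                   ifelse(ap, "P",
                          ifelse(inMZ, "N", "unassigned")))
    basis <- ifelse(is.na(ap), "position",
                    ifelse(ap & inVZ, "both",
                           ifelse(ap, "apical_contact", "position")))
  } else {
    fate <- ifelse(inVZ, "P", ifelse(inMZ, "N", "unassigned"))
    basis <- rep("position", length(z))
  }
  out <- data.frame(fate = fate, basis = basis)
  if ("cell_id" %in% names(cells)) out <- cbind(cell_id = cells$cell_id, out)
  out
}

#' Classify division modes from tracked daughter cells
#'
#' For every division in the tracked lineage trees, the mode is read from the
#' daughters' spatial configuration and fates: PN when the daughters are not
#' in close contact, one closer to the ventricle and the other to the mantle
#' zone; PP (or NN) when the daughters are in close contact at the same
#' dorsoventral level and both are fated P (or N). Fate is not ascribed to a
#' terminal daughter tracked for less than `minTrackedAfter` hours after the
#' division, in which case the division is "unassigned"; a daughter that
#' itself divides later is a progenitor by definition. Contradictory
#' configurations (contact but opposite fates, or separation without a VZ/MZ
#' split) are "unassigned" with the reason recorded.
#'
#' @param trees list of [LineageTree-class] objects (the track topology).
#' @param cells cell table giving per-frame positions of the tracked cells
#'   (cell ids `<cloneId>_<nodeId>` as produced by [renderCellTable()], or
#'   matching the tree node ids directly).
#' @param vzMax VZ/MZ dividing line (micrometers).
#' @param dContact contact distance (micrometers).
#' @param dvTol maximal dorsoventral offset still counting as "same DV
#'   level"; default half the contact distance.
#' @param minTrackedAfter hours a terminal daughter must remain tracked after
#'   the division for a fate call (default 3).
#' @param frameInterval imaging cadence in hours; daughters are evaluated at
#'   least one frame after the division (a newborn neuron may still hold its
#'   apical endfoot at the division frame itself).
#' @return data.frame with one row per division: identifiers, `time`, the
#'   called `mode` ("PP", "PN", "NN", "unassigned"), `true_mode` from the
#'   tree, and `reason` for unassigned calls.
#' @export
classifyDivisions <- function(trees, cells, vzMax = 16, dContact = 12,
                              dvTol = dContact / 2, minTrackedAfter = 3,
                              frameInterval = 1) {
  if (is(trees, "LineageTree")) trees <- list(trees)
  rows <- lapply(trees, function(tree)
    .classifyTreeDivisions(tree, cells, vzMax, dContact, dvTol,
                           minTrackedAfter, frameInterval))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cellTrack <- function(cells, cid) {
  tr <- cells[cells$cell_id == cid, , drop = FALSE]
  tr[order(tr$time_hpf), , drop = FALSE]
}

.classifyTreeDivisions <- function(tree, cells, vzMax, dContact, dvTol,
                                   minTrackedAfter, frameInterval = 1) {
  ev <- divisionEvents(tree)
  if (nrow(ev) == 0L) {
    return(data.frame(cloneId = character(), condition = character(),
                      mother = character(), time = numeric(),
                      mode = character(), true_mode = character(),
                      reason = character()))
  }
  nd <- tree@nodes
  prefix <- paste0(tree@cloneId, "_")
  useId <- function(node)
    if (any(cells$cell_id == paste0(prefix, node))) paste0(prefix, node) else node
  mode <- character(nrow(ev)); reason <- rep(NA_character_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    t <- ev$time[i]
    ds <- c(ev$daughter1[i], ev$daughter2[i])
    di <- match(ds, nd$id)
    isDividing <- !is.na(nd$divTime[di])
    tracks <- lapply(ds, function(d) .cellTrack(cells, useId(d)))
    lastObs <- vapply(tracks, function(tr)
      if (nrow(tr)) max(tr$time_hpf) else -Inf, numeric(1))
    ## 3-h rule: terminal daughters must be followed long enough
    short <- !isDividing & (lastObs - t < minTrackedAfter - 1e-9)
    if (any(short)) {
      mode[i] <- "unassigned"; reason[i] <- "tracked_under_min_hours"
      next
    }
    if (any(vapply(tracks, nrow, integer(1)) == 0L)) {
      mode[i] <- "unassigned"; reason[i] <- "daughter_not_in_table"
      next
    }
    ## evaluation frame: minTrackedAfter after the division (at least one
    ## frame), clipped to the frames at which each daughter is observed
    horizon <- t + max(minTrackedAfter, frameInterval)
    evalAt <- function(tr) {
      tt <- tr$time_hpf[tr$time_hpf <= horizon + 1e-9]
      if (!length(tt)) tr$time_hpf[1] else max(tt)
    }
    ## each daughter is judged at its own evaluation frame (the latest frame
    ## up to the horizon at which it is observed, skipping the division frame
    ## whenever a later one exists); geometry uses those positions
    pos <- lapply(tracks, function(tr) {
      tt <- tr$time_hpf[tr$time_hpf <= horizon + 1e-9 & tr$time_hpf > t + 1e-9]
      if (!length(tt)) tr[tr$time_hpf == evalAt(tr), ][1, ] else
        tr[tr$time_hpf == max(tt), ][1, ]
    })
    dd <- sqrt(sum((c(pos[[1]]$x_um, pos[[1]]$y_um, pos[[1]]$z_um) -
                      c(pos[[2]]$x_um, pos[[2]]$y_um, pos[[2]]$z_um))^2))
    dvDiff <- abs(pos[[1]]$z_um - pos[[2]]$z_um)
    fates <- vapply(seq_along(ds), function(k) {
      if (isDividing[k]) "P" else assignFate(pos[[k]], vzMax = vzMax)$fate
    }, character(1))
    inContact <- dd <= dContact + 1e-9
    if (!inContact) {
      zz <- c(pos[[1]]$z_um, pos[[2]]$z_um)
      splitVZMZ <- (min(zz) < vzMax) && (max(zz) > vzMax)
      if (splitVZMZ && setequal(fates, c("P", "N"))) {
        mode[i] <- "PN"
      } else {
        mode[i] <- "unassigned"; reason[i] <- "separated_without_vz_mz_split"
      }
    } else if (dvDiff <= dvTol + 1e-9 && all(fates == "P")) {
      mode[i] <- "PP"
    } else if (dvDiff <= dvTol + 1e-9 && all(fates == "N")) {
      mode[i] <- "NN"
    } else {
      mode[i] <- "unassigned"; reason[i] <- "contradictory_configuration"
    }
  }
  data.frame(cloneId = ev$cloneId, condition = ev$condition,
             mother = ev$mother, time = ev$time, mode = mode,
             true_mode = ev$mode, reason = reason)
}

#' Proliferative capacity and endpoint fate composition
#'
#' Over a tracking window, a progenitor counts as dividing iff it undergoes
#' at least one division within the window; the endpoint fate composition is
#' taken over all tracked cells present at the window end. Alternatively,
#' pass printed counts directly via `counts` to turn a dividing/total tally
#' into the same summary.
#'
#' @param trees list of [LineageTree-class] objects.
#' @param window tracking window `c(t0, tf)` in hpf; defaults to the full
#'   range of the trees.
#' @param cohort "at_start" (default): progenitors alive at the window start;
#'   "all": every progenitor observed during the window.
#' @param counts optional named vector `c(dividing = , total = )`; when given,
#'   trees are ignored.
#' @return list with `n_progenitors`, `n_dividing`, `dividing_fraction`,
#'   `nondividing_fraction`, and (tree input only) `endpoint_fates`
#'   (P/N counts and fractions at `tf`).
#' @examples
#' proliferativeCapacity(counts = c(dividing = 48, total = 90))
#' @export
proliferativeCapacity <- function(trees = NULL, window = NULL,
                                  cohort = c("at_start", "all"),
                                  counts = NULL) {
  if (!is.null(counts)) {
    stopifnot(all(c("dividing", "total") %in% names(counts)),
              counts["total"] > 0)
    f <- unname(counts["dividing"] / counts["total"])
    return(list(n_progenitors = unname(counts["total"]),
                n_dividing = unname(counts["dividing"]),
                dividing_fraction = f, nondividing_fraction = 1 - f))
  }
  cohort <- match.arg(cohort)
  if (length(trees) == 0L) stop("empty input: no trees and no counts")
  if (is.null(window)) {
    allT <- unlist(lapply(trees, function(tr) tr@nodes$birth))
    window <- c(min(allT), max(unlist(lapply(trees, function(tr)
      c(tr@nodes$birth, tr@nodes$divTime)), use.names = FALSE), na.rm = TRUE))
  }
  t0 <- window[1]; tf <- window[2]
  nProg <- 0L; nDiv <- 0L; nP <- 0L; nN <- 0L
  for (tree in trees) {
    nd <- tree@nodes
    inCohort <- if (cohort == "at_start") .aliveAt(nd, t0) else
      nd$fate == "P" & nd$birth <= tf + 1e-9
    prog <- inCohort & nd$fate == "P"
    nProg <- nProg + sum(prog)
    nDiv <- nDiv + sum(prog & !is.na(nd$divTime) &
                         nd$divTime >= t0 - 1e-9 & nd$divTime <= tf + 1e-9)
    end <- .aliveAt(nd, tf)
    nP <- nP + sum(end & nd$fate == "P")
    nN <- nN + sum(end & nd$fate == "N")
  }
  if (nProg == 0L) stop("no progenitors in the window")
  list(n_progenitors = nProg, n_dividing = nDiv,
       dividing_fraction = nDiv / nProg,
       nondividing_fraction = 1 - nDiv / nProg,
       endpoint_fates = list(P = nP, N = nN,
                             P_fraction = nP / (nP + nN),
                             N_fraction = nN / (nP + nN)))
}

#' Infer division-mode counts from endpoint clone composition
#'
#' Two-timepoint (functional) designs have no continuous tracks, so division
#' modes are inferred from what a clone is made of: every PP division adds a
#' progenitor, so the PP count equals the number of progenitors (minus the
#' `founders` the clone started from, when known); every PN division adds a
#' neuron, so the PN count starts from the number of neurons. NN divisions
#' are only considered in clones with an even number of neurons; with
#' `nnRule = "paired"` (default) one NN is counted per mutually-nearest pair
#' of neurons in contact at the same dorsoventral level, and each counted
#' pair removes two neurons from the PN tally (and, when founders are
#' subtracted, restores the progenitor consumed by the NN division). The
#' `nnRule = "even_all"` alternative attributes all neurons of even-neuron
#' clones to NN divisions.
#'
#' @param cloneCells cell table of one clone at one timepoint, with `z_um`,
#'   positions and (optionally) `apical_contact`; fates are called with
#'   [assignFate()] unless a `fate` column is already present.
#' @param founders number of progenitors the clone started from (0 = the
#'   literal composition rule, which does not discount founders).
#' @param vzMax,dContact,dvTol geometry as in [classifyDivisions()].
#' @param nnRule "paired" or "even_all" (see above).
#' @return list with `counts` (named PP/PN/NN), `percentages`, `n_P`, `n_N`.
#' @examples
#' # three progenitors, no neuron: all divisions symmetric proliferative
#' cl <- data.frame(z_um = c(5, 5, 5), y_um = c(0, 5, 10), x_um = 0,
#'                  apical_contact = TRUE)
#' inferDivisionModesEndpoint(cl)
#' @export
inferDivisionModesEndpoint <- function(cloneCells, founders = 0L, vzMax = 16,
                                       dContact = 12, dvTol = dContact / 2,
                                       nnRule = c("paired", "even_all")) {
  nnRule <- match.arg(nnRule)
  if (nrow(cloneCells) == 0L) stop("empty clone")
  fate <- if ("fate" %in% names(cloneCells)) cloneCells$fate else
    assignFate(cloneCells, vzMax = vzMax)$fate
  nP <- sum(fate == "P"); nN <- sum(fate == "N")
  if (nP + nN == 0L) stop("clone has no fated cells")
  nn <- 0L
  if (nN >= 2L && nN %% 2L == 0L) {
    if (nnRule == "even_all") {
      nn <- nN %/% 2L
    } else {
      neurons <- cloneCells[fate == "N", , drop = FALSE]
      nn <- .countMutualNearestPairs(neurons, dContact, dvTol)
    }
  }
  pp <- nP - founders + (if (founders > 0L) nn else 0L)
  pp <- max(0L, pp)
  pn <- if (nnRule == "even_all" && nn > 0L) 0L else nN - 2L * nn
  pn <- max(0L, pn)
  counts <- c(PP = pp, PN = pn, NN = nn)
  total <- sum(counts)
  list(counts = counts,
       percentages = if (total > 0) 100 * counts / total else
         c(PP = NA_real_, PN = NA_real_, NN = NA_real_),
       n_P = nP, n_N = nN)
}

## mutually-nearest neuron pairs in contact at the same DV level
.countMutualNearestPairs <- function(neurons, dContact, dvTol) {
  n <- nrow(neurons)
  if (n < 2L) return(0L)
  m <- as.matrix(neurons[, c("x_um", "y_um", "z_um")])
  d <- as.matrix(dist(m))
  diag(d) <- Inf
  nearest <- apply(d, 1, which.min)
  pairs <- 0L
  used <- logical(n)
  for (i in seq_len(n)) {
    j <- nearest[i]
    if (used[i] || used[j]) next
    if (nearest[j] == i && i < j &&
        d[i, j] <= dContact + 1e-9 &&
        abs(m[i, 3] - m[j, 3]) <= dvTol + 1e-9) {
      pairs <- pairs + 1L
      used[i] <- TRUE; used[j] <- TRUE
    }
  }
  pairs
}

#' Division-mode shares from mode counts
#'
#' Converts division-mode tallies into percentage shares.
#'
#' @param counts named vector of counts (typically PP, PN, NN).
#' @param digits rounding of the returned percentages; `NULL` keeps full
#'   precision.
#' @return named numeric vector of percentages summing to 100.
#' @examples
#' divisionModeShares(c(PP = 19, PN = 28, NN = 1))
#' @export
divisionModeShares <- function(counts, digits = 0) {
  total <- sum(counts)
  if (total <= 0) stop("no divisions counted")
  shares <- 100 * counts / total
  if (!is.null(digits)) shares <- round(shares, digits)
  shares
}

#' Sister-cell behavior of one two-cell clone
#'
#' For a clone consisting of two sister cells at the reference timepoint,
#' reports whether the sisters had the same proliferative behavior (both
#' divided or neither did), whether their divisions were synchronous (within
#' one frame interval) or asynchronous, the absolute delay between the two
#' divisions, and whether they used the same division mode.
#'
#' @param tree a [LineageTree-class]; the clone must have exactly two cells
#'   at `t0`.
#' @param t0 reference timepoint (hpf).
#' @param frameInterval frame interval (hours) defining synchrony.
#' @return list with `concordance` ("same"/"different"), `synchrony`
#'   ("synchronous"/"asynchronous"/NA), `delay_hours` (NA unless both
#'   divide), `modes` and `mode_concordance`.
#' @export
sisterAnalysis <- function(tree, t0, frameInterval = 1) {
  nd <- tree@nodes
  alive <- which(.aliveAt(nd, t0))
  if (length(alive) != 2L)
    stop("sister analysis is restricted to two-cell clones at t0")
  tDiv <- nd$divTime[alive]
  modes <- nd$mode[alive]
  divides <- !is.na(tDiv)
  concordance <- if (sum(divides) %in% c(0L, 2L)) "same" else "different"
  if (all(divides)) {
    delay <- abs(diff(tDiv))
    synchrony <- if (delay <= frameInterval + 1e-9) "synchronous" else
      "asynchronous"
    modeConc <- if (modes[1] == modes[2]) "same" else "different"
  } else {
    delay <- NA_real_; synchrony <- NA_character_; modeConc <- NA_character_
  }
  list(concordance = concordance, synchrony = synchrony,
       delay_hours = delay, modes = modes, mode_concordance = modeConc)
}

#' Cohort-level sister-cell statistics
#'
#' Applies [sisterAnalysis()] to every two-cell clone of a cohort and
#' aggregates: proliferative concordance, synchrony among clones where both
#' sisters divide, the distribution of inter-sister delays, and division-mode
#' concordance.
#'
#' @param trees list of [LineageTree-class] objects.
#' @param t0 reference timepoint (hpf).
#' @param frameInterval frame interval (hours).
#' @return list with counts and fractions plus `delays` (vector),
#'   `delay_mean`, `delay_sd`.
#' @export
sisterStatistics <- function(trees, t0, frameInterval = 1) {
  res <- list()
  for (tree in trees) {
    if (nCells(tree, at = t0) != 2L) next
    res[[length(res) + 1L]] <- sisterAnalysis(tree, t0, frameInterval)
  }
  if (!length(res))
    return(list(n_clones = 0L))
  conc <- vapply(res, `[[`, character(1), "concordance")
  sync <- vapply(res, function(x)
    if (is.na(x$synchrony)) NA_character_ else x$synchrony, character(1))
  delays <- unlist(lapply(res, `[[`, "delay_hours"))
  delays <- delays[!is.na(delays)]
  mc <- vapply(res, function(x)
    if (is.na(x$mode_concordance)) NA_character_ else x$mode_concordance,
    character(1))
  list(n_clones = length(res),
       concordance_same_fraction = mean(conc == "same"),
       n_both_dividing = sum(!is.na(sync)),
       synchronous_fraction = if (any(!is.na(sync)))
         mean(sync[!is.na(sync)] == "synchronous") else NA_real_,
       delays = delays,
       delay_mean = if (length(delays)) mean(delays) else NA_real_,
       delay_sd = if (length(delays) > 1L) sd(delays) else NA_real_,
       mode_same_fraction = if (any(!is.na(mc)))
         mean(mc[!is.na(mc)] == "same") else NA_real_)
}

#' Clonal growth across timepoints
#'
#' Number of cells per clone at each requested timepoint, with the cohort
#' mean and standard deviation. Cell counts are monotone non-decreasing over
#' time in the absence of track loss; violations are reported.
#'
#' @param trees list of [LineageTree-class] objects.
#' @param atTimes timepoints (hpf).
#' @return list with `per_clone` (clones x timepoints matrix), `summary`
#'   (data.frame time/mean/sd/n) and `violations` (clone ids whose counts
#'   decreased).
#' @export
cloneGrowth <- function(trees, atTimes) {
  counts <- vapply(trees, function(tree)
    vapply(atTimes, function(t) nCells(tree, at = t), numeric(1)),
    numeric(length(atTimes)))
  counts <- matrix(counts, nrow = length(atTimes))
  rownames(counts) <- as.character(atTimes)
  colnames(counts) <- vapply(trees, function(tr) tr@cloneId, character(1))
  mono <- apply(counts, 2, function(x) all(diff(x) >= 0))
  list(per_clone = t(counts),
       summary = data.frame(time_hpf = atTimes,
                            mean = rowMeans(counts),
                            sd = apply(counts, 1, sd),
                            n = ncol(counts)),
       violations = colnames(counts)[!mono])
}

#' Division-mode fractions over time
#'
#' Bins assigned divisions into time bins and reports the PP and PN fraction
#' per bin together with the least-squares slope and R-squared of each
#' fraction against time — flat profiles indicate that the division mode is
#' not temporally patterned.
#'
#' @param divisions data.frame from [classifyDivisions()] (columns `time`,
#'   `mode`), or any data.frame with those columns.
#' @param binWidth bin width in hours (default 1).
#' @return list with `bins` (per-bin counts and fractions), `regression`
#'   (per-mode slope, intercept, r_squared, p_value) and `sparse` flag (fewer
#'   than 2 usable bins; regression is then NA).
#' @export
modeTimecourse <- function(divisions, binWidth = 1) {
  div <- divisions[divisions$mode %in% c("PP", "PN", "NN"), , drop = FALSE]
  if (nrow(div) == 0L) stop("no assigned divisions")
  bin <- floor(div$time / binWidth) * binWidth
  tab <- table(bin, factor(div$mode, levels = c("PP", "PN", "NN")))
  binMid <- as.numeric(rownames(tab)) + binWidth / 2
  total <- rowSums(tab)
  bins <- data.frame(bin_start = as.numeric(rownames(tab)),
                     bin_mid = binMid, n = as.integer(total),
                     PP_fraction = tab[, "PP"] / total,
                     PN_fraction = tab[, "PN"] / total,
                     NN_fraction = tab[, "NN"] / total)
  rownames(bins) <- NULL
  sparse <- nrow(bins) < 2L
  reg <- do.call(rbind, lapply(c("PP", "PN"), function(m) {
    y <- bins[[paste0(m, "_fraction")]]
    if (sparse || length(unique(y)) == 1L) {
      slope <- if (sparse) NA_real_ else 0
      return(data.frame(mode = m, slope = slope, intercept = y[1],
                        r_squared = if (sparse) NA_real_ else 0,
                        p_value = NA_real_))
    }
    fit <- lm(y ~ bins$bin_mid)
    sm <- summary(fit)
    data.frame(mode = m, slope = coef(fit)[2], intercept = coef(fit)[1],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4])
  }))
  rownames(reg) <- NULL
  list(bins = bins, regression = reg, sparse = sparse)
}
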