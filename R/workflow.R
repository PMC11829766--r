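## Pipeline configuration and the two end-to-end workflows: time-lapse
## clonal tracking and the two-timepoint functional (red vs non-red)
## comparison.

#' Pipeline configuration
#'
#' Collects the analysis constants in one validated list: color thresholds,
#' contact distance, dorsoventral tolerance, ventricular-zone geometry,
#' imaging cadence, the fate-exclusion window, endpoint-rule flags and the
#' seed. Unknown keys are rejected.
#'
#' @param thresholds a [colorThresholds()] list.
#' @param dContact contact distance, micrometers.
#' @param dvTol "same DV level" tolerance, micrometers.
#' @param vzFraction ventricular-zone fraction of the tissue height.
#' @param tissueHeight dorsoventral tissue extent, micrometers.
#' @param frameInterval hours between frames.
#' @param fateExclusionHours minimum tracked time after division for a fate
#'   call (default 3).
#' @param endpointFounders founders discounted by the endpoint composition
#'   rule (0 = literal rule).
#' @param nnRule endpoint NN attribution: "paired" or "even_all".
#' @param seed integer seed.
#' @param ... rejected; guards against misspelled keys.
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(thresholds = colorThresholds(), dContact = 12,
                           dvTol = dContact / 2, vzFraction = 0.4,
                           tissueHeight = 40, frameInterval = 1,
                           fateExclusionHours = 3, endpointFounders = 0L,
                           nnRule = "paired", seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  stopifnot(dContact > 0, dvTol >= 0, vzFraction >= 0, vzFraction <= 1,
            tissueHeight > 0, frameInterval > 0, fateExclusionHours >= 0,
            nnRule %in% c("paired", "even_all"))
  structure(list(thresholds = thresholds, dContact = dContact, dvTol = dvTol,
                 vzFraction = vzFraction, tissueHeight = tissueHeight,
                 frameInterval = frameInterval,
                 fateExclusionHours = fateExclusionHours,
                 endpointFounders = endpointFounders, nnRule = nnRule,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

.vzMax <- function(pc) pc$vzFraction * pc$tissueHeight

#' Run an end-to-end clonal-analysis workflow
#'
#' Two workflows are provided. `"timelapse"`: clones are called and filtered
#' at the first timepoint, divisions are classified from the tracks, and the
#' lineage statistics (proliferative capacity, endpoint fates, clonal growth,
#' sister-cell behavior, division-mode time-course) are computed.
#' `"functional"`: clones are called at both timepoints, classified as red or
#' non-red, linked across timepoints, their endpoint composition converted to
#' division-mode estimates, and red vs non-red compared with the
#' normality-gated two-group test.
#'
#' @param dataset list as returned by [simulateDataset()] (`cells`, `trees`,
#'   `truth`), or a list with `cells` only for the functional workflow on
#'   imported data.
#' @param workflow "timelapse" or "functional".
#' @param config a [pipelineConfig()].
#' @param timepoints length-2 timepoints (hpf) for the functional workflow;
#'   defaults to the first and last rendered time.
#' @return named list of workflow products (tables and summaries).
#' @export
runWorkflow <- function(dataset, workflow = c("timelapse", "functional"),
                        config = pipelineConfig(), timepoints = NULL) {
  workflow <- match.arg(workflow)
  cells <- dataset$cells
  times <- sort(unique(cells$time_hpf))
  vz <- .vzMax(config)
  if (workflow == "timelapse") {
    t0 <- times[1]; tf <- times[length(times)]
    cs0 <- callClones(cells[cells$time_hpf == t0, ], config$dContact)
    freq <- classifyFrequency(
      cloneAssignments(cs0)$region_index[!is.na(cloneAssignments(cs0)$region_index)],
      config$thresholds)
    traceable <- filterTraceable(cs0, freq, vzMax = vz)
    trees <- dataset$trees
    div <- classifyDivisions(trees, cells, vzMax = vz,
                             dContact = config$dContact, dvTol = config$dvTol,
                             minTrackedAfter = config$fateExclusionHours)
    divIn <- div[div$time >= t0, , drop = FALSE]
    assigned <- divIn[divIn$mode %in% c("PP", "PN", "NN"), , drop = FALSE]
    prolif <- proliferativeCapacity(trees, window = c(t0, tf))
    growth <- cloneGrowth(trees, atTimes = c(t0, tf))
    sisters <- sisterStatistics(trees, t0, config$frameInterval)
    tc <- if (nrow(assigned) >= 2L) modeTimecourse(assigned) else NULL
    list(workflow = "timelapse", t0 = t0, tf = tf,
         clones_t0 = cs0, frequency = freq, traceable = traceable,
         divisions = div,
         mode_counts = table(factor(assigned$mode,
                                    levels = c("PP", "PN", "NN"))),
         mode_shares = if (nrow(assigned))
           divisionModeShares(table(factor(assigned$mode,
                                           levels = c("PP", "PN", "NN"))),
                              digits = NULL) else NULL,
         proliferation = prolif, growth = growth, sisters = sisters,
         timecourse = tc)
  } else {
    if (is.null(timepoints)) timepoints <- c(times[1], times[length(times)])
    sub1 <- cells[cells$time_hpf == timepoints[1], ]
    sub2 <- cells[cells$time_hpf == timepoints[2], ]
    cs1 <- callClones(sub1, config$dContact)
    cs2 <- callClones(sub2, config$dContact)
    links <- linkClones(cs1, cs2)
    perClone <- .functionalCloneTable(cs2, config, vz)
    cmp <- NULL
    if (length(unique(perClone$condition[perClone$condition != "excluded"])) == 2L) {
      red <- perClone[perClone$condition == "red", ]
      nonred <- perClone[perClone$condition == "nonred", ]
      if (nrow(red) >= 2L && nrow(nonred) >= 2L)
        cmp <- list(
          neuron_percent = suppressWarnings(
            compareTwoGroups(nonred$neuron_percent, red$neuron_percent,
                             labels = c("nonred", "red"))),
          progenitor_percent = suppressWarnings(
            compareTwoGroups(nonred$progenitor_percent, red$progenitor_percent,
                             labels = c("nonred", "red"))),
          clone_size = suppressWarnings(
            compareTwoGroups(nonred$n_cells, red$n_cells,
                             labels = c("nonred", "red"))))
    }
    list(workflow = "functional", timepoints = timepoints,
         clones_t1 = cs1, clones_t2 = cs2, links = links,
         per_clone = perClone, comparisons = cmp)
  }
}

## per-clone condition, fate composition and endpoint mode estimates at one
## timepoint
.functionalCloneTable <- function(cloneSet, config, vzMax) {
  cells <- cloneAssignments(cloneSet)
  cl <- cloneSummary(cloneSet)
  rows <- lapply(cl$clone_id, function(id) {
    mem <- cells[!is.na(cells$clone_id) & cells$clone_id == id, , drop = FALSE]
    cond <- classifyRedCondition(mem, config$thresholds)
    fates <- assignFate(mem, vzMax = vzMax)$fate
    nP <- sum(fates == "P"); nN <- sum(fates == "N")
    modes <- tryCatch(
      inferDivisionModesEndpoint(mem, founders = config$endpointFounders,
                                 vzMax = vzMax, dContact = config$dContact,
                                 dvTol = config$dvTol, nnRule = config$nnRule),
      error = function(e) NULL)
    data.frame(clone_id = id, condition = cond$condition,
               red_fraction = cond$red_fraction,
               n_cells = nrow(mem), n_P = nP, n_N = nN,
               progenitor_percent = if (nP + nN > 0) 100 * nP / (nP + nN)
                 else NA_real_,
               neuron_percent = if (nP + nN > 0) 100 * nN / (nP + nN)
                 else NA_real_,
               PP_percent = if (!is.null(modes)) modes$percentages["PP"]
                 else NA_real_,
               PN_percent = if (!is.null(modes)) modes$percentages["PN"]
                 else NA_real_,
               NN_percent = if (!is.null(modes)) modes$percentages["NN"]
                 else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Command-line dispatcher
#'
#' Backs the `clonebow` command-line script (see
#' `system.file("scripts", "clonebow.R", package = "cloneBow")`). Subcommands:
#' `simulate`, `classify-colors`, `call-clones`, `lineage`, `endpoint`,
#' `compare`, `run-all`. Every run writes its outputs plus a JSON run log
#' (seed, configuration hash, package version) into `--out`.
#'
#' @param args character vector of command-line arguments (subcommand first).
#' @return exit status (0 on success), invisibly; called for its side
#'   effects.
#' @export
cloneBowCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: clonebow <subcommand> [--seed S] [--out DIR] [options]",
    "  simulate        --seed S --out DIR [--founders N] [--noise SD]",
    "  classify-colors --cells FILE --out DIR",
    "  call-clones     --cells FILE --out DIR [--time T] [--dcontact D]",
    "  lineage         --seed S --out DIR",
    "  endpoint        --cells FILE --out DIR --time T",
    "  compare         --cells FILE --out DIR (red vs non-red at --time T)",
    "  run-all         --seed S --out DIR --workflow timelapse|functional",
    sep = "\n")
  fail <- function(msg) {
    message(msg); message(usage); return(invisible(1L))
  }
  if (length(args) < 1L) return(fail("error: missing subcommand"))
  sub <- args[1]
  opts <- .parseFlags(args[-1])
  if (!is.null(opts$error)) return(fail(opts$error))
  known <- c("simulate", "classify-colors", "call-clones", "lineage",
             "endpoint", "compare", "run-all")
  if (!sub %in% known) return(fail(sprintf("error: unknown subcommand '%s'", sub)))
  outDir <- opts$out %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(opts$seed %||% "1")
  status <- tryCatch({
    switch(sub,
      "simulate" = {
        cfg <- simulationConfig(
          nFounders = as.integer(opts$founders %||% "50"),
          channelNoiseSD = as.numeric(opts$noise %||% "0.02"),
          seed = seed)
        ds <- simulateDataset(cfg)
        writeCellTable(ds$cells, file.path(outDir, "cells.tsv"))
        writeCellTable(ds$truth, file.path(outDir, "truth.tsv"))
        .writeRunLog(outDir, sub, seed, simParams(cfg))
        0L
      },
      "classify-colors" = {
        cells <- readCellTable(.required(opts, "cells"))
        if (nrow(cells) == 0L) stop("schema error: empty cell table")
        tern <- normalizeRGB(cells$r_mean, cells$g_mean, cells$b_mean,
                             onZero = "na")
        cells$region_index <- assignColorIdentity(tern)
        freq <- classifyFrequency(cells$region_index[!is.na(cells$region_index)])
        writeCellTable(cbind(cells, tern), file.path(outDir, "colors.tsv"))
        writeCellTable(freq, file.path(outDir, "region_frequency.tsv"))
        .writeRunLog(outDir, sub, seed, list(cells = opts$cells))
        0L
      },
      "call-clones" = {
        cells <- readCellTable(.required(opts, "cells"))
        if (!is.null(opts$time))
          cells <- cells[cells$time_hpf == as.numeric(opts$time), ]
        cs <- callClones(cells, as.numeric(opts$dcontact %||% "12"))
        writeCellTable(cloneAssignments(cs), file.path(outDir, "clone_members.tsv"))
        writeCellTable(cloneSummary(cs), file.path(outDir, "clones.tsv"))
        .writeRunLog(outDir, sub, seed, list(cells = opts$cells))
        0L
      },
      "lineage" = {
        cfg <- simulationConfig(seed = seed)
        ds <- simulateDataset(cfg)
        res <- runWorkflow(ds, "timelapse")
        writeCellTable(res$divisions, file.path(outDir, "divisions.tsv"))
        writeCellTable(res$growth$summary, file.path(outDir, "clone_growth.tsv"))
        .writeRunLog(outDir, sub, seed, simParams(cfg))
        0L
      },
      "endpoint" = ,
      "compare" = {
        cells <- readCellTable(.required(opts, "cells"))
        tp <- as.numeric(.required(opts, "time"))
        cs <- callClones(cells[cells$time_hpf == tp, ])
        pc <- pipelineConfig(seed = seed)
        tab <- .functionalCloneTable(cs, pc, .vzMax(pc))
        writeCellTable(tab, file.path(outDir, "clone_modes.tsv"))
        .writeRunLog(outDir, sub, seed, list(cells = opts$cells, time = tp))
        0L
      },
      "run-all" = {
        wf <- opts$workflow %||% "timelapse"
        if (!wf %in% c("timelapse", "functional"))
          stop("usage error: --workflow must be timelapse or functional")
        cfg <- simulationConfig(
          seed = seed,
          redManipulatedFraction = if (wf == "functional") 1 else 0,
          tStart = if (wf == "functional") 36 else 32,
          tEnd = if (wf == "functional") 48 else 45)
        ds <- simulateDataset(cfg)
        res <- runWorkflow(ds, wf)
        if (wf == "timelapse") {
          writeCellTable(res$divisions, file.path(outDir, "divisions.tsv"))
          writeCellTable(res$growth$summary, file.path(outDir, "growth.tsv"))
        } else {
          writeCellTable(res$per_clone, file.path(outDir, "per_clone.tsv"))
          if (!is.null(res$comparisons)) {
            rep <- do.call(rbind, lapply(names(res$comparisons), function(nm) {
              x <- res$comparisons[[nm]]
              data.frame(measure = nm, test = x$test,
                         statistic = x$statistic, p_value = x$p_value)
            }))
            writeCellTable(rep, file.path(outDir, "comparisons.tsv"))
          }
        }
        .writeRunLog(outDir, sub, seed,
                     c(simParams(cfg), list(workflow = wf)))
        0L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.required <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v)) stop(sprintf("usage error: --%s is required", key))
  v
}

.parseFlags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      return(list(error = sprintf("error: unexpected argument '%s'", a)))
    key <- sub("^--", "", a)
    if (i + 1L > length(args))
      return(list(error = sprintf("error: flag --%s needs a value", key)))
    if (!is.null(opts[[key]]))
      return(list(error = sprintf("error: conflicting duplicate flag --%s", key)))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.writeRunLog <- function(outDir, subcommand, seed, config) {
  cfgFile <- tempfile()
  writeLines(paste(capture.output(str(config)), collapse = "\n"), cfgFile)
  log <- list(subcommand = subcommand, seed = seed,
              config_hash = unname(tools::md5sum(cfgFile)),
              package_version = as.character(utils::packageVersion("cloneBow")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  unlink(cfgFile)
  jsonlite::write_json(c(log, list(config = .jsonSafe(config))),
                       file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

.jsonSafe <- function(x) {
  lapply(x, function(v) {
    if (is.function(v) || isS4(v)) return(NULL)
    if (inherits(v, "ColorThresholds")) return(unclass(v))
    v
  })
}
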