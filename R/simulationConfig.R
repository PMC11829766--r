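#' Create a simulation configuration
#'
#' Builds a validated [SimulationConfig-class]. Defaults describe a
#' hindbrain-boundary multicolor time-lapse: hourly frames from 32 to 45 hpf,
#' a per-frame division probability of 0.056 (so that about half of the
#' progenitors present at the start divide within the 13 h window), division
#' modes PP 40% / PN 58% / NN 2%, a sister-division delay of 2.8 +/- 1.9 h,
#' and clones starting with one to three cells (mostly two).
#'
#' @param nFounders number of labelled founders (default 50).
#' @param copyNumberProbs named weights over transgene copy counts.
#' @param recombinationProbs named per-copy outcome probabilities over
#'   `farred` (unrecombined), `yfp`, `turquoise`, `tdtomato`.
#' @param redManipulatedFraction fraction of tdTomato-carrying founders that
#'   are labelled as genetically manipulated (0 disables the functional
#'   design).
#' @param divisionProbPerFrame per-frame progenitor division probability.
#' @param modeProbs named division-mode probabilities (PP, PN, NN), sum 1.
#' @param modeProbsRed optional mode probabilities for manipulated clones
#'   (NULL: same as `modeProbs`).
#' @param sisterDelayMean,sisterDelaySD sister-division delay (hours), normal
#'   truncated at 0.
#' @param tStart,tEnd,frameInterval imaging window (hpf) and cadence (hours).
#' @param initialCellsProbs named weights over cells per clone at `tStart`.
#' @param vzFraction ventricular-zone fraction of the dorsoventral extent.
#' @param tissueHeight dorsoventral tissue extent (micrometers).
#' @param cloneSpacing lateral spacing between rendered clones (micrometers).
#' @param channelNoiseSD additive noise s.d. per normalized color channel.
#' @param halfFrameJitter allow divisions on half-frame times.
#' @param seed integer seed.
#'
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nFounders = 10, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nFounders = 50,
                             copyNumberProbs = c("1" = 0.5, "2" = 0.3, "3" = 0.2),
                             recombinationProbs = c(farred = 0.1, yfp = 0.3,
                                                    turquoise = 0.3, tdtomato = 0.3),
                             redManipulatedFraction = 0,
                             divisionProbPerFrame = 0.056,
                             modeProbs = c(PP = 0.40, PN = 0.58, NN = 0.02),
                             modeProbsRed = NULL,
                             sisterDelayMean = 2.8,
                             sisterDelaySD = 1.9,
                             tStart = 32,
                             tEnd = 45,
                             frameInterval = 1,
                             initialCellsProbs = c("1" = 0.14, "2" = 0.77, "3" = 0.09),
                             vzFraction = 0.4,
                             tissueHeight = 40,
                             cloneSpacing = 60,
                             channelNoiseSD = 0.02,
                             halfFrameJitter = FALSE,
                             seed = 1L) {
  new("SimulationConfig",
      nFounders = nFounders,
      copyNumberProbs = copyNumberProbs,
      recombinationProbs = recombinationProbs[c("farred", "yfp", "turquoise",
                                                "tdtomato")],
      redManipulatedFraction = redManipulatedFraction,
      divisionProbPerFrame = divisionProbPerFrame,
      modeProbs = modeProbs[c("PP", "PN", "NN")],
      modeProbsRed = if (is.null(modeProbsRed)) numeric(0) else
        modeProbsRed[c("PP", "PN", "NN")],
      sisterDelayMean = sisterDelayMean,
      sisterDelaySD = sisterDelaySD,
      tStart = tStart, tEnd = tEnd, frameInterval = frameInterval,
      initialCellsProbs = initialCellsProbs,
      vzFraction = vzFraction, tissueHeight = tissueHeight,
      cloneSpacing = cloneSpacing,
      channelNoiseSD = channelNoiseSD,
      halfFrameJitter = halfFrameJitter,
      seed = seed)
}

#' @rdname simParams
#' @export
setMethod("simParams", "SimulationConfig", function(x) {
  nm <- slotNames(x)
  setNames(lapply(nm, function(s) slot(x, s)), nm)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  founders: %d, window: %g-%g hpf (every %g h)\n",
              as.integer(object@nFounders), object@tStart, object@tEnd,
              object@frameInterval))
  cat(sprintf("  division prob/frame: %.3f; modes PP/PN/NN: %s\n",
              object@divisionProbPerFrame,
              paste(sprintf("%.2f", object@modeProbs), collapse = "/")))
  cat(sprintf("  sister delay: %.1f +/- %.1f h; channel noise sd: %.3f; seed: %d\n",
              object@sisterDelayMean, object@sisterDelaySD,
              object@channelNoiseSD, as.integer(object@seed)))
  invisible(NULL)
})
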