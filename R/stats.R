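## Group-comparison layer: normality-gated two-group tests, Welch from
## summary statistics, one-way ANOVA with Dunnett contrasts, and generic
## marker-positive counting.

#' Build a group sample
#'
#' Small labelled container for one experimental group: values plus the unit
#' of analysis (embryo, boundary or clone) the measurements come from.
#'
#' @param values numeric measurements (percentages or counts).
#' @param label group label.
#' @param unit experimental unit: "embryo", "boundary" or "clone".
#' @return list of class `GroupSample`.
#' @export
groupSample <- function(values, label = "group",
                        unit = c("embryo", "boundary", "clone")) {
  unit <- match.arg(unit)
  stopifnot(length(values) >= 1L, is.numeric(values))
  structure(list(label = label, values = as.numeric(values), unit = unit),
            class = "GroupSample")
}

.groupValues <- function(x) {
  if (inherits(x, "GroupSample")) x$values else as.numeric(x)
}
.groupLabel <- function(x, default) {
  if (inherits(x, "GroupSample")) x$label else default
}

.summarize <- function(v, label) {
  data.frame(label = label, n = length(v), mean = mean(v),
             sd = if (length(v) > 1L) sd(v) else NA_real_,
             median = median(v))
}

#' Compare two groups with a normality-gated test
#'
#' Runs a Shapiro-Wilk normality check on each group at `normalityAlpha`; if
#' both groups are consistent with normality the groups are compared with
#' Welch's unequal-variance two-sided t-test, otherwise with the two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. Groups too small for the normality
#' gate (n < 3) or constant-valued groups fall back to Mann-Whitney, with a
#' warning or a note respectively.
#'
#' @param a,b numeric vectors or [groupSample()] objects.
#' @param normalityAlpha significance level of the normality gate.
#' @param labels length-2 character, used when `a`/`b` are bare vectors.
#' @return list of class `ComparisonResult`: `test` ("welch" or
#'   "mann_whitney"), `statistic`, `p_value`, `summaries` (per-group n, mean,
#'   sd, median), `normality_p`, `notes`.
#' @examples
#' compareTwoGroups(c(5, 6, 4, 7, 5), c(9, 11, 10, 12, 13))
#' @export
compareTwoGroups <- function(a, b, normalityAlpha = 0.05,
                             labels = c("group1", "group2")) {
  va <- .groupValues(a); vb <- .groupValues(b)
  la <- .groupLabel(a, labels[1]); lb <- .groupLabel(b, labels[2])
  notes <- character()
  constant <- function(v) length(unique(v)) == 1L
  normP <- c(NA_real_, NA_real_)
  if (length(va) < 3L || length(vb) < 3L) {
    warning("group below n = 3: normality gate skipped, using Mann-Whitney")
    useWelch <- FALSE
    notes <- c(notes, "small_group_mann_whitney")
  } else if (constant(va) || constant(vb)) {
    useWelch <- FALSE
    notes <- c(notes, "constant_group_mann_whitney")
  } else {
    normP <- c(shapiro.test(va)$p.value, shapiro.test(vb)$p.value)
    useWelch <- all(normP > normalityAlpha)
  }
  if (useWelch) {
    tt <- t.test(va, vb, var.equal = FALSE)
    res <- list(test = "welch", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(va, vb, exact = NULL))
    res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(res, list(summaries = rbind(.summarize(va, la),
                                          .summarize(vb, lb)),
                        normality_p = normP, notes = notes)),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Welch's t-test from summary statistics
#'
#' Closed-form Welch unequal-variance two-sided t-test computed from group
#' means, standard deviations and sizes — the form needed to verify printed
#' figure-legend statistics when raw values are unavailable.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summaries.
#' @return list with `statistic` (t), `df` (Welch-Satterthwaite), `p_value`
#'   (two-sided).
#' @examples
#' welchFromSummary(5.3, 4, 6, 13.5, 5.7, 9)
#' @export
welchFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) stop("both groups constant: Welch statistic undefined")
  tstat <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}

#' Compare several groups to a reference (ANOVA + Dunnett)
#'
#' One-way ANOVA across all groups followed by Dunnett's multiple-comparison
#' test of every group against the reference, with family-wise adjusted
#' p-values.
#'
#' @param groups named list of numeric vectors (or [groupSample()] objects);
#'   at least three groups.
#' @param reference name of the reference group (default: the first).
#' @return list with `anova` (F statistic, df, p) and `comparisons`
#'   (data.frame: group, estimate, statistic, p_adjusted, p_unadjusted).
#' @examples
#' set.seed(1)
#' g <- list(ctrl = rnorm(8), a = rnorm(8), b = rnorm(8, 3))
#' compareMultiGroups(g)
#' @export
compareMultiGroups <- function(groups, reference = NULL) {
  if (length(groups) < 3L)
    stop("need at least 3 groups; use compareTwoGroups() for two")
  vals <- lapply(groups, .groupValues)
  nms <- names(groups)
  if (is.null(nms) || any(nms == ""))
    stop("groups must be named")
  if (is.null(reference)) reference <- nms[1]
  if (!reference %in% nms) stop("reference group not found")
  df <- data.frame(value = unlist(vals, use.names = FALSE),
                   group = factor(rep(nms, lengths(vals)),
                                  levels = c(reference,
                                             setdiff(nms, reference))))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  smAdj <- summary(gl)
  smRaw <- summary(gl, test = multcomp::adjusted("none"))
  cmp <- data.frame(
    group = setdiff(nms, reference),
    estimate = unname(smAdj$test$coefficients),
    statistic = unname(smAdj$test$tstat),
    p_adjusted = unname(smAdj$test$pvalues),
    p_unadjusted = unname(smRaw$test$pvalues))
  list(anova = list(F = an[["F value"]][1],
                    df = c(an[["Df"]][1], an[["Df"]][2]),
                    p_value = an[["Pr(>F)"]][1]),
       reference = reference, comparisons = cmp)
}

#' Fraction of marker-positive cells within a region of interest
#'
#' Generic percent-positive counting: the fraction of cells carrying a
#' logical marker flag among all cells inside a region of interest, across
#' all imaging planes.
#'
#' @param cells cell table.
#' @param flag name of the logical marker column.
#' @param roi optional list with any of `x`, `y`, `z` set to `c(min, max)`
#'   bounds (micrometers); `NULL` counts all cells.
#' @return list with `fraction`, `percent`, `n_positive`, `n_total`.
#' @examples
#' tb <- data.frame(x_um = 1:10, y_um = 0, z_um = 0, pos = rep(c(TRUE, FALSE), 5))
#' percentPositive(tb, "pos")
#' @export
percentPositive <- function(cells, flag, roi = NULL) {
  if (!flag %in% names(cells)) stop(sprintf("flag column '%s' missing", flag))
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(roi)) {
    axisCol <- c(x = "x_um", y = "y_um", z = "z_um")
    for (ax in names(roi)) {
      cn <- axisCol[[ax]]
      keep <- keep & cells[[cn]] >= roi[[ax]][1] & cells[[cn]] <= roi[[ax]][2]
    }
  }
  n <- sum(keep)
  if (n == 0L) stop("empty ROI")
  pos <- sum(isTRUE_vec(cells[[flag]][keep]))
  list(fraction = pos / n, percent = 100 * pos / n,
       n_positive = pos, n_total = n)
}
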