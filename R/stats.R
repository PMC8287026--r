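# Cohort statistics: group comparison, correlation, normality, paired
# agreement, and assembly of the characteristic/correlation report tables.
# The individual tests delegate to the standard stats:: implementations;
# this layer adds the uniform result container, listwise deletion and the
# report assembly.

.statResult <- function(test, statistic, p, estimate = NA_real_,
                        n = integer(0), ci = NULL, extra = list()) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(c(list(test = test, statistic = unname(statistic),
                   p_value = unname(p), estimate = unname(estimate),
                   n = n, ci = ci), extra),
            class = c("StatResult", "list"))
}

#' @export
print.StatResult <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), sep = "")
  if (!is.na(x$estimate))
    cat(", estimate = ", format(x$estimate, digits = 4), sep = "")
  cat(", n = ", paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Pearson correlation with two-sided t-transform p-value
#'
#' Pairs with a missing value in either variable are deleted listwise.
#'
#' @param x,y paired numeric vectors.
#' @return A `StatResult` with the correlation as `estimate`.
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  .statResult("Pearson correlation", ct$statistic, ct$p.value,
              estimate = ct$estimate, n = length(x),
              ci = unname(ct$conf.int))
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided; the p-value is exact (enumeration over rank arrangements)
#' when both groups have at most `exactThreshold` observations and there
#' are no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples for the two groups.
#' @param exactThreshold maximum per-group size for the exact p-value.
#' @return A `StatResult`; `statistic` is the U statistic of `x`.
#' @export
mannWhitneyU <- function(x, y, exactThreshold = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  useExact <- !ties && length(x) <= exactThreshold &&
    length(y) <= exactThreshold
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = useExact, correct = TRUE))
  .statResult("Mann-Whitney U", wt$statistic, wt$p.value,
              n = c(length(x), length(y)),
              extra = list(exact = useExact))
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 to 2000 non-missing values, non-constant.
#' @return A `StatResult` with the W statistic.
#' @export
shapiroWilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 2000L)
    stop("sample size must be between 3 and 2000")
  if (stats::sd(x) == 0) stop("constant sample: W undefined")
  st <- stats::shapiro.test(x)
  .statResult("Shapiro-Wilk", st$statistic, st$p.value, n = length(x))
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors (incomplete pairs deleted listwise).
#' @return A `StatResult` with the mean difference as `estimate`.
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("at least 2 complete pairs required")
  if (stats::sd(x - y) == 0)
    stop("zero variance of the paired differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  .statResult("paired t", tt$statistic, tt$p.value,
              estimate = tt$estimate, n = length(x),
              ci = unname(tt$conf.int))
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences `d = x - y` against means `m = (x + y) / 2`:
#' bias = mean(d), limits of agreement = bias +/- 1.96 sd(d).
#'
#' @param x,y paired measurements of the same quantity.
#' @return A `StatResult` with `estimate` = bias and fields `loa`
#'   (lower, upper), `means` and `diffs` for plotting.
#' @export
blandAltman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs required")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  .statResult("Bland-Altman", bias, NA_real_, estimate = bias,
              n = length(x),
              extra = list(loa = c(lower = bias - 1.96 * s,
                                   upper = bias + 1.96 * s),
                           sd = s, means = (x + y) / 2, diffs = d))
}

#' Statistics configuration
#'
#' @param alpha significance level for flagging.
#' @param exactThreshold Mann-Whitney exactness threshold.
#' @param adjust p-value adjustment across report rows: `"none"`
#'   (default, matching per-variable uncorrected reporting) or `"holm"`.
#' @return A named list of class `statsControl`.
#' @export
statsControl <- function(alpha = 0.05, exactThreshold = 8,
                         adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1, exactThreshold >= 0)
  structure(list(alpha = alpha, exactThreshold = exactThreshold,
                 adjust = adjust),
            class = c("statsControl", "list"))
}

.reportVars <- c(
  age_years = "Age (years)",
  cct_um = "Central corneal thickness (um)",
  corneal_radius_mm = "Radius of corneal curvature (mm)",
  al_mm = "Axial length (mm)",
  acv_ul = "Anterior chamber volume (uL)",
  iop_mmhg = "Intraocular pressure (mmHg)",
  opa_mmhg = "Ocular pulse amplitude (mmHg)",
  dv_ul = "Ocular volume change (uL)",
  k_per_ul = "Ocular rigidity (1/uL)",
  sp_a1 = "SP-A1",
  sp_hc = "SP-HC")

.corrVars <- c("cct_um", "corneal_radius_mm", "al_mm", "acv_ul",
               "iop_mmhg", "opa_mmhg", "sp_a1", "sp_hc",
               "pv_ratio_mmhg_per_ul")

#' Assemble the cohort characteristic and correlation report
#'
#' Produces (a) a per-variable group summary (mean +/- sd per group with
#' the two-sided Mann-Whitney p-value) and (b) the correlation of ocular
#' rigidity with each morphological/biomechanical characteristic for the
#' combined cohort and the control-only stratum. Missing values reduce the
#' per-cell n, which is always reported. With a single group the
#' comparison columns are omitted but correlations are still produced.
#'
#' @param table cohort data.frame with a `group` column and derived
#'   fields (see [computeCohort()]).
#' @param control a [statsControl()].
#' @param rigidityVar column holding the rigidity estimate.
#' @return list of class `ocupulseReport`: `groupSummary` and
#'   `correlations` data.frames plus the control list used.
#' @export
buildReport <- function(table, control = statsControl(),
                        rigidityVar = "k_per_ul") {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  if (!nrow(table)) stop("empty cohort")
  groups <- unique(table$group)
  if (any(!table(table$group))) stop("empty group")
  twoGroups <- length(groups) >= 2L

  vars <- intersect(names(.reportVars), names(table))
  sumRows <- lapply(vars, function(v) {
    row <- list(variable = .reportVars[[v]], column = v)
    for (g in groups) {
      xs <- table[[v]][table$group == g]
      xs <- xs[!is.na(xs)]
      row[[paste0("mean_", g)]] <- if (length(xs)) mean(xs) else NA_real_
      row[[paste0("sd_", g)]] <- if (length(xs) > 1) stats::sd(xs)
                                 else NA_real_
      row[[paste0("n_", g)]] <- length(xs)
    }
    if (twoGroups) {
      a <- table[[v]][table$group == groups[1]]
      b <- table[[v]][table$group == groups[2]]
      p <- tryCatch(mannWhitneyU(a[!is.na(a)], b[!is.na(b)],
                                 control$exactThreshold)$p_value,
                    error = function(e) NA_real_)
      row$p_value <- p
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  groupSummary <- do.call(rbind, sumRows)
  if (twoGroups) {
    if (control$adjust == "holm")
      groupSummary$p_value <- stats::p.adjust(groupSummary$p_value,
                                              "holm")
    groupSummary$significant <-
      !is.na(groupSummary$p_value) & groupSummary$p_value < control$alpha
  }

  strata <- list(combined = rep(TRUE, nrow(table)))
  if ("control" %in% groups && twoGroups)
    strata$control_only <- table$group == "control"
  cvars <- intersect(.corrVars, names(table))
  corRows <- list()
  for (sn in names(strata)) {
    sub <- table[strata[[sn]], , drop = FALSE]
    for (v in cvars) {
      res <- tryCatch(pearsonCorr(sub[[rigidityVar]], sub[[v]]),
                      error = function(e) NULL)
      corRows[[length(corRows) + 1L]] <- data.frame(
        stratum = sn, variable = v,
        n = if (is.null(res)) sum(!is.na(sub[[rigidityVar]]) &
                                    !is.na(sub[[v]])) else res$n,
        r = if (is.null(res)) NA_real_ else res$estimate,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corRows)
  if (control$adjust == "holm")
    correlations$p_value <- stats::p.adjust(correlations$p_value, "holm")
  correlations$significant <-
    !is.na(correlations$p_value) & correlations$p_value < control$alpha
  structure(list(groupSummary = groupSummary,
                 correlations = correlations,
                 control = unclass(control)),
            class = c("ocupulseReport", "list"))
}

#' @export
print.ocupulseReport <- function(x, ...) {
  cat("Cohort report\n== Group summary ==\n")
  print(x$groupSummary, digits = 4)
  cat("== Correlations with ocular rigidity ==\n")
  print(x$correlations, digits = 4)
  invisible(x)
}

#' Write a cohort report to CSV and Markdown
#'
#' @param report an `ocupulseReport` from [buildReport()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "ocupulseReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "group_summary.csv")
  p2 <- file.path(dir, "correlations.csv")
  utils::write.csv(report$groupSummary, p1, row.names = FALSE)
  utils::write.csv(report$correlations, p2, row.names = FALSE)
  md <- file.path(dir, "report.md")
  lines <- c("# Cohort report", "", "## Group summary", "",
             knitrFreeTable(report$groupSummary), "",
             "## Correlations with ocular rigidity", "",
             knitrFreeTable(report$correlations), "")
  writeLines(lines, md)
  invisible(c(p1, p2, md))
}

# minimal Markdown table writer (avoids a knitr dependency)
knitrFreeTable <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) format(signif(v, 4), trim = TRUE) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
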