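#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal significance level in (0, 1).
#' @param nComparisons number of comparisons (>= 1); e.g. three segment
#'   comparisons across six frequency bands give 18 and a threshold of
#'   0.05/18 = 0.00278.
#' @return `alpha / nComparisons`.
#' @examples
#' bonferroniThreshold(0.05, 18)
#' @export
bonferroniThreshold <- function(alpha, nComparisons) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(nComparisons), length(nComparisons) == 1L,
            nComparisons >= 1)
  alpha / nComparisons
}

#' Build / validate a long-format segment table
#'
#' The row type of all segment statistics: one row per
#' (patient, seizure, band, segment) with the mean AE of that window.
#' `segmentTableFromSummaries` reshapes the wide per-seizure summaries of
#' [segmentMeans()] into this long format; `validateSegmentTable` checks
#' the invariants (exactly the three segments pre/ictal/post per
#' (patient, seizure, band) triple).
#'
#' @param summaries a data.frame of rows from [segmentMeans()].
#' @return A data.frame with columns `patientId`, `seizureId`, `band`,
#'   `segment` (factor pre/ictal/post) and `meanAe`.
#' @export
segmentTableFromSummaries <- function(summaries) {
  stopifnot(all(c("patientId", "seizureId", "band", "meanPre", "meanIctal",
                  "meanPost") %in% names(summaries)))
  long <- do.call(rbind, lapply(c("pre", "ictal", "post"), function(seg) {
    col <- c(pre = "meanPre", ictal = "meanIctal", post = "meanPost")[[seg]]
    data.frame(patientId = summaries$patientId,
               seizureId = summaries$seizureId, band = summaries$band,
               segment = seg, meanAe = summaries[[col]],
               stringsAsFactors = FALSE)
  }))
  long$segment <- factor(long$segment, levels = c("ictal", "pre", "post"))
  validateSegmentTable(long)
  long[order(long$patientId, long$seizureId, long$band, long$segment), ]
}

#' @rdname segmentTableFromSummaries
#' @param table a long-format segment table.
#' @export
validateSegmentTable <- function(table) {
  need <- c("patientId", "seizureId", "band", "segment", "meanAe")
  if (!all(need %in% names(table)))
    stop("segment table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(as.character(table$segment) %in% c("pre", "ictal", "post")))
    stop("segment labels must be pre/ictal/post", call. = FALSE)
  if (any(!is.finite(table$meanAe)))
    stop("non-finite mean AE in segment table", call. = FALSE)
  cnt <- table(paste(table$patientId, table$seizureId, table$band))
  if (any(cnt != 3L))
    stop("each (patient, seizure, band) must contribute exactly 3 rows",
         call. = FALSE)
  invisible(table)
}

#' Linear mixed-effects test of segment differences
#'
#' Fits `meanAe ~ segment + (1 | patientId)` by maximum likelihood for one
#' band, with the ictal segment as the reference level, and reports the two
#' non-reference fixed effects (pre - ictal, post - ictal) with asymptotic
#' Wald z tests. Repeated seizures from the same patient are handled by the
#' patient-level random intercept. A singular fit (zero between-patient
#' variance) raises a warning but still produces the report; fewer than two
#' patients is an error. With `perPatient = TRUE` seizures are averaged
#' within patient before fitting.
#'
#' @param table a long-format segment table (see
#'   [segmentTableFromSummaries()]).
#' @param band band name to subset (default: the single band present).
#' @param perPatient average seizures within patient first (default FALSE:
#'   one row per seizure per segment, which keeps the random intercept
#'   meaningful at cohort scale).
#' @return A data.frame with one row per non-reference segment: `band`,
#'   `term` ("pre" or "post", each vs ictal), `estimate`, `se`, `z`, `p`,
#'   plus attributes `ranefVar` (random-intercept variance) and `singular`.
#' @export
fitSegmentModel <- function(table, band = NULL, perPatient = FALSE) {
  validateSegmentTable(table)
  if (is.null(band)) {
    band <- unique(as.character(table$band))
    if (length(band) != 1L)
      stop("several bands present; pass 'band'", call. = FALSE)
  }
  tab <- table[as.character(table$band) == band, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for band '", band, "'", call. = FALSE)
  if (length(unique(tab$patientId)) < 2L)
    stop("model error: need at least 2 patients", call. = FALSE)
  if (perPatient) {
    agg <- stats::aggregate(meanAe ~ patientId + band + segment, tab, mean)
    agg$seizureId <- "avg"
    tab <- agg
  }
  tab$segment <- factor(as.character(tab$segment),
                        levels = c("ictal", "pre", "post"))
  fit <- suppressMessages(lme4::lmer(
    meanAe ~ segment + (1 | patientId), data = tab, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  if (lme4::isSingular(fit, tol = 1e-5))
    warning("singular fit: between-patient variance estimated at zero")
  co <- summary(fit)$coefficients
  rows <- grep("^segment", rownames(co))
  res <- data.frame(
    band = band,
    term = sub("^segment", "", rownames(co)[rows]),
    estimate = co[rows, "Estimate"],
    se = co[rows, "Std. Error"],
    z = co[rows, "t value"],
    p = 2 * stats::pnorm(-abs(co[rows, "t value"])),
    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(res, "ranefVar") <- vc$vcov[vc$grp == "patientId"]
  attr(res, "singular") <- lme4::isSingular(fit, tol = 1e-5)
  res
}

#' Per-band effect report with Bonferroni-adjusted significance
#'
#' Runs [fitSegmentModel()] for every band in the table and flags fixed
#' effects whose Wald p-value falls below
#' `alpha / (comparisonsPerBand * nBands)` (default: three comparisons per
#' band, matching a pre/ictal/post design).
#'
#' @inheritParams fitSegmentModel
#' @param alpha nominal level (default 0.05).
#' @param comparisonsPerBand comparisons counted per band (default 3).
#' @return A data.frame of [fitSegmentModel()] rows for all bands with an
#'   added logical `significant` column; the threshold is attached as
#'   attribute `threshold`.
#' @export
segmentEffectReport <- function(table, alpha = 0.05, comparisonsPerBand = 3,
                                perPatient = FALSE) {
  validateSegmentTable(table)
  bands <- unique(as.character(table$band))
  thr <- bonferroniThreshold(alpha, comparisonsPerBand * length(bands))
  res <- do.call(rbind, lapply(bands, function(b)
    fitSegmentModel(table, band = b, perPatient = perPatient)))
  res$significant <- res$p < thr
  attr(res, "threshold") <- thr
  res
}

#' Spearman rank correlation with midrank ties
#'
#' Rho is the Pearson correlation of the midranks; the two-sided p-value
#' uses the t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n - 2
#' degrees of freedom (p = 0 at |rho| = 1).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return A list with `rho`, `p` and `n`.
#' @examples
#' rankCorrelation(1:4, c(2, 4, 6, 8))   # rho = 1
#' @export
rankCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with midrank ties: the exact null distribution when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction (the
#' chosen policy is reported in the result).
#'
#' @param a,b numeric vectors (both non-empty).
#' @param sided `"two"`, `"one-greater"` (a tends larger) or `"one-less"`.
#' @return A list with `statistic` (the rank sum of `a`), `p`, and
#'   `method` ("exact" or "normal-approximation").
#' @examples
#' rankSumTest(c(1, 2), c(10, 11))$p   # exact: 1/3
#' @export
rankSumTest <- function(a, b, sided = c("two", "one-greater", "one-less")) {
  sided <- match.arg(sided)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  alt <- switch(sided, two = "two.sided", `one-greater` = "greater",
                `one-less` = "less")
  ties <- anyDuplicated(c(a, b)) > 0L
  useExact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                            exact = useExact,
                                            correct = !useExact))
  W <- unname(wt$statistic) + length(a) * (length(a) + 1) / 2
  p <- wt$p.value
  if (is.nan(p)) p <- 1        # all observations tied: no evidence either way
  list(statistic = W, p = p,
       method = if (useExact) "exact" else "normal-approximation")
}
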