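#' Pearson correlation / least-squares line fit
#'
#' Least-squares line of y on x with R-squared equal to the squared Pearson
#' correlation and a two-sided p-value from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, x non-constant).
#' @return data.frame with `slope`, `intercept`, `r`, `r2`, `p`, `n`.
#' @examples
#' pearsonFit(1:10, 2 * (1:10) + 1)  # r2 = 1, slope = 2, intercept = 1
#' @export
pearsonFit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0) stop("x is constant: fit undefined")
  r <- if (sd(y) == 0) 0 else cor(x, y)
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(slope = slope, intercept = intercept, r = r, r2 = r^2,
             p = min(p, 1), n = n)
}

#' Z-transform values within groups
#'
#' Maps each group to mean 0 and sample SD 1 (n - 1 convention) — used to
#' remove the between-group (child/adult) mean difference before
#' cross-metric correlation.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return Z-scored vector.
#' @export
zscoreWithinGroups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- values
  for (g in unique(groups)) {
    sel <- which(groups == g)
    if (length(sel) < 2) stop("group '", g, "' has fewer than 2 values")
    s <- sd(values[sel])
    if (s == 0 || !is.finite(s)) stop("group '", g, "' is constant")
    out[sel] <- (values[sel] - mean(values[sel])) / s
  }
  out
}

#' Child/adult group labels
#' @param age Ages in years.
#' @param cut Child/adult boundary (default 18).
#' @return "child"/"adult" per subject.
#' @export
ageGroups <- function(age, cut = 18) ifelse(age < cut, "child", "adult")

#' Per-region node-degree slopes against age
#'
#' One [pearsonFit()] of node degree versus age per region.
#'
#' @param degrees subjects x regions matrix (colnames = region labels).
#' @param age Age per subject (>= 3 subjects).
#' @return data.frame with one row per region: `region`, `slope`,
#'   `intercept`, `r2`, `p`.
#' @export
degreeAgeSlopes <- function(degrees, age) {
  degrees <- as.matrix(degrees)
  stopifnot(nrow(degrees) == length(age))
  fits <- lapply(seq_len(ncol(degrees)), function(j) {
    f <- pearsonFit(age, degrees[, j])
    data.frame(region = colnames(degrees)[j] %||% as.character(j), f)
  })
  do.call(rbind, fits)
}

#' Per-frequency correlation of burst spectra with age
#'
#' For every frequency on a common grid, the Pearson correlation of
#' per-subject burst-state PSD values against age, with uncorrected p-values
#' and a p < alpha flag (an optional Benjamini-Hochberg adjustment is
#' exposed for the sweep).
#'
#' @param psd subjects x frequencies matrix of burst-state PSDs.
#' @param age Age per subject.
#' @param freq Frequency grid (Hz).
#' @param alpha Flagging level (default 0.01, uncorrected).
#' @param adjust "none" (default) or "BH".
#' @return data.frame with `freq`, `r`, `p`, `flagged`.
#' @export
psdAgeCorrelation <- function(psd, age, freq, alpha = 0.01,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  psd <- as.matrix(psd)
  stopifnot(nrow(psd) == length(age), ncol(psd) == length(freq))
  if (any(apply(psd, 2, sd) == 0)) {
    stop("constant PSD across subjects: correlation undefined")
  }
  fits <- lapply(seq_len(ncol(psd)), function(j) pearsonFit(age, psd[, j]))
  r <- vapply(fits, function(f) f$r, numeric(1))
  p <- vapply(fits, function(f) f$p, numeric(1))
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  data.frame(freq = freq, r = r, p = p, flagged = padj < alpha)
}

#' Cohort-level trend report
#'
#' Age trends of every cohort metric plus the cross-metric association
#' between classical beta modulation and burst probability modulation
#' (within-group z-transformed to mitigate the age confound).
#'
#' @param tab Cohort table: one row per subject with columns `age`,
#'   `betamod`, `m50`, `deltaP`, `burstAmplitude`, `globalConnectivity`.
#' @return List of fit data.frames (`betamodAge`, `m50Age`, `deltaPAge`,
#'   `burstAmplitudeAge`, `connectivityAge`, `betamodDeltaP`).
#' @export
groupTrendReport <- function(tab) {
  grp <- ageGroups(tab$age)
  # the within-group z-transform needs >= 2 non-constant values per group;
  # degenerate (tiny) cohorts fall back to the unadjusted correlation
  z <- tryCatch(
    list(b = zscoreWithinGroups(tab$betamod, grp),
         p = zscoreWithinGroups(tab$deltaP, grp)),
    error = function(e) list(b = tab$betamod, p = tab$deltaP))
  zb <- z$b
  zp <- z$p
  list(betamodAge = pearsonFit(tab$age, tab$betamod),
       m50Age = pearsonFit(tab$age, tab$m50),
       deltaPAge = pearsonFit(tab$age, tab$deltaP),
       burstAmplitudeAge = pearsonFit(tab$age, tab$burstAmplitude),
       connectivityAge = pearsonFit(tab$age, tab$globalConnectivity),
       betamodDeltaP = pearsonFit(zb, zp))
}
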