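#' Welch's two-sample t test
#'
#' Unequal-variance two-sample t with Welch–Satterthwaite degrees of freedom
#' and a two-sided p-value. The degenerate case of two zero-variance samples
#' with equal means returns t = 0, p = 1; zero-variance samples with
#' different means are an error.
#'
#' @param x,y numeric samples of length >= 2.
#' @return a \code{welch_result} list: t, df, p, plus the sample means.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) .stopf("both samples need n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                            mean_x = mean(x), mean_y = mean(y)),
                       class = "welch_result"))
    .stopf("both samples have zero variance but different means")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_x = mean(x), mean_y = mean(y)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3f, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Benjamini–Hochberg step-up adjustment (capped at 1, monotone in p-value
#' rank) by default; "bonferroni" is available by flag.
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @param method "BH" or "bonferroni".
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0,1]")
  p.adjust(pvals, method = method)
}

#' Ordinary least squares on log-log data
#'
#' Fits log(y) ~ log(x) by OLS after excluding non-positive observations
#' (their count is recorded), returning the slope, its classical standard
#' error, and the intercept. The canonical use is regressing log nascent
#' gene-body coverage on log mRNA expression.
#'
#' @param x,y positive observations (non-positive pairs are excluded).
#' @return a \code{loglog_fit} list: beta, se_beta, intercept, n, n_excluded,
#'   r_squared.
#' @export
loglog_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_excluded <- sum(!ok)
  if (sum(ok) < 3) .stopf("need at least 3 positive (x, y) pairs")
  lx <- log(x[ok]); ly <- log(y[ok])
  fit <- lm(ly ~ lx)
  sm <- summary(fit)
  structure(list(beta = unname(coef(fit)[2]),
                 se_beta = unname(sm$coefficients[2, 2]),
                 intercept = unname(coef(fit)[1]),
                 n = sum(ok), n_excluded = n_excluded,
                 r_squared = sm$r.squared),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("log-log OLS: beta = %.4g (SE %.4g), intercept = %.4g, n = %d\n",
              x$beta, x$se_beta, x$intercept, x$n))
  invisible(x)
}

#' Compare two regression slopes by a z statistic
#'
#' z = (beta1 − beta2) / sqrt(se1^2 + se2^2), with a two-sided p-value from
#' the standard normal. When both standard errors are zero and the slopes
#' differ, z is infinite and p = 0 (flagged).
#'
#' @param fit1,fit2 \code{loglog_fit} objects, or lists with beta / se_beta.
#' @return a \code{slope_comparison} list: beta1, se1, beta2, se2, z, p,
#'   degenerate.
#' @export
slope_z <- function(fit1, fit2) {
  b1 <- fit1$beta; s1 <- fit1$se_beta
  b2 <- fit2$beta; s2 <- fit2$se_beta
  if (s1 < 0 || s2 < 0) .stopf("standard errors must be >= 0")
  denom <- sqrt(s1^2 + s2^2)
  degenerate <- denom == 0
  z <- if (degenerate) {
    if (b1 == b2) 0 else sign(b1 - b2) * Inf
  } else (b1 - b2) / denom
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  structure(list(beta1 = b1, se1 = s1, beta2 = b2, se2 = s2, z = z, p = p,
                 degenerate = degenerate),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope comparison: z = %.4g, p = %.3g\n", x$z, x$p))
  invisible(x)
}

#' TMM between-sample normalisation factors
#'
#' Trimmed mean of M-values (Robinson–Oshlack) with the stated log-ratio and
#' absolute-intensity trims, precision-weighted, renormalised to geometric
#' mean 1. Delegates to the reference implementation in \pkg{edgeR}.
#'
#' @param counts non-negative matrix (genes x samples, >= 2 samples).
#' @param ref_column optional reference sample index.
#' @param trim_M,trim_A trim fractions for M and A values.
#' @return per-sample normalisation factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref_column = NULL, trim_M = 0.30,
                        trim_A = 0.05) {
  if (ncol(counts) < 2) .stopf("need at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero)) .stopf("sample %s has all-zero counts",
                        colnames(counts)[which(zero)[1]] %||% which(zero)[1])
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_column,
                              logratioTrim = trim_M, sumTrim = trim_A)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Two-condition differential-expression caller
#'
#' A transparent DE procedure for count matrices: genes failing
#' CPM > \code{cpm_min} in at least half of the samples are removed; library
#' sizes are TMM-corrected; per-gene Welch t tests compare conditions on
#' log2(CPM + pseudocount); p-values are BH-adjusted; logFC is the
#' difference of condition means of log2-CPM (second condition level minus
#' first).
#'
#' @param counts genes x samples count matrix with rownames.
#' @param design factor (or character) of conditions per sample, 2 levels;
#'   the first level is the reference.
#' @param cpm_min CPM filter threshold.
#' @param pseudocount added to CPM before the log2.
#' @return data frame gene_id, mean log2-CPM per condition, logfc, p, adj_p;
#'   filter and normalisation metadata in attributes.
#' @export
de_call <- function(counts, design, cpm_min = 1, pseudocount = 0.5) {
  design <- as.factor(design)
  if (nlevels(design) != 2) .stopf("design must have exactly 2 conditions")
  if (any(table(design) < 2)) .stopf("need >= 2 replicates per condition")
  cpm_raw <- sweep(counts, 2, colSums(counts), `/`) * 1e6
  keep <- rowSums(cpm_raw > cpm_min) >= ncol(counts) / 2
  if (!any(keep)) .stopf("no gene passes the CPM filter")
  counts <- counts[keep, , drop = FALSE]
  f <- tmm_factors(counts)
  eff_lib <- colSums(counts) * f
  lcpm <- log2(sweep(counts, 2, eff_lib, `/`) * 1e6 + pseudocount)
  a <- design == levels(design)[1]
  b <- !a
  na <- sum(a); nb <- sum(b)
  ma <- rowMeans(lcpm[, a, drop = FALSE])
  mb <- rowMeans(lcpm[, b, drop = FALSE])
  va <- apply(lcpm[, a, drop = FALSE], 1, var)
  vb <- apply(lcpm[, b, drop = FALSE], 1, var)
  sem <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(sem)
  df <- sem^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  zero <- sem == 0
  p <- 2 * pt(-abs(tstat), df)
  p[zero & ma == mb] <- 1
  tstat[zero & ma == mb] <- 0
  if (any(zero & ma != mb)) p[zero & ma != mb] <- 0
  out <- data.frame(gene_id = rownames(counts),
                    mean_log2cpm_1 = ma, mean_log2cpm_2 = mb,
                    logfc = mb - ma, p = p, adj_p = bh_adjust(p),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_log2cpm_", levels(design))
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  attr(out, "tmm_factors") <- f
  attr(out, "pseudocount") <- pseudocount
  out
}
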