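#' Rankit (rank-based inverse normal) transform, z-scored
#'
#' Replaces values by their average ranks, maps rank k of n through
#' `qnorm((k - 0.5) / n)`, and standardizes the result to sample mean 0 and
#' sample SD 1.  Used to reduce skewness and kurtosis of covariates (PDS,
#' CBCL symptom scores) before they enter linear models.  The transform is
#' invariant under strictly increasing transformations of the input.
#'
#' @param x Numeric vector, length >= 2; ties receive average ranks.
#' @return Numeric vector of the same length.
#' @export
rankit_z <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (anyNA(x)) stop("missing values not allowed")
  if (length(unique(x)) == 1L) stop("all values identical: Rankit undefined")
  n <- length(x)
  q <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  as.numeric(scale(q))
}

#' Prepare a subject design table for analysis
#'
#' Validates the required columns, coerces `group`, `sex` and `site` to
#' factors (with `case` as the first group level so signed contrasts read
#' case minus control), and appends Rankit+z transformed copies of the PDS
#' and CBCL scores (`pds_z`, `cbcl_z`) alongside the originals.
#'
#' @param design Data frame with columns `subject_id`, `group`
#'   (`case`/`control`), `sex` (`female`/`male`), `pds`, `site`,
#'   `cbcl_adhd`, and optionally `medicated` (logical, `NA` for controls).
#' @return The augmented data frame.
#' @export
prepare_design <- function(design) {
  need <- c("subject_id", "group", "sex", "pds", "site", "cbcl_adhd")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design table missing columns: ",
                         paste(miss, collapse = ", "))
  for (v in c("group", "sex", "site"))
    if (anyNA(design[[v]])) stop("missing values in '", v, "'")
  design$group <- factor(design$group, levels = c("case", "control"))
  if (anyNA(design$group)) stop("'group' must be 'case' or 'control'")
  design$sex <- factor(design$sex)
  design$site <- factor(design$site)
  design$pds_z <- rankit_z(design$pds)
  design$cbcl_z <- rankit_z(design$cbcl_adhd)
  design
}

#' Read a design table CSV
#'
#' @param path CSV with the columns listed in [prepare_design()].
#' @return Validated, transformed design table.
#' @export
read_design_table <- function(path) {
  prepare_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Factorial 2 x 2 ANCOVA with Type-III tests and partial eta squared
#'
#' Fits a linear model with effect-coded (sum-to-zero) Group and Sex
#' factors, their interaction, a continuous covariate (Rankit-z PDS by
#' default), and sum-to-zero scan-site dummies, and returns Type-III F
#' tests for every model effect with partial eta squared
#' `F * df_effect / (F * df_effect + df_error)`.
#'
#' @param response Numeric vector, one value per design row.
#' @param design Prepared design table (see [prepare_design()]).
#' @param factor1,factor2 Names of the two crossed factor columns (defaults
#'   `group`, `sex`; the medication follow-up swaps in `medicated`).
#' @param covariates Character vector of covariate columns; factor columns
#'   enter as sum-coded dummies.
#' @return List of class `ancova_result`: `effects` data frame (`effect`,
#'   `F`, `df_effect`, `df_error`, `p`, `partial_eta_sq`),
#'   `adjusted_t` (signed t for the first level of `factor1` minus the
#'   second, adjusted for all other terms), and the fitted `model`.
#' @export
ancova_2x2 <- function(response, design, factor1 = "group", factor2 = "sex",
                       covariates = c("pds_z", "site")) {
  dat <- design
  dat$.y <- response
  if (length(response) != nrow(dat))
    stop("response length does not match design rows")
  for (v in c(factor1, factor2)) {
    dat[[v]] <- droplevels(factor(dat[[v]]))
    if (nlevels(dat[[v]]) != 2L)
      stop(sprintf("'%s' must have exactly 2 observed levels", v))
  }
  for (v in covariates)
    if (is.character(dat[[v]]) || is.logical(dat[[v]]))
      dat[[v]] <- factor(dat[[v]])
  fml <- stats::reformulate(
    c(sprintf("%s * %s", factor1, factor2), covariates), response = ".y")
  nfac <- vapply(dat[all.vars(fml)[-1]], is.factor, logical(1))
  contr <- lapply(names(nfac)[nfac], function(v) "contr.sum")
  names(contr) <- names(nfac)[nfac]
  fit <- stats::lm(fml, data = dat, contrasts = contr)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    mm <- stats::model.matrix(fit)
    aliased <- colnames(mm)[is.na(stats::coef(fit))]
    stop("singular design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  a3 <- car::Anova(fit, type = 3)
  tab <- as.data.frame(a3)
  keep <- !(rownames(tab) %in% c("(Intercept)", "Residuals"))
  df_err <- tab["Residuals", "Df"]
  eff <- data.frame(effect = rownames(tab)[keep],
                    F = tab$`F value`[keep],
                    df_effect = tab$Df[keep],
                    df_error = df_err,
                    p = tab$`Pr(>F)`[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  eff$partial_eta_sq <- eff$F * eff$df_effect /
    (eff$F * eff$df_effect + eff$df_error)
  # with contr.sum and case as first level, the factor1 coefficient is
  # (level1 - level2)/2 adjusted for all other terms
  co <- summary(fit)$coefficients
  cname <- paste0(factor1, "1")
  adj_t <- if (cname %in% rownames(co)) unname(co[cname, "t value"])
           else NA_real_
  structure(list(effects = eff, adjusted_t = adj_t, model = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  print(x$effects, digits = 4)
  invisible(x)
}

#' Post-hoc two-sample t test
#'
#' Pooled-variance t for the group difference (case minus control).  By
#' default the unadjusted two-sample statistic; with `adjusted = TRUE` the
#' t of the Group contrast from the covariate-adjusted ANCOVA model is
#' returned instead.
#'
#' @param response Numeric vector.
#' @param group Factor/vector with `case` and `control` (or any two levels;
#'   the first level minus the second).
#' @param adjusted Use the ANCOVA-adjusted contrast; requires `design`.
#' @param design Prepared design table (only for `adjusted = TRUE`).
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
posthoc_t <- function(response, group, adjusted = FALSE, design = NULL) {
  if (adjusted) {
    if (is.null(design)) stop("'design' required for the adjusted contrast")
    res <- ancova_2x2(response, design)
    i <- res$effects$effect == "group"
    return(list(t = res$adjusted_t, df = res$effects$df_error[1],
                p = res$effects$p[i],
                mean_diff = 2 * stats::coef(res$model)[["group1"]]))
  }
  g <- droplevels(factor(group))
  if (nlevels(g) != 2L) stop("need exactly 2 groups")
  x1 <- response[g == levels(g)[1]]
  x2 <- response[g == levels(g)[2]]
  if (length(x1) < 2L || length(x2) < 2L) stop("each group needs n >= 2")
  pooled_t_from_summary(mean(x1), stats::sd(x1), length(x1),
                        mean(x2), stats::sd(x2), length(x2))
}

#' Pooled-variance t from summary statistics
#'
#' Two-sample t computed from group means, SDs and sizes (group 1 minus
#' group 2), with `df = n1 + n2 - 2`.  Used both as the post-hoc test and to
#' reproduce matching statistics from published summary tables.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be >= 0")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) stop("degenerate: zero variance and equal means")
    return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p = 0,
                mean_diff = m1 - m2))
  }
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_diff = m1 - m2)
}

#' Benjamini-Hochberg step-up FDR control within a family
#'
#' The classic step-up rule: sort the p values, find the largest k with
#' `p(k) <= k * q / m`, and reject hypotheses 1..k in sorted order.
#' Families are declared by the caller (in this pipeline, one family per
#' network; an ROI belonging to two networks enters both families).
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return List with `reject` (logical, input order), `critical_index` (k,
#'   0 when nothing is rejected), and `p_critical` (the threshold
#'   `k * q / m`, 0 when nothing is rejected).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  m <- length(pvals)
  if (!m) return(list(reject = logical(0), critical_index = 0L,
                      p_critical = 0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p values must lie in [0, 1] with no missing entries")
  o <- order(pvals)
  ps <- pvals[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok))
    return(list(reject = rep(FALSE, m), critical_index = 0L, p_critical = 0))
  k <- max(ok)
  reject <- rep(FALSE, m)
  reject[o[seq_len(k)]] <- TRUE
  list(reject = reject, critical_index = k, p_critical = k * q / m)
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on the covariates (with intercept) by least
#' squares and correlates the residuals.  The p value comes from
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom, where k is the number of covariate columns after factor
#' expansion (site dummies each count).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates `NULL` (plain Pearson correlation), a numeric matrix,
#'   or a data frame (factors expand to dummies).
#' @return List of class `partial_corr`: `r`, `z` (= atanh r), `n`, `k`,
#'   `t`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    mm <- matrix(1, n, 1)
  } else {
    cdat <- as.data.frame(covariates)
    for (j in seq_along(cdat))
      if (is.character(cdat[[j]]) || is.logical(cdat[[j]]))
        cdat[[j]] <- factor(cdat[[j]])
    mm <- stats::model.matrix(~ ., data = cdat)
  }
  k <- ncol(mm) - 1L
  if (n <= k + 2L) stop("insufficient n for ", k, " covariates")
  qr_c <- qr(mm)
  if (qr_c$rank < ncol(mm))
    stop("singular covariate design (rank ", qr_c$rank, " < ", ncol(mm), ")")
  rx <- qr.resid(qr_c, x)
  ry <- qr.resid(qr_c, y)
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, z = atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)),
                 n = n, k = k, t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df)),
            class = "partial_corr")
}

#' Compare two independent partial correlations
#'
#' Fisher-z test for the difference between partial correlations estimated
#' in two independent groups sharing the same covariate count k:
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1 - k - 3) + 1/(n2 - k - 3))`,
#' referred to the standard normal (two-sided).
#'
#' @param res1,res2 [partial_correlation()] results (or lists with `r`,
#'   `n`, `k`).
#' @return List with `z`, `p`, and the group-wise inputs.
#' @export
compare_partial_corr <- function(res1, res2) {
  if (res1$k != res2$k) stop("covariate counts differ between groups")
  d1 <- res1$n - res1$k - 3L
  d2 <- res2$n - res2$k - 3L
  if (d1 <= 0 || d2 <= 0) stop("insufficient n: need n > k + 3 in each group")
  z <- (atanh(res1$r) - atanh(res2$r)) / sqrt(1 / d1 + 1 / d2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       r1 = res1$r, r2 = res2$r, n1 = res1$n, n2 = res2$n, k = res1$k)
}

#' Yates continuity-corrected chi-square for a 2 x 2 table
#'
#' `sum((|O - E| - 0.5)^2 / E)` with one degree of freedom; the correction
#' term is floored at zero when `|O - E| < 0.5`.  Used for the sex-by-group
#' matching check.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
yates_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2 x 2 table")
  if (any(tab < 0)) stop("counts must be >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square undefined")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- pmax(abs(tab - E) - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}
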