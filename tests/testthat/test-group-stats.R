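# shared fixture: a prepared design with a known-seed covariate draw
make_design <- function(n = 80, seed = 1, p_case = 0.45) {
  set.seed(seed)
  grp <- ifelse(seq_len(n) <= round(n * p_case), "case", "control")
  prepare_design(data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = grp,
    sex = sample(c("female", "male"), n, replace = TRUE),
    pds = runif(n, 1, 4),
    site = paste0("site", sample.int(3, n, replace = TRUE)),
    cbcl_adhd = rexp(n, 0.2),
    medicated = ifelse(grp == "case", runif(n) < 0.5, NA)))
}

test_that("Rankit transform maps ranks through the normal quantile and standardizes", {
  expect_equal(rankit_z(c(1.2, 3.1, 5.0)), c(-1, 0, 1))
  raw <- qnorm((1:3 - 0.5) / 3)
  expect_equal(rankit_z(c(1.2, 3.1, 5.0)) * sd(raw), raw)
  set.seed(2)
  x <- rexp(50)
  expect_equal(rankit_z(x), rankit_z(log(x)))        # monotone invariance
  expect_equal(rankit_z(rev(x)), rev(rankit_z(x)))
  expect_equal(mean(rankit_z(x)), 0)
  expect_equal(sd(rankit_z(x)), 1)
  expect_error(rankit_z(rep(2, 10)), "identical")
})

test_that("Yates chi-square reproduces the continuity-corrected statistic", {
  res <- yates_chi2(matrix(c(25, 38, 29, 63), 2, byrow = TRUE))
  expect_equal(res$chi2,
               unname(chisq.test(matrix(c(25, 38, 29, 63), 2, byrow = TRUE),
                                 correct = TRUE)$statistic))
  expect_equal(yates_chi2(matrix(10, 2, 2))$chi2, 0)
  tab <- matrix(c(7, 12, 20, 5), 2)
  expect_equal(yates_chi2(tab)$chi2, yates_chi2(t(tab))$chi2)
  expect_error(yates_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("pooled t from summary moments matches t.test on raw data", {
  set.seed(3)
  x <- rnorm(20, 1); y <- rnorm(30)
  res <- pooled_t_from_summary(mean(x), sd(x), 20, mean(y), sd(y), 30)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$df, 48)
  expect_equal(pooled_t_from_summary(1, 1, 10, 1, 2, 10)$t, 0)
})

test_that("post-hoc t is the pooled two-sample statistic and flips with labels", {
  set.seed(4)
  d <- make_design(40)
  y <- rnorm(40)
  res <- posthoc_t(y, d$group)
  ref <- t.test(y[d$group == "case"], y[d$group == "control"],
                var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  flipped <- factor(d$group, levels = c("control", "case"))
  expect_equal(posthoc_t(y, flipped)$t, -res$t)
  expect_equal(posthoc_t(c(y, y), factor(rep(c("a", "b"), each = 40)))$t, 0)
  expect_error(posthoc_t(y[1:3], factor(c("a", "a", "b"))), "n >= 2")
})

test_that("BH step-up matches worked examples, the naive rule, and p.adjust", {
  r1 <- bh_fdr(c(0.001, 0.013, 0.02, 0.04), 0.05)
  expect_true(all(r1$reject))
  expect_equal(r1$critical_index, 4L)
  r2 <- bh_fdr(c(0.04, 0.5), 0.05)
  expect_false(any(r2$reject))
  expect_true(all(bh_fdr(rep(0, 5), 0.05)$reject))
  expect_equal(bh_fdr(numeric(0), 0.05)$reject, logical(0))
  set.seed(5)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)$reject
    expect_identical(got, naive_bh(p, q))
    expect_identical(got, p.adjust(p, "BH") <= q)
  }
})

test_that("partial correlation equals the precision-matrix oracle and reduces to Pearson", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    k <- sample(1:4, 1)
    C <- matrix(rnorm(n * k), n)
    x <- rnorm(n) + C %*% rnorm(k)
    y <- rnorm(n) + C %*% rnorm(k)
    got <- partial_correlation(as.numeric(x), as.numeric(y), C)
    expect_equal(got$r, precision_partial_corr(as.numeric(x), as.numeric(y), C),
                 tolerance = 1e-10)
    expect_equal(got$k, k)
    expect_equal(got$df, n - 2 - k)
  }
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partial_correlation(x, y)$r, cor(x, y))
  expect_equal(partial_correlation(x, y)$p, cor.test(x, y)$p.value)
})

test_that("conditioning on a shared covariate removes spurious correlation", {
  set.seed(7)
  n <- 10000
  c0 <- rnorm(n)
  x <- c0 + rnorm(n)
  y <- c0 + rnorm(n)
  expect_gt(cor(x, y), 0.4)
  expect_lt(abs(partial_correlation(x, y, cbind(c0))$r), 0.03)
})

test_that("factor covariates expand to dummies in partial correlations", {
  set.seed(8)
  d <- make_design(60)
  x <- rnorm(60); y <- rnorm(60)
  res <- partial_correlation(x, y, d[, c("sex", "pds_z", "site")])
  expect_equal(res$k, 1L + 1L + (nlevels(d$site) - 1L))
  mm <- model.matrix(~ sex + pds_z + site, d)[, -1]
  expect_equal(res$r, precision_partial_corr(x, y, mm), tolerance = 1e-10)
})

test_that("two-group comparison of partial correlations follows the Fisher-z formula", {
  r1 <- list(r = 0.5, n = 63, k = 3)
  r2 <- list(r = 0.0, n = 92, k = 3)
  cmp <- compare_partial_corr(r1, r2)
  expect_equal(cmp$z, atanh(0.5) / sqrt(1 / 57 + 1 / 86))
  expect_equal(cmp$z, 3.216, tolerance = 1e-3)
  expect_equal(compare_partial_corr(r1, r1)$z, 0)
  expect_equal(compare_partial_corr(r2, r1)$z, -cmp$z)
  expect_error(compare_partial_corr(r1, list(r = 0, n = 92, k = 2)),
               "covariate")
  expect_error(compare_partial_corr(list(r = 0.1, n = 6, k = 3), r2),
               "insufficient")
})

test_that("ANCOVA returns Type-III tests with the partial eta-squared identity", {
  set.seed(9)
  d <- make_design(100)
  y <- rnorm(100) + 0.5 * (d$group == "case") + 0.3 * d$pds_z
  res <- ancova_2x2(y, d)
  eff <- res$effects
  expect_setequal(eff$effect, c("group", "sex", "group:sex", "pds_z", "site"))
  expect_equal(eff$partial_eta_sq,
               eff$F * eff$df_effect / (eff$F * eff$df_effect + eff$df_error))
  # 1-df Type-III F equals the squared adjusted-contrast t
  i <- eff$effect == "group"
  expect_equal(eff$F[i], res$adjusted_t^2)
  # adjusted contrast agrees with the posthoc adjusted variant
  expect_equal(posthoc_t(y, d$group, adjusted = TRUE, design = d)$t,
               res$adjusted_t)
  expect_error(ancova_2x2(y[1:50], d), "length")
})

test_that("ANCOVA Type-III F values agree with an independent drop-one refit", {
  # SS_effect = RSS(model without the term, effect-coded) - RSS(full)
  set.seed(10)
  d <- make_design(90)
  y <- rnorm(90)
  res <- ancova_2x2(y, d)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  full <- lm(.y ~ group * sex + pds_z + site, data = cbind(d, .y = y))
  red <- lm(.y ~ group * sex + site, data = cbind(d, .y = y))  # drop pds_z
  ss <- sum(residuals(red)^2) - sum(residuals(full)^2)
  Fref <- ss / (sum(residuals(full)^2) / full$df.residual)
  i <- res$effects$effect == "pds_z"
  expect_equal(res$effects$F[i], Fref)
})

test_that("singular designs are reported with the aliased column", {
  set.seed(11)
  d <- make_design(50)
  d$dup <- d$pds_z
  y <- rnorm(50)
  expect_error(ancova_2x2(y, d, covariates = c("pds_z", "dup", "site")),
               "aliased|singular")
})

test_that("design preparation validates and augments the table", {
  d <- make_design(30)
  expect_true(all(c("pds_z", "cbcl_z") %in% names(d)))
  expect_equal(levels(d$group), c("case", "control"))
  expect_equal(mean(d$pds_z), 0, tolerance = 1e-12)
  raw <- data.frame(subject_id = "a", group = "case", sex = "female",
                    pds = 2, site = "s1")
  expect_error(prepare_design(raw), "cbcl_adhd")
  bad <- make_design(20)
  bad$group <- as.character(bad$group); bad$group[1] <- "patient"
  expect_error(prepare_design(bad), "case")
})
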