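#' Analysis configuration
#'
#' Tunables shared by the pipeline stages: entropy parameters, the FDR
#' level, the covariates entering the ANCOVAs and partial correlations, and
#' toggles for the scale-wise variants and for an optional global (rather
#' than per-network) FDR family that also covers cross-network units.
#'
#' @param entropy An [entropy_params()] object.
#' @param q Target false discovery rate in `(0, 1)`.
#' @param covariates Covariate columns for the ANCOVAs.
#' @param pc_covariates Covariate columns for partial correlations.
#' @param scalewise Also run the per-scale SampEn analyses.
#' @param symptom_score Column holding the (transformed) symptom score used
#'   in partial correlations; `cbcl_z` is the Rankit+z copy.
#' @param global_fdr Correct all units in one family instead of per network
#'   (covers cross-network edges/linkages, which per-network families skip).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(entropy = entropy_params(), q = 0.05,
                            covariates = c("pds_z", "site"),
                            pc_covariates = c("sex", "pds_z", "site"),
                            scalewise = TRUE, symptom_score = "cbcl_z",
                            global_fdr = FALSE) {
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  stopifnot(inherits(entropy, "entropy_params"))
  structure(list(entropy = entropy, q = q, covariates = covariates,
                 pc_covariates = pc_covariates, scalewise = scalewise,
                 symptom_score = symptom_score, global_fdr = global_fdr),
            class = "analysis_config")
}

#' Per-subject run-averaged entropy over a cohort
#'
#' Computes the multiscale entropy profile of every ROI series in every
#' run and averages profiles across runs per subject.
#'
#' @param panels Per-subject list of per-run [roi_panel()]s (as in a
#'   [simulate_cohort()] result).
#' @param params An [entropy_params()] object.
#' @return List with `mse` (subjects x ROIs matrix) and `sampen`
#'   (subjects x ROIs x scales array); dimnames carry ROI ids.
#' @export
cohort_entropy <- function(panels, params = entropy_params()) {
  S <- length(panels)
  ids <- as.character(panels[[1]][[1]]$roi_ids)
  R <- length(ids); a <- params$scales
  mse <- matrix(NA_real_, S, R, dimnames = list(NULL, ids))
  sampen <- array(NA_real_, c(S, R, a), dimnames = list(NULL, ids, NULL))
  for (s in seq_len(S)) {
    for (j in seq_len(R)) {
      profs <- lapply(panels[[s]], function(p)
        suppressWarnings(multiscale_entropy(p$mat[, j], params)))
      avg <- average_runs(profs)
      mse[s, j] <- avg$mse
      sampen[s, j, ] <- avg$sampen
    }
  }
  list(mse = mse, sampen = sampen)
}

#' Per-subject run-combined connectivity over a cohort
#'
#' @param panels Per-subject list of per-run [roi_panel()]s.
#' @return Subjects x ROI x ROI array of run-averaged Fisher-z values.
#' @export
cohort_fc <- function(panels) {
  S <- length(panels)
  ids <- as.character(panels[[1]][[1]]$roi_ids)
  R <- length(ids)
  z <- array(NA_real_, c(S, R, R), dimnames = list(NULL, ids, ids))
  for (s in seq_len(S)) {
    fc <- combine_runs_fc(lapply(panels[[s]], fc_matrix))
    z[s, , ] <- fc$z_matrix
  }
  z
}

# run the Group (or other factor) ANCOVA across the columns of a value
# matrix and return one row per column.  Shares one QR decomposition of the
# (common) design matrix across units: for a 1-df effect under sum-to-zero
# coding the Type-III F is the squared t of the factor's coefficient, which
# ancova_2x2 reproduces unit-by-unit (asserted in the test suite).
ancova_over_units <- function(values, design, factor1, config) {
  values <- as.matrix(values)
  dat <- design
  for (v in c(factor1, "sex")) {
    dat[[v]] <- droplevels(factor(dat[[v]]))
    if (nlevels(dat[[v]]) != 2L)
      stop(sprintf("'%s' must have exactly 2 observed levels", v))
  }
  fml <- stats::reformulate(c(sprintf("%s * sex", factor1),
                              config$covariates))
  vars <- all.vars(fml)
  isfac <- vapply(dat[vars], is.factor, logical(1))
  contr <- stats::setNames(as.list(rep("contr.sum", sum(isfac))),
                           vars[isfac])
  mm <- stats::model.matrix(fml, dat, contrasts.arg = contr)
  jj <- match(paste0(factor1, "1"), colnames(mm))
  fit_block <- function(X, Y) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) stop("singular design in batch ANCOVA")
    df_err <- nrow(X) - qrx$rank
    coefs <- qr.coef(qrx, Y)
    if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
    s2 <- colSums(qr.resid(qrx, Y)^2) / df_err
    tval <- coefs[jj, ] / sqrt(s2 * chol2inv(chol(crossprod(X)))[jj, jj])
    F <- tval^2
    data.frame(F = unname(F), df_effect = 1L, df_error = df_err,
               p = unname(stats::pf(F, 1, df_err, lower.tail = FALSE)),
               partial_eta_sq = unname(F / (F + df_err)),
               t_adjusted = unname(tval))
  }
  has_na <- colSums(is.na(values)) > 0L
  out <- data.frame(F = rep(NA_real_, ncol(values)), df_effect = 1L,
                    df_error = NA_real_, p = NA_real_,
                    partial_eta_sq = NA_real_, t_adjusted = NA_real_)
  if (any(!has_na))
    out[!has_na, ] <- fit_block(mm, values[, !has_na, drop = FALSE])
  for (j in which(has_na)) {
    # per-unit complete cases (e.g. undefined SampEn at a coarse scale);
    # units whose reduced design degenerates stay NA
    ok <- !is.na(values[, j])
    if (sum(ok) <= ncol(mm) + 1L) next
    out[j, ] <- tryCatch(
      fit_block(mm[ok, , drop = FALSE], values[ok, j, drop = FALSE]),
      error = function(e) out[j, ])
  }
  out
}

# unadjusted pooled t per column, complete cases (NA when a group drops
# below n = 2 after removing undefined entries)
unit_posthoc_t <- function(values, group) {
  vapply(seq_len(ncol(values)), function(j) {
    ok <- !is.na(values[, j])
    g <- droplevels(factor(group[ok]))
    if (nlevels(g) < 2L || min(table(g)) < 2L) return(NA_real_)
    posthoc_t(values[ok, j], group[ok])$t
  }, numeric(1))
}

# partial correlation of each column with a score, complete cases per column
unit_partial_corr <- function(values, score, covariates) {
  k_cols <- ncol(stats::model.matrix(~ ., data = covariates))
  res <- vapply(seq_len(ncol(values)), function(j) {
    ok <- !is.na(values[, j])
    if (sum(ok) <= k_cols + 2L) return(c(NA_real_, NA_real_))
    tryCatch({
      pc <- partial_correlation(values[ok, j], score[ok],
                                droplevels(covariates[ok, , drop = FALSE]))
      c(pc$r, pc$p)
    }, error = function(e) c(NA_real_, NA_real_))
  }, numeric(2))
  list(r = res[1, ], p = res[2, ])
}

# per-network BH families over a result table with columns `network`
# (semicolon-separated memberships or "cross") and `p`; cross-network rows
# stay NA under per-network correction
apply_network_fdr <- function(tab, q, global = FALSE) {
  sig <- rep(NA, nrow(tab))
  defined <- !is.na(tab$p)
  if (global) {
    sig[defined] <- bh_fdr(tab$p[defined], q)$reject
  } else {
    fams <- unique(unlist(strsplit(tab$network[tab$network != "cross"], ";")))
    sig[tab$network != "cross" & defined] <- FALSE
    for (f in fams) {
      idx <- which(defined & vapply(strsplit(tab$network, ";"),
                                    function(s) f %in% s, logical(1)))
      if (length(idx))
        sig[idx] <- sig[idx] | bh_fdr(tab$p[idx], q)$reject
    }
  }
  tab$sig_fdr <- sig
  tab
}

roi_network_string <- function(network_map) network_map$networks

#' Group comparison of regional complexity
#'
#' Stage 1 of the pipeline: run-averaged MSE per ROI enters a
#' Group-by-Sex ANCOVA with the configured covariates; Type-III Group F,
#' p and partial eta squared are corrected per network by
#' Benjamini-Hochberg; unadjusted post-hoc case-minus-control t values and
#' group means are attached; the whole-sample partial correlation of MSE
#' with the transformed symptom score (controlling sex, PDS-z, site) is
#' appended.  With `scalewise = TRUE` the same analysis is repeated for
#' SampEn at each temporal scale.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `panels` and
#'   a prepared `design`.
#' @param config An [analysis_config()].
#' @param entropy Optional precomputed [cohort_entropy()] result (reused by
#'   the linkage stage to avoid recomputation).
#' @return Data frame, one row per (measure, scale, ROI): columns
#'   `measure` (`"mse"`/`"sampen"`), `scale` (`NA` for MSE), `roi_id`,
#'   `label`, `network`, the ANCOVA columns, `sig_fdr`, `t_posthoc`,
#'   `mean_case`, `mean_control`, `cbcl_r`, `cbcl_p`.
#' @export
run_complexity_analysis <- function(cohort, config = analysis_config(),
                                    entropy = NULL) {
  nm <- cohort$config$network_map %||% default_network_map()
  design <- cohort$design
  if (is.null(entropy))
    entropy <- cohort_entropy(cohort$panels, config$entropy)
  cc <- design[, config$pc_covariates, drop = FALSE]
  score <- design[[config$symptom_score]]
  one_block <- function(values, measure, scale) {
    tab <- ancova_over_units(values, design, "group", config)
    tab <- cbind(data.frame(measure = measure, scale = scale,
                            roi_id = nm$roi_id, label = nm$label,
                            network = roi_network_string(nm),
                            stringsAsFactors = FALSE), tab)
    tab$t_posthoc <- unit_posthoc_t(values, design$group)
    tab$mean_case <- colMeans(values[design$group == "case", , drop = FALSE],
                              na.rm = TRUE)
    tab$mean_control <- colMeans(values[design$group == "control", ,
                                        drop = FALSE], na.rm = TRUE)
    pc <- unit_partial_corr(values, score, cc)
    tab$cbcl_r <- pc$r
    tab$cbcl_p <- pc$p
    apply_network_fdr(tab, config$q, config$global_fdr)
  }
  out <- one_block(entropy$mse, "mse", NA_integer_)
  if (config$scalewise) {
    for (s in seq_len(config$entropy$scales))
      out <- rbind(out, one_block(entropy$sampen[, , s], "sampen", s))
  }
  rownames(out) <- NULL
  out
}

#' Group comparison of seed-to-seed functional connectivity
#'
#' Stage 2: run-averaged Fisher-z per edge enters the same Group-by-Sex
#' ANCOVA; per-network BH families cover within-network edges (an edge
#' belongs to a network when both endpoints do); cross-network edges are
#' reported but only corrected in `global_fdr` mode.  Post-hoc t, group
#' means, and the symptom-score partial correlation per edge are attached.
#'
#' @inheritParams run_complexity_analysis
#' @param fcz Optional precomputed [cohort_fc()] array.
#' @return Data frame, one row per unordered edge.
#' @export
run_fc_analysis <- function(cohort, config = analysis_config(), fcz = NULL) {
  nm <- cohort$config$network_map %||% default_network_map()
  design <- cohort$design
  if (is.null(fcz)) fcz <- cohort_fc(cohort$panels)
  R <- nrow(nm)
  idx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  values <- vapply(seq_len(nrow(idx)), function(e)
    fcz[, idx[e, 1], idx[e, 2]], numeric(dim(fcz)[1]))
  sets <- network_sets(nm)
  net <- vapply(seq_len(nrow(idx)), function(e) {
    shared <- intersect(sets[[idx[e, 1]]], sets[[idx[e, 2]]])
    if (length(shared)) paste(shared, collapse = ";") else "cross"
  }, character(1))
  tab <- ancova_over_units(values, design, "group", config)
  tab <- cbind(data.frame(roi_a = nm$roi_id[idx[, 1]],
                          roi_b = nm$roi_id[idx[, 2]],
                          label_a = nm$label[idx[, 1]],
                          label_b = nm$label[idx[, 2]],
                          network = net, stringsAsFactors = FALSE), tab)
  tab$t_posthoc <- unit_posthoc_t(values, design$group)
  tab$mean_case <- colMeans(values[design$group == "case", , drop = FALSE],
                            na.rm = TRUE)
  tab$mean_control <- colMeans(values[design$group == "control", ,
                                      drop = FALSE], na.rm = TRUE)
  cc <- design[, config$pc_covariates, drop = FALSE]
  score <- design[[config$symptom_score]]
  pc <- unit_partial_corr(values, score, cc)
  tab$cbcl_r <- pc$r
  tab$cbcl_p <- pc$p
  tab <- apply_network_fdr(tab, config$q, config$global_fdr)
  rownames(tab) <- NULL
  tab
}

#' Complexity-connectivity linkage analysis
#'
#' Stage 3: for every directional linkage (seed ROI, seed-to-partner edge),
#' the partial correlation between the seed's complexity (MSE, and
#' optionally SampEn per scale) and the edge's Fisher-z is estimated within
#' each group, controlling for sex, PDS-z and site; the two group
#' correlations are then compared with the Fisher-z difference test.
#' Per-network BH families (seed and partner both in the network) are
#' applied separately to each group's p values and to the
#' between-group p values; cross-network linkages are reported uncorrected
#' unless `global_fdr` is set.
#'
#' @inheritParams run_complexity_analysis
#' @param fcz Optional precomputed [cohort_fc()] array.
#' @return Data frame, one row per (measure, scale, directional linkage).
#' @export
run_linkage_analysis <- function(cohort, config = analysis_config(),
                                 entropy = NULL, fcz = NULL) {
  nm <- cohort$config$network_map %||% default_network_map()
  design <- cohort$design
  if (is.null(entropy))
    entropy <- cohort_entropy(cohort$panels, config$entropy)
  if (is.null(fcz)) fcz <- cohort_fc(cohort$panels)
  R <- nrow(nm)
  sets <- network_sets(nm)
  g_case <- design$group == "case"
  cc <- design[, config$pc_covariates, drop = FALSE]
  k_req <- ncol(stats::model.matrix(~ ., data = cc)) - 1L
  if (min(sum(g_case), sum(!g_case)) <= k_req + 3L)
    stop("insufficient subjects per group for ", k_req, " covariates")
  pairs <- expand.grid(seed = seq_len(R), partner = seq_len(R))
  pairs <- pairs[pairs$seed != pairs$partner, ]
  one_block <- function(cmplx, measure, scale) {
    rows <- lapply(seq_len(nrow(pairs)), function(e) {
      s <- pairs$seed[e]; p <- pairs$partner[e]
      edge <- fcz[, s, p]
      ok <- !is.na(cmplx[, s]) & !is.na(edge)
      grp_pc <- function(sel) {
        sel <- sel & ok
        partial_correlation(cmplx[sel, s], edge[sel],
                            droplevels(cc[sel, , drop = FALSE]))
      }
      est <- tryCatch({
        p1 <- grp_pc(g_case)
        p2 <- grp_pc(!g_case)
        list(p1 = p1, p2 = p2, cmp = compare_partial_corr(p1, p2))
      }, error = function(e) {
        # insufficient complete cases in a group: skip this linkage
        na <- list(r = NA_real_, p = NA_real_)
        list(p1 = na, p2 = na, cmp = list(z = NA_real_, p = NA_real_))
      })
      p1 <- est$p1; p2 <- est$p2; cmp <- est$cmp
      shared <- intersect(sets[[s]], sets[[p]])
      data.frame(measure = measure, scale = scale,
                 seed_roi = nm$roi_id[s], partner_roi = nm$roi_id[p],
                 seed_label = nm$label[s], partner_label = nm$label[p],
                 network = if (length(shared)) paste(shared, collapse = ";")
                           else "cross",
                 r_case = p1$r, p_case = p1$p,
                 r_control = p2$r, p_control = p2$p,
                 z_diff = cmp$z, p = cmp$p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    for (col in c("p_case", "p_control")) {
      tmp <- tab; tmp$p <- tab[[col]]
      tab[[sub("^p", "sig_fdr", col)]] <-
        apply_network_fdr(tmp, config$q, config$global_fdr)$sig_fdr
    }
    apply_network_fdr(tab, config$q, config$global_fdr)
  }
  out <- one_block(entropy$mse, "mse", NA_integer_)
  if (config$scalewise) {
    for (s in seq_len(config$entropy$scales))
      out <- rbind(out, one_block(entropy$sampen[, , s], "sampen", s))
  }
  rownames(out) <- NULL
  out
}

#' Medication follow-up ANCOVA within cases
#'
#' Stage 4: restricted to case subjects, repeats the factorial ANCOVA with
#' Medication (medicated vs. non-medicated) replacing Group, for regional
#' MSE, per-scale SampEn (when `scalewise`), and edge-wise connectivity.
#'
#' @inheritParams run_complexity_analysis
#' @param fcz Optional precomputed [cohort_fc()] array.
#' @return Data frame with the same schema as the primary analyses, with
#'   `unit` marking `roi` vs `edge` rows.
#' @export
run_medication_followup <- function(cohort, config = analysis_config(),
                                    entropy = NULL, fcz = NULL) {
  design <- cohort$design
  cases <- which(design$group == "case")
  med <- design$medicated[cases]
  if (anyNA(med)) stop("missing medication flags among cases")
  if (length(unique(med)) < 2L)
    stop("medication follow-up needs both medicated and non-medicated cases")
  nm <- cohort$config$network_map %||% default_network_map()
  if (is.null(entropy))
    entropy <- cohort_entropy(cohort$panels, config$entropy)
  if (is.null(fcz)) fcz <- cohort_fc(cohort$panels)
  dsub <- design[cases, ]
  dsub$medicated <- factor(ifelse(dsub$medicated, "medicated",
                                  "non_medicated"),
                           levels = c("medicated", "non_medicated"))
  dsub$site <- droplevels(dsub$site)
  sub_cfg <- config
  roi_block <- function(values, measure, scale) {
    tab <- ancova_over_units(values, dsub, "medicated", sub_cfg)
    cbind(data.frame(unit = "roi", measure = measure, scale = scale,
                     roi_id = nm$roi_id, label = nm$label,
                     network = roi_network_string(nm),
                     stringsAsFactors = FALSE), tab)
  }
  out <- roi_block(entropy$mse[cases, , drop = FALSE], "mse", NA_integer_)
  if (config$scalewise) {
    for (s in seq_len(config$entropy$scales))
      out <- rbind(out, roi_block(entropy$sampen[cases, , s], "sampen", s))
  }
  out <- apply_network_fdr(out, config$q, config$global_fdr)
  R <- nrow(nm)
  idx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  values <- vapply(seq_len(nrow(idx)), function(e)
    fcz[cases, idx[e, 1], idx[e, 2]], numeric(length(cases)))
  sets <- network_sets(nm)
  net <- vapply(seq_len(nrow(idx)), function(e) {
    shared <- intersect(sets[[idx[e, 1]]], sets[[idx[e, 2]]])
    if (length(shared)) paste(shared, collapse = ";") else "cross"
  }, character(1))
  ftab <- ancova_over_units(values, dsub, "medicated", sub_cfg)
  ftab <- cbind(data.frame(unit = "edge", measure = "fc_z",
                           scale = NA_integer_,
                           roi_id = nm$roi_id[idx[, 1]],
                           label = paste(nm$label[idx[, 1]],
                                         nm$label[idx[, 2]], sep = "-"),
                           network = net, stringsAsFactors = FALSE), ftab)
  ftab <- apply_network_fdr(ftab, config$q, config$global_fdr)
  out <- rbind(out, ftab)
  rownames(out) <- NULL
  out
}

#' Framewise displacement quality control
#'
#' Power-convention framewise displacement: the sum of absolute
#' frame-to-frame differences of the three translations (mm) and of the
#' three rotations (radians) converted to arc length on a 50 mm sphere.
#' Per-subject mean FD is compared between groups with a pooled two-sample
#' t test, per run.
#'
#' @param motion Per-subject list; each element a per-run list of
#'   timepoints x 6 matrices (columns: 3 translations in mm, 3 rotations in
#'   radians).
#' @param design Prepared design table (row i matches `motion[[i]]`).
#' @param radius Rotation-to-displacement conversion radius in mm.
#' @return List with `fd` (subjects x runs matrix of mean FD) and
#'   `tests` (per-run data frame: `t`, `df`, `p`).
#' @export
qc_framewise_displacement <- function(motion, design, radius = 50) {
  stopifnot(length(motion) == nrow(design))
  n_runs <- length(motion[[1]])
  fd <- t(vapply(motion, function(runs)
    vapply(runs, function(m) mean(framewise_displacement(m, radius)),
           numeric(1)), numeric(n_runs)))
  if (n_runs == 1L) fd <- matrix(fd, ncol = 1L)
  tests <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    tt <- posthoc_t(fd[, r], design$group)
    data.frame(run = r, t = tt$t, df = tt$df, p = tt$p)
  }))
  list(fd = fd, tests = tests)
}

#' Per-frame framewise displacement
#'
#' @param params Timepoints x 6 matrix (3 translations mm, 3 rotations rad).
#' @param radius Sphere radius in mm for rotation conversion.
#' @return Numeric vector of per-frame FD (first frame 0).
#' @export
framewise_displacement <- function(params, radius = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    stop("expected 6 motion parameter columns (3 translations, 3 rotations)")
  if (anyNA(params) || !all(is.finite(params)))
    stop("non-finite motion parameters")
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}
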