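#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic two-group, two-run ROI time-series
#' cohort: 63 cases and 92 controls, two runs of 383 timepoints at
#' TR = 0.8 s over the 17-region, three-network layout.  Each ROI series is
#' a shared band-limited (1/f-shaped) network signal scaled by a loading,
#' plus AR(1) noise of fixed marginal SD, plus white noise.  Cases receive
#' an AR(1)-coefficient increment in FPN ROIs (`complexity_effect`); the
#' default is negative, stripping temporal structure at constant variance,
#' which lowers coarse-scale SampEn and hence the multi-scale MSE mean
#' (under a fixed tolerance, correlated noise has higher coarse-scale
#' entropy than white noise, so reduced complexity means a less
#' autocorrelated signal).  Cases also receive an extra shared-signal
#' loading (`fc_effect`) on the AC-R.SFG and AC-L.MidFG edges, which raises
#' their connectivity.  Covariate and
#' symptom-score moments follow the cohort's published matching table.
#'
#' @param n_case,n_control Group sizes.
#' @param n_timepoints,tr,n_runs Acquisition geometry per run.
#' @param network_map ROI table ([default_network_map()]).
#' @param n_sites Number of scan sites (uniform assignment).
#' @param complexity_effect AR(1) coefficient increment for case FPN ROIs.
#' @param fc_effect Loading increment on the two implanted edges for cases.
#' @param lambda,lambda_sd Network-signal loading mean and between-subject SD.
#' @param phi,phi_sd Baseline AR(1) coefficient mean and between-subject SD.
#' @param ar_sd Marginal SD of the AR(1) noise (innovations are scaled by
#'   `sqrt(1 - phi^2)` so the marginal SD does not depend on phi).
#' @param white_sd SD of the white-noise component.
#' @param cbcl_case,cbcl_control,pds_case,pds_control Mean/SD pairs for the
#'   symptom score and pubertal development score per group.
#' @param p_female_case,p_female_control Female proportions per group.
#' @param fc_edge_labels Two-column character matrix of implanted edges.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 63L, n_control = 92L,
                              n_timepoints = 383L, tr = 0.8, n_runs = 2L,
                              network_map = default_network_map(),
                              n_sites = 4L,
                              complexity_effect = -0.3, fc_effect = 0.5,
                              lambda = 0.7, lambda_sd = 0.1,
                              phi = 0.45, phi_sd = 0.05,
                              ar_sd = 1, white_sd = 0.5,
                              cbcl_case = c(5.412, 2.152),
                              cbcl_control = c(1.228, 1.570),
                              pds_case = c(1.665, 0.542),
                              pds_control = c(1.687, 0.522),
                              p_female_case = 25 / 63,
                              p_female_control = 29 / 92,
                              fc_edge_labels = rbind(c("AC", "SFG.R"),
                                                     c("AC", "MidFG.L"))) {
  stopifnot(n_case >= 1, n_control >= 1, n_timepoints >= 8, tr > 0,
            n_runs >= 1, n_sites >= 1, ar_sd > 0, white_sd > 0,
            abs(phi) < 1, abs(phi + complexity_effect) < 1)
  fc_edge_labels <- as.matrix(fc_edge_labels)
  if (!identical(dim(fc_edge_labels), c(2L, 2L)))
    stop("'fc_edge_labels' must be a 2 x 2 matrix (two edges)")
  miss <- setdiff(as.vector(fc_edge_labels), network_map$label)
  if (length(miss)) stop("unknown ROI labels in fc_edge_labels: ",
                         paste(miss, collapse = ", "))
  structure(mget(names(formals()), environment()),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d cases / %d controls, %d run(s) of ",
                     "%d timepoints (TR %g s), %d ROIs, %d sites\n"),
              x$n_case, x$n_control, x$n_runs, x$n_timepoints, x$tr,
              nrow(x$network_map), x$n_sites))
  invisible(x)
}

#' Band-limited 1/f-shaped ("pink") Gaussian noise
#'
#' White Gaussian noise spectrally reshaped so that power falls off as 1/f
#' (amplitude as f^-1/2), then standardized to mean 0 and SD 1.  This is the
#' shared network signal of the generator: slow, autocorrelated fluctuations
#' resembling resting-state BOLD co-activation.
#'
#' @param n Series length.
#' @return Numeric vector of length `n`, unit SD.
#' @export
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) / n      # two-sided frequency axis
  f[1] <- 1 / n                # DC treated as the lowest resolvable band
  f[f == 0] <- 1 / n
  shaped <- Re(stats::fft(W / sqrt(f), inverse = TRUE)) / n
  as.numeric(scale(shaped))
}

ar1_noise <- function(n, phi, marginal_sd) {
  innov_sd <- marginal_sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

primary_network <- function(network_map) {
  vapply(network_sets(network_map), `[[`, character(1), 1L)
}

draw_subject_params <- function(config, is_case) {
  nm <- config$network_map
  R <- nrow(nm)
  lambda <- stats::rnorm(R, config$lambda, config$lambda_sd)
  phi <- pmin(pmax(stats::rnorm(R, config$phi, config$phi_sd), -0.9), 0.9)
  in_fpn <- vapply(network_sets(nm), function(s) "FPN" %in% s, logical(1))
  if (is_case)
    phi[in_fpn] <- pmin(pmax(phi[in_fpn] + config$complexity_effect, -0.95),
                        0.95)
  list(lambda = lambda, phi = phi)
}

#' Simulate one subject's ROI time-series panels
#'
#' Draws the subject's per-ROI loadings and AR(1) coefficients once, then
#' generates `n_runs` independent runs: for each network a fresh shared
#' 1/f signal, plus (for cases) the two edge-specific shared signals that
#' implant the connectivity effect, plus AR(1) and white noise per ROI.
#'
#' @param config A [simulation_config()].
#' @param is_case Logical; case subjects receive the implanted effects.
#' @param subject_id Identifier stored in the panels.
#' @param params Optional pre-drawn subject parameters (internal reuse).
#' @return List with `panels` (list of [roi_panel()], one per run) and
#'   `truth` (one-row data frame of implanted parameters).
#' @export
simulate_subject <- function(config, is_case, subject_id = NA,
                             params = NULL) {
  nm <- config$network_map
  R <- nrow(nm); n <- config$n_timepoints
  if (is.null(params)) params <- draw_subject_params(config, is_case)
  pn <- primary_network(nm)
  nets <- unique(unlist(network_sets(nm)))
  e1 <- match(config$fc_edge_labels[1, ], nm$label)
  e2 <- match(config$fc_edge_labels[2, ], nm$label)
  mu <- if (is_case) config$fc_effect else 0
  panels <- lapply(seq_len(config$n_runs), function(run) {
    g <- vapply(nets, function(nt) pink_noise(n), numeric(n))
    colnames(g) <- nets
    h1 <- pink_noise(n); h2 <- pink_noise(n)
    mat <- vapply(seq_len(R), function(i) {
      x <- params$lambda[i] * g[, pn[i]] +
        ar1_noise(n, params$phi[i], config$ar_sd) +
        stats::rnorm(n, sd = config$white_sd)
      if (mu > 0) {
        if (i == e1[1] || i == e2[1]) {
          if (i == e1[1]) x <- x + mu * h1
          if (i == e2[1]) x <- x + mu * h2
        }
        if (i == e1[2]) x <- x + mu * h1
        if (i == e2[2]) x <- x + mu * h2
      }
      x
    }, numeric(n))
    roi_panel(mat, nm$roi_id, tr = config$tr,
              subject_id = subject_id, run = run)
  })
  truth <- data.frame(subject_id = subject_id,
                      group = if (is_case) "case" else "control",
                      t(stats::setNames(params$lambda,
                                        paste0("lambda.", nm$label))),
                      t(stats::setNames(params$phi,
                                        paste0("phi.", nm$label))),
                      fc_effect = mu, check.names = FALSE)
  list(panels = panels, truth = truth)
}

rnorm_clipped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a full two-group cohort
#'
#' Generates the design table (group, sex, PDS, scan site, CBCL-like
#' symptom score, medication flag among cases) and the per-subject, per-run
#' ROI panels, together with the ground-truth parameter table used for
#' recovery checks.  Sex is Bernoulli per group at the published female
#' proportions; PDS is normal with per-group published moments, clipped to
#' [1, 4]; sites are uniform; symptom scores are normal with per-group
#' published moments, clipped at 0.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed for exact reproducibility.
#' @return List of class `synthetic_cohort`: `panels` (per subject, a list
#'   of per-run [roi_panel()]s), `design` (prepared design table), `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_tot <- config$n_case + config$n_control
  grp <- rep(c("case", "control"), c(config$n_case, config$n_control))
  pf <- ifelse(grp == "case", config$p_female_case, config$p_female_control)
  sex <- ifelse(stats::rbinom(n_tot, 1, pf) == 1, "female", "male")
  pds <- ifelse(grp == "case",
                rnorm_clipped(n_tot, config$pds_case[1], config$pds_case[2],
                              1, 4),
                rnorm_clipped(n_tot, config$pds_control[1],
                              config$pds_control[2], 1, 4))
  site <- paste0("site", sample.int(config$n_sites, n_tot, replace = TRUE))
  cbcl <- ifelse(grp == "case",
                 rnorm_clipped(n_tot, config$cbcl_case[1],
                               config$cbcl_case[2], 0),
                 rnorm_clipped(n_tot, config$cbcl_control[1],
                               config$cbcl_control[2], 0))
  medicated <- ifelse(grp == "case",
                      stats::rbinom(n_tot, 1, 0.5) == 1, NA)
  design <- data.frame(subject_id = sprintf("sub%03d", seq_len(n_tot)),
                       group = grp, sex = sex, pds = pds, site = site,
                       cbcl_adhd = cbcl, medicated = medicated,
                       stringsAsFactors = FALSE)
  sims <- lapply(seq_len(n_tot), function(i)
    simulate_subject(config, grp[i] == "case", design$subject_id[i]))
  structure(list(panels = lapply(sims, `[[`, "panels"),
                 design = prepare_design(design),
                 truth = do.call(rbind, lapply(sims, `[[`, "truth")),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects x %d run(s), %d ROIs, %d timepoints\n",
              length(x$panels), x$config$n_runs, nrow(x$config$network_map),
              x$config$n_timepoints))
  invisible(x)
}

#' Build a small 4D phantom image from an ROI panel
#'
#' Lays the panel's ROIs out as non-overlapping cuboid blocks on a small
#' voxel grid; every voxel of a block carries its ROI's time series plus
#' independent white voxel noise.  Returns the 4D image and the matching
#' integer label atlas, for exercising the voxel-wise entropy and ROI
#' extraction paths.
#'
#' @param panel An [roi_panel()].
#' @param block Block dimensions in voxels (length 3).
#' @param voxel_noise_sd SD of per-voxel white noise (0 for exact
#'   round-trip).
#' @param origins Optional R x 3 matrix of 1-based block origins; blocks
#'   must not overlap.
#' @return List with `bold4d` (4D array), `atlas` (3D integer array).
#' @export
simulate_phantom_4d <- function(panel, block = c(2L, 2L, 2L),
                                voxel_noise_sd = 0, origins = NULL) {
  stopifnot(inherits(panel, "roi_panel"), length(block) == 3L)
  R <- ncol(panel$mat); n <- nrow(panel$mat)
  if (is.null(origins)) {
    per <- ceiling(R^(1 / 3))
    lat <- arrayInd(seq_len(R), c(per, per, per))
    origins <- 1L + (lat - 1L) %*% diag(block)
  }
  origins <- as.matrix(origins)
  if (nrow(origins) != R) stop("need one origin per ROI")
  dims <- apply(origins, 2, max) + block - 1L
  if (any(dims > 20L)) stop("phantom grid exceeds 20 voxels per axis")
  atlas <- array(0L, dims)
  for (i in seq_len(R)) {
    ix <- origins[i, 1]:(origins[i, 1] + block[1] - 1L)
    iy <- origins[i, 2]:(origins[i, 2] + block[2] - 1L)
    iz <- origins[i, 3]:(origins[i, 3] + block[3] - 1L)
    if (any(atlas[ix, iy, iz] != 0L))
      stop("invalid geometry: ROI blocks overlap")
    atlas[ix, iy, iz] <- panel$roi_ids[i]
  }
  bold <- array(0, c(dims, n))
  vox_per <- prod(block)
  for (i in seq_len(R)) {
    sel <- which(atlas == panel$roi_ids[i])
    for (t in seq_len(n)) {
      slab <- bold[, , , t]
      slab[sel] <- panel$mat[t, i] +
        if (voxel_noise_sd > 0) stats::rnorm(length(sel), 0, voxel_noise_sd)
        else 0
      bold[, , , t] <- slab
    }
  }
  list(bold4d = bold, atlas = atlas)
}
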