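#' Default ROI-to-network map
#'
#' The 17-region layout analyzed by the pipeline, drawn from the
#' Harvard-Oxford atlas nomenclature and grouped into three networks: the
#' frontoparietal network (FPN: anterior cingulate gyrus, bilateral middle
#' and superior frontal gyri), the default mode network (DMN: anterior
#' cingulate gyrus, bilateral anterior/posterior supramarginal gyri, medial
#' frontal cortex, posterior cingulate gyrus), and the reward/motivation
#' network (RMN: bilateral frontal orbital cortex, caudate, putamen).  The
#' anterior cingulate belongs to both FPN and DMN, so network membership is
#' a set, encoded as a semicolon-separated string.
#'
#' @return Data frame with columns `roi_id` (integer label), `label`,
#'   `hemisphere` (`L`, `R`, or `M` for midline), `networks`.
#' @export
default_network_map <- function() {
  data.frame(
    roi_id = 1:17,
    label = c("AC", "MidFG.L", "MidFG.R", "SFG.L", "SFG.R",
              "aSMG.L", "aSMG.R", "pSMG.L", "pSMG.R", "MedFC", "PC",
              "FOrb.L", "FOrb.R", "Caudate.L", "Caudate.R",
              "Putamen.L", "Putamen.R"),
    hemisphere = c("M", "L", "R", "L", "R", "L", "R", "L", "R", "M", "M",
                   "L", "R", "L", "R", "L", "R"),
    networks = c("FPN;DMN", "FPN", "FPN", "FPN", "FPN",
                 "DMN", "DMN", "DMN", "DMN", "DMN", "DMN",
                 "RMN", "RMN", "RMN", "RMN", "RMN", "RMN"),
    stringsAsFactors = FALSE
  )
}

#' Read a network map from TSV
#'
#' Expects columns `roi_id`, `label`, `hemisphere`, `networks`
#' (semicolon-separated memberships).  ROI output order everywhere in the
#' pipeline follows the row order of this table.
#'
#' @param path TSV file path.
#' @return Data frame as [default_network_map()].
#' @export
read_network_map <- function(path) {
  nm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "label", "hemisphere", "networks")
  miss <- setdiff(need, names(nm))
  if (length(miss)) stop("network map missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(nm$networks))) stop("every ROI needs >= 1 network")
  nm
}

network_sets <- function(network_map) {
  strsplit(network_map$networks, ";", fixed = TRUE)
}

#' ROI time-series panel
#'
#' Container for one subject-run: an N-timepoints by R-ROIs matrix of
#' ROI-mean BOLD values.
#'
#' @param mat Numeric matrix, timepoints x ROIs.
#' @param roi_ids Ordered ROI labels (one per column).
#' @param tr Repetition time in seconds.
#' @param subject_id,run Identifiers carried through to output tables.
#' @return Object of class `roi_panel`.
#' @export
roi_panel <- function(mat, roi_ids, tr = 0.8, subject_id = NA, run = 1L) {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(roi_ids))
    stop("column count does not match roi_ids length")
  if (any(colSums(is.finite(mat)) == 0L))
    stop("panel contains an all-undefined ROI column")
  colnames(mat) <- as.character(roi_ids)
  structure(list(mat = mat, roi_ids = roi_ids, tr = tr,
                 subject_id = subject_id, run = as.integer(run)),
            class = "roi_panel")
}

#' @export
print.roi_panel <- function(x, ...) {
  cat(sprintf("roi_panel: subject %s run %d, %d timepoints x %d ROIs (TR %g s)\n",
              x$subject_id, x$run, nrow(x$mat), ncol(x$mat), x$tr))
  invisible(x)
}

#' Extract ROI-mean time series from a 4D image
#'
#' For every ROI in the network map, averages the BOLD signal over the
#' voxels carrying that label at each timepoint.
#'
#' @param bold4d 4D numeric array or `niftiImage` (x, y, z, time).
#' @param atlas 3D integer label volume on the same grid.
#' @param network_map ROI table as from [default_network_map()]; every
#'   `roi_id` must be present in the atlas.
#' @param tr,subject_id,run Metadata for the returned panel.
#' @return An [roi_panel()].
#' @export
extract_roi_timeseries <- function(bold4d, atlas,
                                   network_map = default_network_map(),
                                   tr = 0.8, subject_id = NA, run = 1L) {
  arr <- as_array4d(bold4d)
  lab <- as_array3d(atlas)
  if (!identical(dim(arr)[1:3], dim(lab)))
    stop("atlas grid does not match the image grid")
  present <- unique(as.vector(lab))
  missing_rois <- setdiff(network_map$roi_id, present)
  if (length(missing_rois))
    stop("ROI labels absent from atlas: ",
         paste(missing_rois, collapse = ", "))
  nt <- dim(arr)[4]
  flat <- matrix(arr, nrow = prod(dim(arr)[1:3]), ncol = nt)
  mat <- vapply(network_map$roi_id, function(id) {
    colMeans(flat[which(lab == id), , drop = FALSE])
  }, numeric(nt))
  roi_panel(mat, network_map$roi_id, tr = tr,
            subject_id = subject_id, run = run)
}

#' Seed-to-seed functional connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time series, with Fisher's
#' z = atanh(r) for variance stabilization.  `|r|` is clipped to
#' `1 - clip` before the transform so that duplicated columns yield a large
#' finite z rather than infinity; diagonal z entries are `NA`.
#'
#' @param panel An [roi_panel()] with >= 3 timepoints.
#' @param clip Clipping margin for `|r|` before `atanh` (default `1e-7`).
#' @return Object of class `fc_matrix`: list with `r_matrix`, `z_matrix`,
#'   `roi_ids`.
#' @export
fc_matrix <- function(panel, clip = 1e-7) {
  stopifnot(inherits(panel, "roi_panel"))
  mat <- panel$mat
  if (nrow(mat) < 3L) stop("need >= 3 timepoints for correlation")
  v <- apply(mat, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI series: ",
         paste(panel$roi_ids[v == 0], collapse = ", "))
  r <- stats::cor(mat)
  rc <- pmin(pmax(r, -1 + clip), 1 - clip)
  z <- atanh(rc)
  diag(z) <- NA_real_
  diag(r) <- 1
  structure(list(r_matrix = r, z_matrix = z, roi_ids = panel$roi_ids,
                 subject_id = panel$subject_id),
            class = "fc_matrix")
}

#' Combine per-run connectivity matrices
#'
#' First-level combination across runs: the Fisher-z matrices are averaged
#' element-wise and the correlation matrix is back-transformed as
#' `tanh(mean z)`.
#'
#' @param fcs List of [fc_matrix()] objects sharing ROI set and order.
#' @return An `fc_matrix`.
#' @export
combine_runs_fc <- function(fcs) {
  stopifnot(is.list(fcs), length(fcs) >= 1L)
  ids <- fcs[[1]]$roi_ids
  for (f in fcs) {
    if (!inherits(f, "fc_matrix") || !identical(f$roi_ids, ids))
      stop("fc matrices have mismatched ROI sets")
  }
  if (length(fcs) == 1L) return(fcs[[1]])
  zs <- vapply(fcs, function(f) f$z_matrix, fcs[[1]]$z_matrix)
  z <- apply(zs, 1:2, mean)
  r <- tanh(z)
  diag(r) <- 1
  structure(list(r_matrix = r, z_matrix = z, roi_ids = ids,
                 subject_id = fcs[[1]]$subject_id),
            class = "fc_matrix")
}

#' Long-format edge table from a connectivity matrix
#'
#' @param fc An [fc_matrix()].
#' @param network_map Optional ROI table used to attach labels and the edge's
#'   network family (the set of networks shared by both endpoints, or
#'   `"cross"` when the endpoints share none).
#' @return Data frame with one row per unordered ROI pair: `roi_a`, `roi_b`,
#'   `r`, `z`, and (when a map is given) `label_a`, `label_b`, `network`.
#' @export
fc_edges <- function(fc, network_map = NULL) {
  ids <- fc$roi_ids
  idx <- which(upper.tri(fc$z_matrix), arr.ind = TRUE)
  out <- data.frame(roi_a = ids[idx[, 1]], roi_b = ids[idx[, 2]],
                    r = fc$r_matrix[idx], z = fc$z_matrix[idx])
  if (!is.null(network_map)) {
    sets <- network_sets(network_map)
    names(sets) <- as.character(network_map$roi_id)
    lab <- stats::setNames(network_map$label, as.character(network_map$roi_id))
    out$label_a <- unname(lab[as.character(out$roi_a)])
    out$label_b <- unname(lab[as.character(out$roi_b)])
    out$network <- mapply(function(a, b) {
      shared <- intersect(sets[[as.character(a)]], sets[[as.character(b)]])
      if (length(shared)) paste(shared, collapse = ";") else "cross"
    }, out$roi_a, out$roi_b)
  }
  out
}
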