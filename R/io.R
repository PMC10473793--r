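#' Read and write ROI time-series panels as TSV
#'
#' Wide TSV, one column per ROI (header = ROI id), one row per timepoint;
#' panel metadata (`subject_id`, `run`, `tr`) is stored in `#key=value`
#' comment lines before the header.
#'
#' @param panel An [roi_panel()].
#' @param path File path.
#' @return `write_roi_panel` returns `path` invisibly; `read_roi_panel`
#'   returns an [roi_panel()].
#' @export
write_roi_panel <- function(panel, path) {
  stopifnot(inherits(panel, "roi_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#subject_id=%s", panel$subject_id),
               sprintf("#run=%d", panel$run),
               sprintf("#tr=%.10g", panel$tr)), con)
  utils::write.table(panel$mat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_panel
#' @export
read_roi_panel <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[meta_lines]), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, `[`, character(1), 2L),
                        vapply(meta, `[`, character(1), 1L))
  mat <- utils::read.delim(text = lines[-meta_lines], check.names = FALSE)
  roi_panel(as.matrix(mat), colnames(mat),
            tr = as.numeric(kv[["tr"]]),
            subject_id = kv[["subject_id"]],
            run = as.integer(kv[["run"]]))
}

#' Long-format entropy profile table for a cohort
#'
#' One row per (subject, ROI, scale) with the per-scale SampEn and the
#' subject-ROI MSE, the layout used for TSV export.
#'
#' @param entropy A [cohort_entropy()] result.
#' @param subject_ids Subject identifiers (rows of the entropy matrices).
#' @return Data frame with columns `subject_id`, `roi_id`, `scale`,
#'   `sampen`, `mse`.
#' @export
entropy_profile_table <- function(entropy, subject_ids = NULL) {
  d <- dim(entropy$sampen)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(d[1]))
  ids <- dimnames(entropy$sampen)[[2]]
  out <- expand.grid(subject_id = subject_ids, roi_id = ids,
                     scale = seq_len(d[3]), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$sampen <- as.vector(entropy$sampen)
  out$mse <- as.vector(entropy$mse[cbind(match(out$subject_id, subject_ids),
                                         match(out$roi_id, ids))])
  out
}

#' Write a long-format connectivity edge table
#'
#' @param fc An [fc_matrix()].
#' @param path TSV path.
#' @param network_map Optional ROI table for labels/network family.
#' @return `path`, invisibly.
#' @export
write_fc_edges <- function(fc, path, network_map = NULL) {
  edges <- fc_edges(fc, network_map)
  edges <- cbind(subject_id = fc$subject_id %||% NA, edges)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an analysis configuration from YAML
#'
#' Recognized keys: `entropy` (`m`, `r`, `scales`, `tolerance_reference`),
#' `q`, `covariates`, `pc_covariates`, `scalewise`, `symptom_score`,
#' `global_fdr`.  Missing keys keep their [analysis_config()] defaults.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  ep <- do.call(entropy_params, y$entropy %||% list())
  args <- y[setdiff(names(y), "entropy")]
  do.call(analysis_config, c(list(entropy = ep), args))
}
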