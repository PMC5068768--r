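# Probe-exclusion stages applied before DMR detection: detection-P failures,
# SNP-affected probes, sex chromosomes, and named exclusion lists (e.g. the
# cell-type marker probes). Each stage returns the removed ids so a report
# can account for every probe.

#' Filtering configuration
#'
#' @param detection_p_threshold A probe is removed when any sample's detection
#'   P-value exceeds this (strictly); `NA` disables the stage. Default 0.05.
#' @param snp_offset_window Annotated SNP offsets that disqualify a probe;
#'   default `0:2` (0 = single-base extension, 1-2 = CpG site). `integer(0)`
#'   disables the stage.
#' @param drop_sex_chromosomes Remove probes on X/Y. Default `TRUE`.
#' @param exclusion_lists Named list of probe-id character vectors to mask,
#'   e.g. `list(celltype = <10k cell-type marker probes>)`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(detection_p_threshold = 0.05,
                          snp_offset_window = 0:2,
                          drop_sex_chromosomes = TRUE,
                          exclusion_lists = list()) {
  if (!is.na(detection_p_threshold) &&
      (detection_p_threshold <= 0 || detection_p_threshold >= 1))
    stopf("detection_p_threshold must lie in (0,1) or be NA")
  if (length(exclusion_lists) && is.null(names(exclusion_lists)))
    stopf("exclusion_lists must be named")
  structure(list(detection_p_threshold = detection_p_threshold,
                 snp_offset_window = as.integer(snp_offset_window),
                 drop_sex_chromosomes = isTRUE(drop_sex_chromosomes),
                 exclusion_lists = exclusion_lists),
            class = "filter_config")
}

check_aligned <- function(mat, detp) {
  if (!identical(rownames(mat), rownames(detp)) ||
      !identical(colnames(mat), colnames(detp)))
    stopf("methylation and detection-P matrices are misaligned; refusing to reorder")
}

#' Remove probes failing detection
#'
#' A probe is removed iff at least one sample's detection P-value is strictly
#' greater than the threshold.
#'
#' @param mat Probes-by-samples methylation matrix.
#' @param detp Detection P-value matrix aligned to `mat`.
#' @param threshold Detection P threshold (default 0.05).
#' @return `list(matrix =, removed =)` with removed probe ids.
#' @export
filter_detection <- function(mat, detp, threshold = 0.05) {
  check_aligned(mat, detp)
  fail <- rowSums(detp > threshold) > 0
  list(matrix = mat[!fail, , drop = FALSE], removed = rownames(mat)[fail])
}

#' Remove probes with annotated SNPs at assay-critical positions
#'
#' @param manifest Probe manifest with a `snp_offsets` column.
#' @param window Integer offsets that disqualify a probe (default `0:2`).
#' @return `list(manifest =, removed =)`.
#' @export
filter_snp_probes <- function(manifest, window = 0:2) {
  offs <- parse_snp_offsets(manifest$snp_offsets)
  hit <- vapply(offs, function(v) any(v %in% window), logical(1))
  list(manifest = manifest[!hit, , drop = FALSE],
       removed = manifest$probe_id[hit])
}

#' Remove probes on the sex chromosomes
#'
#' Both `"X"`/`"Y"` and `"chrX"`/`"chrY"` labels are recognised.
#'
#' @param manifest Probe manifest.
#' @return `list(manifest =, removed =)`.
#' @export
filter_sex_chromosomes <- function(manifest) {
  hit <- is_sex_chrom(manifest$chrom)
  list(manifest = manifest[!hit, , drop = FALSE],
       removed = manifest$probe_id[hit])
}

#' Mask an explicit probe list
#'
#' Ids absent from the matrix are ignored (with a warning) and counted
#' separately from the removals.
#'
#' @param mat Probes-by-samples matrix.
#' @param list_name Label for reporting.
#' @param probe_ids Character vector of probe ids to remove.
#' @return `list(matrix =, removed =, unknown =)`.
#' @export
mask_probe_list <- function(mat, list_name, probe_ids) {
  present <- intersect(probe_ids, rownames(mat))
  unknown <- setdiff(probe_ids, rownames(mat))
  if (length(unknown))
    warnf("exclusion list '%s': %d probe id(s) not present in the matrix",
          list_name, length(unknown))
  keep <- !(rownames(mat) %in% present)
  list(matrix = mat[keep, , drop = FALSE], removed = present, unknown = unknown)
}

#' Run the full probe-filter stack
#'
#' Stages are applied in a fixed order -- detection P, SNP-affected probes,
#' sex chromosomes, then each named exclusion list -- with per-stage removal
#' counts reported on the surviving set (sequential accounting).
#'
#' @param mat Probes-by-samples methylation matrix, rows aligned to `manifest`.
#' @param detp Optional detection P-value matrix aligned to `mat`.
#' @param manifest Probe manifest aligned to the rows of `mat`.
#' @param config A [filter_config()].
#' @return `list(matrix =, manifest =, detp =, report =)` where `report` is a
#'   `filter_report` data.frame of per-stage counts.
#' @export
run_filter_stack <- function(mat, detp = NULL, manifest, config = filter_config()) {
  if (!identical(rownames(mat), manifest$probe_id))
    stopf("matrix rows and manifest probe ids are misaligned; refusing to reorder")
  if (!is.null(detp)) check_aligned(mat, detp)

  n_input <- nrow(mat)
  stages <- character(0)
  removed_n <- integer(0)
  remaining <- integer(0)

  subset_all <- function(keep_ids) {
    mat <<- mat[keep_ids, , drop = FALSE]
    manifest <<- manifest[match(keep_ids, manifest$probe_id), , drop = FALSE]
    if (!is.null(detp)) detp <<- detp[keep_ids, , drop = FALSE]
  }
  record <- function(stage, removed) {
    stages <<- c(stages, stage)
    removed_n <<- c(removed_n, length(removed))
    remaining <<- c(remaining, nrow(mat))
    if (nrow(mat) == 0L) stopf("no probes remain after stage '%s'", stage)
  }

  if (!is.null(detp) && !is.na(config$detection_p_threshold)) {
    res <- filter_detection(mat, detp, config$detection_p_threshold)
    subset_all(rownames(res$matrix))
    record("detection_p", res$removed)
  }
  if (length(config$snp_offset_window)) {
    res <- filter_snp_probes(manifest, config$snp_offset_window)
    subset_all(res$manifest$probe_id)
    record("snp", res$removed)
  }
  if (config$drop_sex_chromosomes) {
    res <- filter_sex_chromosomes(manifest)
    subset_all(res$manifest$probe_id)
    record("sex_chromosomes", res$removed)
  }
  for (nm in names(config$exclusion_lists)) {
    res <- mask_probe_list(mat, nm, config$exclusion_lists[[nm]])
    subset_all(rownames(res$matrix))
    record(paste0("list:", nm), res$removed)
  }

  report <- data.frame(stage = stages, removed = removed_n,
                       remaining = remaining, stringsAsFactors = FALSE)
  attr(report, "n_input") <- n_input
  class(report) <- c("filter_report", "data.frame")
  list(matrix = mat, manifest = manifest, detp = detp, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  n_in <- attr(x, "n_input")
  cat(sprintf("Probe filtering: %d probes in, %d removed, %d remaining\n",
              n_in, n_in - (if (nrow(x)) x$remaining[nrow(x)] else n_in),
              if (nrow(x)) x$remaining[nrow(x)] else n_in))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s removed %6d  (remaining %d)\n",
                x$stage[i], x$removed[i], x$remaining[i]))
  invisible(x)
}
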