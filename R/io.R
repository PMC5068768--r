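# Readers/writers for the tabular formats the pipeline touches, and the
# beta <-> M transforms. Coordinates are 1-based inclusive everywhere inside
# the package; only BED export converts to 0-based half-open.

read_matrix_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = file_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2)
    stopf("'%s': expected a probe-id column plus at least one sample column", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("'%s': duplicate probe id '%s'", path, ids[duplicated(ids)][1])
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stopf("'%s': non-numeric value '%s' at probe '%s', sample '%s'",
              path, as.character(v)[bad[1]], ids[bad[1]], names(vals)[j])
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  mat
}

validate_methyl_values <- function(mat, scale, where = "matrix") {
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stopf("%s: missing value at probe '%s', sample '%s'", where,
          rownames(mat)[bad[1]] %||% bad[1], colnames(mat)[bad[2]] %||% bad[2])
  }
  if (scale == "beta") {
    out <- mat < 0 | mat > 1
    if (any(out)) {
      bad <- which(out, arr.ind = TRUE)[1, ]
      stopf("%s: beta value %g outside [0,1] at probe '%s', sample '%s'", where,
            mat[bad[1], bad[2]],
            rownames(mat)[bad[1]] %||% bad[1], colnames(mat)[bad[2]] %||% bad[2])
    }
  } else if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stopf("%s: non-finite M value at probe '%s', sample '%s'", where,
          rownames(mat)[bad[1]] %||% bad[1], colnames(mat)[bad[2]] %||% bad[2])
  }
  invisible(mat)
}

#' Read a probes-by-samples methylation matrix
#'
#' Reads a TSV/CSV matrix (probe ids in the first column, sample ids in the
#' header) and validates it for the stated scale: beta values must lie in
#' \[0, 1\], M-values must be finite, and no missing values are tolerated.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param scale `"beta"` or `"M"`; determines validation.
#' @return A numeric matrix with probe rownames and sample colnames, carrying
#'   a `"scale"` attribute.
#' @export
read_methyl_matrix <- function(path, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  mat <- read_matrix_file(path)
  validate_methyl_values(mat, scale, where = sprintf("'%s'", path))
  attr(mat, "scale") <- scale
  mat
}

#' Write a methylation (or detection-P) matrix to TSV/CSV
#'
#' @param mat Numeric matrix with probe rownames and sample colnames.
#' @param path Output path; `.csv` selects comma separation, anything else tab.
#' @export
write_methyl_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = file_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a detection P-value matrix
#'
#' Same layout as [read_methyl_matrix()]; values must lie in \[0, 1\].
#'
#' @inheritParams read_methyl_matrix
#' @return Numeric matrix of detection P-values.
#' @export
read_detection_p <- function(path) {
  mat <- read_matrix_file(path)
  if (anyNA(mat) || any(mat < 0 | mat > 1))
    stopf("'%s': detection P-values must lie in [0,1] with no missing values", path)
  mat
}

#' Read a probe manifest
#'
#' Expects columns `probe_id`, `chrom`, `pos` (1-based CpG coordinate) and,
#' optionally, `snp_offsets` (comma-joined integers; 0 = single-base
#' extension, 1-2 = CpG site). Probe ids and (chrom, pos) pairs must be
#' unique.
#'
#' @param path Path to a TSV/CSV manifest.
#' @return A data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `snp_offsets` (character, `""` when none).
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = file_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"",
                          colClasses = "character")
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stopf("'%s': manifest needs columns %s", path, paste(need, collapse = ", "))
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos) || any(pos < 1))
    stopf("'%s': probe positions must be integers >= 1", path)
  man <- data.frame(probe_id = df$probe_id, chrom = df$chrom, pos = pos,
                    snp_offsets = if ("snp_offsets" %in% names(df))
                      ifelse(is.na(df$snp_offsets), "", df$snp_offsets) else "",
                    stringsAsFactors = FALSE)
  validate_probe_manifest(man, where = sprintf("'%s'", path))
  man
}

validate_probe_manifest <- function(man, where = "manifest") {
  if (anyDuplicated(man$probe_id))
    stopf("%s: duplicate probe id '%s'", where,
          man$probe_id[duplicated(man$probe_id)][1])
  key <- paste(man$chrom, man$pos)
  if (anyDuplicated(key))
    stopf("%s: duplicate (chrom, pos) pair '%s'", where, key[duplicated(key)][1])
  parse_snp_offsets(man$snp_offsets)  # validates the encoding
  invisible(man)
}

#' @rdname read_probe_manifest
#' @param manifest A probe-manifest data.frame.
#' @export
write_probe_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = file_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns `sample_id` and `group` (`case`/`control`); optional
#' covariate columns `sex` (`F`/`M`), `age` (years) and `pmi` (post-mortem
#' interval, hours) may contain missing values.
#'
#' @param path Path to a TSV/CSV sample sheet.
#' @return A data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = file_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"",
                          na.strings = c("NA", ""))
  if (!all(c("sample_id", "group") %in% names(df)))
    stopf("'%s': sample sheet needs columns sample_id, group", path)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("'%s': duplicate sample id '%s'", path,
          df$sample_id[duplicated(df$sample_id)][1])
  df$group <- tolower(as.character(df$group))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    stopf("'%s': group must be 'case' or 'control' (found '%s')", path, bad[1])
  if ("sex" %in% names(df)) {
    df$sex <- toupper(as.character(df$sex))
    badsex <- setdiff(unique(df$sex[!is.na(df$sex)]), c("F", "M"))
    if (length(badsex))
      stopf("'%s': sex must be 'F' or 'M' (found '%s')", path, badsex[1])
  }
  for (cv in intersect(c("age", "pmi"), names(df))) df[[cv]] <- as.numeric(df[[cv]])
  df
}

#' Read gene models for nearest-gene annotation
#'
#' Accepts a TSV with columns `name`, `chrom`, `start`, `end`, `strand`
#' (1-based inclusive) or a BED file (0-based half-open; converted on read).
#'
#' @param path Path to the gene table.
#' @return A data.frame with columns `name`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stopf("'%s': BED gene file needs at least 4 columns", path)
    genes <- data.frame(name = as.character(df[[4]]), chrom = as.character(df[[1]]),
                        start = as.integer(df[[2]]) + 1L, end = as.integer(df[[3]]),
                        strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+",
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = file_sep(path),
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("name", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stopf("'%s': gene table needs columns %s", path, paste(need, collapse = ", "))
    genes <- data.frame(name = as.character(df$name), chrom = as.character(df$chrom),
                        start = as.integer(df$start), end = as.integer(df$end),
                        strand = if ("strand" %in% names(df)) as.character(df$strand) else "+",
                        stringsAsFactors = FALSE)
  }
  if (any(genes$start > genes$end))
    stopf("'%s': gene start must be <= end", path)
  genes
}

#' Read a one-probe-id-per-line exclusion list
#'
#' @param path Path to a plain-text file; blank lines and `#` comments ignored.
#' @return Character vector of probe ids.
#' @export
read_probe_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Convert beta values to M-values
#'
#' The M-value is the base-2 logit of the methylation fraction,
#' `log2(beta / (1 - beta))`. Betas are clamped to
#' `[epsilon, 1 - epsilon]` first so boundary values stay finite.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @param epsilon Clamp bound in (0, 0.5); default `1e-3`.
#' @return M-values with the same shape as `beta`.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (!is.numeric(beta)) stopf("beta must be numeric")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 0.5)
    stopf("epsilon must lie in (0, 0.5)")
  out <- beta < 0 | beta > 1
  if (any(out, na.rm = TRUE)) {
    bad <- which(out)[1]
    lab <- if (is.matrix(beta) && !is.null(rownames(beta)))
      sprintf(" (probe '%s')", rownames(beta)[(bad - 1) %% nrow(beta) + 1]) else ""
    stopf("beta value %g outside [0,1]%s", beta[bad], lab)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  attr(m, "scale") <- "M"
  m
}

#' Convert M-values to beta values
#'
#' Inverse of [beta_to_m()]: `2^m / (1 + 2^m)`.
#'
#' @param m Numeric vector or matrix of finite M-values.
#' @return Beta values in (0, 1) with the same shape as `m`.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stopf("m must be numeric")
  b <- 1 / (1 + 2^(-m))
  attr(b, "scale") <- "beta"
  b
}

region_sorted <- function(regions) {
  if (nrow(regions) < 2) return(TRUE)
  ord <- order(regions$chrom, regions[[region_start_col(regions)]], method = "radix")
  identical(ord, seq_len(nrow(regions)))
}

region_start_col <- function(regions) {
  if ("start" %in% names(regions)) "start" else "intersect_start"
}
region_end_col <- function(regions) {
  if ("end" %in% names(regions)) "end" else "intersect_end"
}

#' Write regions to TSV or BED
#'
#' TSV keeps every column of the region table. BED converts the 1-based
#' inclusive coordinates to 0-based half-open (`start - 1`, `end`), with the
#' region direction encoded as strand (`+` hyper, `-` hypo) and the area as
#' score.
#'
#' @param regions A candidate- or consensus-region data.frame sorted by
#'   (chrom, start).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!region_sorted(regions))
    stopf("regions must be sorted by (chrom, start)")
  if (format == "tsv") {
    utils::write.table(regions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    sc <- region_start_col(regions)
    ec <- region_end_col(regions)
    bed <- data.frame(
      chrom = regions$chrom,
      start = regions[[sc]] - 1L,
      end = regions[[ec]],
      name = sprintf("dmr_%04d", seq_len(nrow(regions))),
      score = if ("area" %in% names(regions)) signif(regions$area, 6) else 0,
      strand = if ("direction" %in% names(regions))
        ifelse(regions$direction == "hyper", "+", "-") else ".",
      stringsAsFactors = FALSE)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a region TSV written by [write_regions()]
#'
#' @param path Path to the TSV.
#' @return The region data.frame.
#' @export
read_regions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}
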