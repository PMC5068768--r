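# Internal helpers shared across the package.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip an optional "chr" prefix so "X" and "chrX" compare equal.
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom), ignore.case = TRUE)

is_sex_chrom <- function(chrom) toupper(norm_chrom(chrom)) %in% c("X", "Y")

# snp_offsets travel as comma-joined integers ("" = none) in manifest files.
parse_snp_offsets <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    v <- trimws(v)
    v <- v[nzchar(v)]
    if (!length(v)) return(integer(0))
    out <- suppressWarnings(as.integer(v))
    if (anyNA(out)) stopf("malformed snp_offsets entry: '%s'", paste(v, collapse = ","))
    out
  })
}

format_snp_offsets <- function(offsets) {
  vapply(offsets, function(v) paste(v, collapse = ","), character(1))
}

# "Sorted" means each chromosome occupies one contiguous block and positions
# increase strictly within it; the block order itself is immaterial.
manifest_is_sorted <- function(manifest) {
  if (nrow(manifest) < 2) return(TRUE)
  runs <- rle(as.character(manifest$chrom))
  if (anyDuplicated(runs$values)) return(FALSE)
  ok <- tapply(manifest$pos, factor(manifest$chrom, levels = runs$values),
               function(p) !is.unsorted(p, strictly = TRUE))
  all(unlist(ok))
}

sort_manifest <- function(manifest) {
  ord <- order(manifest$chrom, manifest$pos, method = "radix")
  out <- manifest[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

file_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

# sample() that never falls into the 1:n trap when x has length 1
safe_sample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
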