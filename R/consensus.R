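# Cross-cohort consensus of significant DMRs and nearest-gene annotation.
# Overlap detection and intersection use GenomicRanges/IRanges; consensus
# requires a common intersection of at least `min_overlap` bp across all
# cohorts, stratified by direction.

#' Select significant regions
#'
#' Keeps scored regions with `p_value` strictly below `alpha`.
#'
#' @param regions Scored candidate-region data.frame.
#' @param alpha Significance level (default 0.05).
#' @return The significant subset.
#' @export
select_significant <- function(regions, alpha = 0.05) {
  if (!"p_value" %in% names(regions) || anyNA(regions$p_value))
    stopf("regions must be scored (non-missing p_value) before selection")
  out <- regions[regions$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Common seqlevels keep findOverlaps quiet about chromosomes private to one set.
granges_on <- function(chrom, start, end, levels) {
  GenomicRanges::GRanges(factor(as.character(chrom), levels = levels),
                         IRanges::IRanges(start, end))
}

#' Direction-stratified multi-cohort consensus overlap
#'
#' A consensus region exists where one significant region per cohort, all with
#' the same direction, shares a common intersection of width at least
#' `min_overlap` bp (1-based inclusive width = end - start + 1). When one
#' cohort contributes several regions overlapping the same locus the
#' largest-area one is used, with a warning.
#'
#' @param cohort_regions Named list (>= 2 cohorts) of significant
#'   candidate-region data.frames.
#' @param min_overlap Minimum common intersection width in bp (default 2).
#' @param require_all Require a contribution from every cohort (default
#'   `TRUE`); with `FALSE`, loci overlapping in at least two cohorts are kept
#'   and non-contributing cohorts get `NA` columns.
#' @return Data.frame with one row per consensus region: `chrom`,
#'   `intersect_start`, `intersect_end`, `width`, `direction`, and per-cohort
#'   `<label>_start`, `<label>_end`, `<label>_avg_delta_m` columns.
#' @export
consensus_overlap <- function(cohort_regions, min_overlap = 2,
                              require_all = TRUE) {
  if (!is.list(cohort_regions) || length(cohort_regions) < 2)
    stopf("at least two cohorts are required")
  if (min_overlap < 1) stopf("min_overlap must be >= 1")
  k <- length(cohort_regions)
  labels <- names(cohort_regions) %||% paste0("cohort", seq_len(k))
  labels[!nzchar(labels)] <- paste0("cohort", which(!nzchar(labels)))

  rows <- list()
  for (dir in c("hyper", "hypo")) {
    sets <- lapply(cohort_regions, function(r)
      r[r$direction == dir, , drop = FALSE])
    if (nrow(sets[[1]]) == 0) next
    cs <- sets[[1]]$start
    ce <- sets[[1]]$end
    chrom <- as.character(sets[[1]]$chrom)
    picks <- matrix(NA_integer_, length(cs), k)
    picks[, 1] <- seq_along(cs)
    alive <- rep(TRUE, length(cs))
    for (j in 2:k) {
      sj <- sets[[j]]
      if (!nrow(sj)) {
        alive[] <- !require_all & alive
        next
      }
      lev <- unique(c(chrom, as.character(sj$chrom)))
      grj <- granges_on(sj$chrom, sj$start, sj$end, lev)
      cur <- granges_on(chrom, cs, ce, lev)
      hits <- GenomicRanges::findOverlaps(cur, grj, minoverlap = min_overlap)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (i in which(alive)) {
        cand <- sh[qh == i]
        if (!length(cand)) {
          if (require_all) alive[i] <- FALSE
          next
        }
        if (length(cand) > 1) {
          warnf("cohort '%s' contributes %d regions to one consensus locus; using the largest-area one",
                labels[j], length(cand))
          cand <- cand[which.max(sj$area[cand])]
        }
        picks[i, j] <- cand
        cs[i] <- max(cs[i], sj$start[cand])
        ce[i] <- min(ce[i], sj$end[cand])
      }
    }
    if (!require_all)
      alive <- alive & rowSums(!is.na(picks)) >= 2
    for (i in which(alive)) {
      row <- list(chrom = chrom[i], intersect_start = cs[i],
                  intersect_end = ce[i], width = ce[i] - cs[i] + 1L,
                  direction = dir)
      for (j in seq_len(k)) {
        pj <- picks[i, j]
        row[[paste0(labels[j], "_start")]] <-
          if (is.na(pj)) NA_integer_ else sets[[j]]$start[pj]
        row[[paste0(labels[j], "_end")]] <-
          if (is.na(pj)) NA_integer_ else sets[[j]]$end[pj]
        row[[paste0(labels[j], "_avg_delta_m")]] <-
          if (is.na(pj)) NA_real_ else sets[[j]]$avg_delta_m[pj]
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(chrom = character(0), intersect_start = integer(0),
                      intersect_end = integer(0), width = integer(0),
                      direction = character(0), stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
      out[[paste0(labels[j], "_start")]] <- integer(0)
      out[[paste0(labels[j], "_end")]] <- integer(0)
      out[[paste0(labels[j], "_avg_delta_m")]] <- numeric(0)
    }
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$intersect_start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise overlap counts between cohorts
#'
#' Per-pair and all-cohort consensus counts, stratified by direction; the
#' all-cohort count equals `nrow(consensus_overlap(...))` for the same
#' settings.
#'
#' @inheritParams consensus_overlap
#' @return Data.frame with columns `comparison`, `direction`, `count`.
#' @export
count_overlaps <- function(cohort_regions, min_overlap = 2) {
  k <- length(cohort_regions)
  labels <- names(cohort_regions) %||% paste0("cohort", seq_len(k))
  rows <- list()
  tally <- function(cons, comparison) {
    for (dir in c("hyper", "hypo"))
      rows[[length(rows) + 1L]] <<- data.frame(
        comparison = comparison, direction = dir,
        count = sum(cons$direction == dir), stringsAsFactors = FALSE)
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cons <- suppressWarnings(
      consensus_overlap(cohort_regions[c(i, j)], min_overlap))
    tally(cons, paste(labels[i], labels[j], sep = "&"))
  }
  cons_all <- suppressWarnings(consensus_overlap(cohort_regions, min_overlap))
  tally(cons_all, "all")
  do.call(rbind, rows)
}

#' Annotate regions with the nearest gene
#'
#' Distance is the unstranded gap in bp between the region and the gene
#' interval (0 when they intersect); ties are broken by smaller gene start,
#' then name. Regions on a chromosome with no genes get `nearest_gene =
#' "none"` and `NA` distance.
#'
#' @param regions Consensus- or candidate-region data.frame.
#' @param genes Gene-model data.frame from [read_gene_models()].
#' @return `regions` with `nearest_gene` and `gene_distance` columns added.
#' @export
annotate_nearest_gene <- function(regions, genes) {
  sc <- region_start_col(regions)
  ec <- region_end_col(regions)
  regions$nearest_gene <- rep(NA_character_, nrow(regions))
  regions$gene_distance <- rep(NA_real_, nrow(regions))
  gchrom <- norm_chrom(genes$chrom)
  for (i in seq_len(nrow(regions))) {
    g <- genes[gchrom == norm_chrom(regions$chrom[i]), , drop = FALSE]
    if (!nrow(g)) {
      regions$nearest_gene[i] <- "none"
      next
    }
    d <- pmax(0, g$start - regions[[ec]][i], regions[[sc]][i] - g$end)
    ord <- order(d, g$start, g$name)
    regions$nearest_gene[i] <- g$name[ord[1]]
    regions$gene_distance[i] <- d[ord[1]]
  }
  regions
}
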