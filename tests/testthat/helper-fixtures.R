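# Fixture builders and independent brute-force oracles used across the suite.

tiny_manifest <- function(pos, chrom = "chr1",
                          ids = sprintf("p%03d", seq_along(pos)),
                          snp = "") {
  data.frame(probe_id = ids, chrom = rep_len(chrom, length(pos)),
             pos = as.integer(pos), snp_offsets = rep_len(snp, length(pos)),
             stringsAsFactors = FALSE)
}

tiny_sheet <- function(n_case = 3, n_control = 3, sex = NULL, age = NULL,
                       pmi = NULL) {
  n <- n_case + n_control
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   group = rep(c("case", "control"), c(n_case, n_control)),
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(age)) df$age <- age
  if (!is.null(pmi)) df$pmi <- pmi
  df
}

tiny_matrix <- function(values, probes, samples) {
  matrix(values, length(probes), length(samples),
         dimnames = list(probes, samples))
}

# Truncated-window running median by direct window enumeration.
oracle_runmed <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  if (n < k) return(x)
  vapply(seq_len(n), function(i)
    stats::median(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

# Interpolated (type-7) quantile computed from first principles.
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  pos <- (n - 1) * q
  lo <- floor(pos)
  if (lo >= n - 1) return(x[n])
  x[lo + 1] + (pos - lo) * (x[lo + 2] - x[lo + 1])
}

# Region calling by explicit left-to-right run enumeration.
oracle_regions <- function(sm, clusters, manifest, cutoff, min_probes = 1) {
  sgn <- function(v) if (v > cutoff) 1 else if (v < -cutoff) -1 else 0
  rows <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    ii <- cur$idx
    if (length(ii) >= min_probes)
      rows[[length(rows) + 1]] <<- data.frame(
        chrom = manifest$chrom[ii[1]], start = manifest$pos[ii[1]],
        end = manifest$pos[ii[length(ii)]], n_probes = length(ii),
        avg_delta_m = mean(sm[ii]), area = sum(abs(sm[ii])),
        direction = if (cur$sign > 0) "hyper" else "hypo",
        stringsAsFactors = FALSE)
    cur <<- NULL
  }
  for (i in seq_along(sm)) {
    s <- sgn(sm[i])
    if (s == 0) { flush(); next }
    if (!is.null(cur) && (cur$sign != s || cur$cluster != clusters[i])) flush()
    if (is.null(cur)) cur <- list(sign = s, cluster = clusters[i], idx = i)
    else cur$idx <- c(cur$idx, i)
  }
  flush()
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      avg_delta_m = numeric(0), area = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Exhaustive triple(+)-loop consensus: every combination of one region per
# cohort, same direction, with a common intersection of width >= min_overlap.
oracle_consensus <- function(sets, min_overlap = 2) {
  combos <- expand.grid(lapply(sets, function(s) seq_len(max(1, nrow(s)))))
  rows <- list()
  if (any(vapply(sets, nrow, 0L) == 0))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0)))
  for (r in seq_len(nrow(combos))) {
    picks <- lapply(seq_along(sets), function(j) sets[[j]][combos[r, j], ])
    dirs <- vapply(picks, function(p) p$direction, character(1))
    chroms <- vapply(picks, function(p) as.character(p$chrom), character(1))
    if (length(unique(dirs)) > 1 || length(unique(chroms)) > 1) next
    s <- max(vapply(picks, function(p) p$start, numeric(1)))
    e <- min(vapply(picks, function(p) p$end, numeric(1)))
    if (e - s + 1 >= min_overlap)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chroms[1], start = s, end = e, direction = dirs[1],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0)))
  out <- unique(do.call(rbind, rows))
  out[order(out$chrom, out$start, out$direction), , drop = FALSE]
}

# Small simulated study for fast end-to-end tests.
small_sim_config <- function(...) {
  sim_config(n_clusters = 40, cases = c(12, 12, 12), controls = c(12, 12, 12),
             ...)
}

# Filter + bumphunt one simulated cohort (masking the cell-type list).
run_sim_cohort <- function(study, i, n_boot = 100, seed = 42, maxgap = 500,
                           cutoff_quantile = 0.95) {
  coh <- study$cohorts[[i]]
  man <- study$manifest[match(rownames(coh$beta), study$manifest$probe_id), ,
                        drop = FALSE]
  filt <- suppressWarnings(run_filter_stack(
    coh$beta, coh$detp, man,
    filter_config(exclusion_lists = list(celltype = study$truth$celltype_probes))))
  bumphunt(filt$matrix, filt$manifest, coh$samples, maxgap = maxgap,
           cutoff_quantile = cutoff_quantile, n_boot = n_boot, seed = seed)
}

# Full three-cohort pipeline -> consensus table.
run_sim_consensus <- function(study, n_boot = 100, seed = 42, maxgap = 500,
                              cutoff_quantile = 0.95, alpha = 0.05,
                              min_overlap = 2) {
  sig <- lapply(seq_along(study$cohorts), function(i)
    select_significant(run_sim_cohort(study, i, n_boot, seed, maxgap,
                                      cutoff_quantile)$regions, alpha))
  names(sig) <- names(study$cohorts)
  suppressWarnings(consensus_overlap(sig, min_overlap = min_overlap))
}

# Does the consensus table recover exactly the planted shared DMRs?
recovers_shared_truth <- function(cons, truth) {
  shared <- truth$dmrs[truth$dmrs$scope == "shared", , drop = FALSE]
  if (nrow(cons) != nrow(shared)) return(FALSE)
  if (sum(cons$direction == "hyper") != sum(shared$direction == "hyper"))
    return(FALSE)
  all(vapply(seq_len(nrow(shared)), function(i) {
    hit <- cons$chrom == shared$chrom[i] &
      cons$direction == shared$direction[i] &
      cons$intersect_start <= shared$end[i] &
      cons$intersect_end >= shared$start[i]
    sum(hit) == 1
  }, logical(1)))
}
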