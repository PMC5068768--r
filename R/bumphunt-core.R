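# Statistical core of the bump-hunting procedure: probe clustering,
# covariate-adjusted per-probe effect estimation on M-values, cluster-wise
# running-median smoothing, the bootstrap empirical null, quantile cut-off
# selection, candidate-region calling and region-level P/FDR/FWER.

#' Assign probes to clusters
#'
#' Greedy left-to-right partition of a sorted manifest: a new cluster starts
#' whenever the chromosome changes or the gap to the previous probe exceeds
#' `maxgap` (500 bp by default; 1000 bp in the sensitivity analysis).
#'
#' @param manifest Probe manifest sorted by (chrom, pos).
#' @param maxgap Maximum within-cluster gap between neighbouring probes (bp).
#' @return Integer vector of cluster ids, one per probe.
#' @export
cluster_probes <- function(manifest, maxgap = 500) {
  if (maxgap < 1) stopf("maxgap must be >= 1")
  n <- nrow(manifest)
  if (n == 0) return(integer(0))
  if (!manifest_is_sorted(manifest))
    stopf("manifest must be sorted by (chrom, pos)")
  if (n == 1) return(1L)
  new <- c(TRUE, manifest$chrom[-1] != manifest$chrom[-n] |
                 diff(manifest$pos) > maxgap)
  cumsum(new)
}

#' Build the case-control design matrix
#'
#' Columns: intercept, group indicator (case = 1), sex indicator (M = 1),
#' centred age and centred PMI. A covariate with any missing value is dropped
#' with a warning ("adjusted ... when available"); a rank-deficient design is
#' an error naming the collinear column.
#'
#' @param sheet Sample sheet with `sample_id`, `group` and optional `sex`,
#'   `age`, `pmi` columns.
#' @return A `dmr_design` list with elements `X` (matrix), `group_col`,
#'   `covariates` (used) and `dropped`.
#' @export
build_design <- function(sheet) {
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stopf("sample sheet needs 'sample_id' and 'group' columns")
  g <- tolower(as.character(sheet$group))
  if (!all(g %in% c("case", "control")))
    stopf("group must be 'case' or 'control'")
  if (sum(g == "case") < 2 || sum(g == "control") < 2)
    stopf("at least 2 cases and 2 controls are required")
  X <- cbind("(Intercept)" = rep(1, nrow(sheet)),
             group = as.numeric(g == "case"))
  used <- character(0)
  dropped <- character(0)
  for (cv in c("sex", "age", "pmi")) {
    if (!cv %in% names(sheet)) next
    if (cv == "sex") {
      v <- toupper(as.character(sheet$sex))
      v[!is.na(v) & !v %in% c("F", "M")] <- NA
      col <- as.numeric(v == "M")
    } else {
      col <- as.numeric(sheet[[cv]])
    }
    if (anyNA(col)) {
      dropped <- c(dropped, cv)
      warnf("covariate '%s' has missing values and was dropped from the design", cv)
      next
    }
    if (cv != "sex") col <- col - mean(col)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
    used <- c(used, cv)
  }
  rownames(X) <- sheet$sample_id
  if (qr(X)$rank < ncol(X)) {
    r0 <- 0L
    for (j in seq_len(ncol(X))) {
      r <- qr(X[, seq_len(j), drop = FALSE])$rank
      if (r == r0)
        stopf("design is rank deficient: column '%s' is collinear with the preceding columns",
              colnames(X)[j])
      r0 <- r
    }
  }
  structure(list(X = X, group_col = 2L, covariates = used, dropped = dropped),
            class = "dmr_design")
}

#' Estimate per-probe case-control M-value differences
#'
#' Ordinary least squares of each probe's M-values on the design; the raw
#' effect is the coefficient of the group indicator (case minus control,
#' adjusted for the covariates in the design).
#'
#' @param M Probes-by-samples matrix of finite M-values.
#' @param design A [build_design()] result.
#' @return An `effect_profile` list with `raw` (per-probe delta-M, named by
#'   probe), `smoothed` (`NULL` until [smooth_effects()]), `coefficients`
#'   (all design coefficients) and `covariates`.
#' @export
fit_probe_effects <- function(M, design) {
  X <- design$X
  if (ncol(M) != nrow(X))
    stopf("matrix has %d samples but the design has %d rows", ncol(M), nrow(X))
  if (!is.null(colnames(M)) && !identical(colnames(M), rownames(X)))
    stopf("matrix samples and design rows are misaligned; refusing to reorder")
  if (nrow(X) < ncol(X))
    stopf("fewer samples (%d) than design columns (%d)", nrow(X), ncol(X))
  if (any(!is.finite(M))) stopf("M-values must be finite")
  H <- solve(crossprod(X), t(X))          # (p_cols x n) hat-coefficient map
  coefs <- M %*% t(H)
  colnames(coefs) <- colnames(X)
  raw <- coefs[, design$group_col]
  names(raw) <- rownames(M)
  structure(list(raw = raw, smoothed = NULL, coefficients = coefs,
                 covariates = design$covariates),
            class = "effect_profile")
}

# Running median with truncated windows: smoothed_i = median of the raw values
# at indices [i-h, i+h] clipped to the vector. Interior points come from
# stats::runmed; the h edge points on each side are recomputed with the
# truncated window.
smooth_trunc <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  sm <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  for (i in seq_len(h)) sm[i] <- stats::median(x[1:(i + h)])
  for (i in (n - h + 1L):n) sm[i] <- stats::median(x[(i - h):n])
  sm
}

smooth_clusterwise <- function(x, cluster_idx, k) {
  out <- x
  if (k == 1L) return(out)
  for (ii in cluster_idx) out[ii] <- smooth_trunc(x[ii], k)
  out
}

# Index lists for clusters large enough to smooth (size >= k).
cluster_index <- function(clusters, k) {
  spl <- split(seq_along(clusters), clusters)
  spl[lengths(spl) >= k]
}

#' Smooth per-probe effects with cluster-wise running medians
#'
#' Within each probe cluster of size at least `k`, the smoothed value at a
#' probe is the median of the raw effects in a window of half-width
#' `(k - 1)/2` truncated at the cluster edges. Clusters smaller than `k` keep
#' their raw values.
#'
#' @param profile An `effect_profile` from [fit_probe_effects()], or a bare
#'   numeric vector.
#' @param clusters Cluster ids from [cluster_probes()].
#' @param k Odd window size (default 5).
#' @return The profile with `smoothed` filled (or a numeric vector if a vector
#'   was supplied).
#' @export
smooth_effects <- function(profile, clusters, k = 5) {
  if (k < 1 || k %% 2 != 1) stopf("smoothing window k must be odd and >= 1")
  raw <- if (inherits(profile, "effect_profile")) profile$raw else profile
  if (length(raw) != length(clusters))
    stopf("profile and cluster assignment lengths differ")
  sm <- smooth_clusterwise(as.numeric(raw), cluster_index(clusters, k), k)
  names(sm) <- names(raw)
  if (!inherits(profile, "effect_profile")) return(sm)
  profile$smoothed <- sm
  profile$smooth_k <- k
  profile
}

#' Bootstrap empirical null distribution of smoothed effects
#'
#' Fits the null model (design without the group column) per probe, then for
#' each bootstrap draws sample indices with replacement, forms
#' `fitted + resampled residuals`, re-fits the full design and smooths the
#' group-coefficient profile exactly as the observed data were smoothed. The
#' resulting probes-by-B matrix of smoothed null effects supplies both the
#' pooled statistics for cut-off selection and, after
#' [tabulate_null_regions()], the null region areas for P/FWER.
#'
#' @param M Probes-by-samples matrix of M-values.
#' @param design A [build_design()] result.
#' @param clusters Cluster ids from [cluster_probes()].
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param smooth_k Odd smoothing window (default 5).
#' @param seed Integer seed; the generator is seeded iff non-`NULL`.
#' @return A `null_dist` list: `smoothed` (p x B matrix), `n_boot`,
#'   `smooth_k`, `seed`, and `areas`/`max_area`/`cutoff` (filled by
#'   [tabulate_null_regions()]).
#' @export
bootstrap_null <- function(M, design, clusters, n_boot = 1000, smooth_k = 5,
                           seed = NULL) {
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (smooth_k < 1 || smooth_k %% 2 != 1) stopf("smooth_k must be odd and >= 1")
  X <- design$X
  gcol <- design$group_col
  X0 <- X[, -gcol, drop = FALSE]
  n <- nrow(X)
  p <- nrow(M)
  H0 <- solve(crossprod(X0), t(X0))
  Fit <- (M %*% t(H0)) %*% t(X0)          # null-model fitted values
  Res <- M - Fit
  Hg <- solve(crossprod(X), t(X))[gcol, ] # maps a sample vector to the group coef
  fg <- as.numeric(Fit %*% Hg)            # ~0: fitted values carry no group effect
  cidx <- cluster_index(clusters, smooth_k)
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(0, p, n_boot)
  for (b in seq_len(n_boot)) {
    draw <- sample.int(n, n, replace = TRUE)
    raw_b <- fg + as.numeric(Res[, draw, drop = FALSE] %*% Hg)
    S[, b] <- if (smooth_k > 1) smooth_clusterwise(raw_b, cidx, smooth_k) else raw_b
  }
  structure(list(smoothed = S, n_boot = n_boot, smooth_k = smooth_k,
                 seed = seed, areas = NULL, max_area = NULL, cutoff = NULL),
            class = "null_dist")
}

#' Select the effect-size cut-off from the empirical null
#'
#' Linear-interpolation empirical quantile (type 7) of the pooled absolute
#' smoothed null statistics.
#'
#' @param null A `null_dist` from [bootstrap_null()], or a numeric vector of
#'   pooled null statistics.
#' @param q Quantile in (0, 1\]; default 0.95 (sensitivity analysis: 0.975).
#' @return The cut-off, in M units.
#' @export
pick_cutoff <- function(null, q = 0.95) {
  if (q <= 0 || q > 1) stopf("q must lie in (0, 1]")
  pool <- if (inherits(null, "null_dist")) abs(null$smoothed) else abs(as.numeric(null))
  if (!length(pool)) stopf("empty null pool")
  as.numeric(stats::quantile(pool, q, names = FALSE, type = 7))
}

# Maximal same-sign runs of |smoothed| > cutoff within clusters. Returns one
# row per run with first/last probe index, probe count, signed sum, area
# (sum of |smoothed|), sign and cluster id.
region_runs <- function(sm, clusters, cutoff, min_probes = 1L) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  n <- length(sm)
  s <- (sm > cutoff) - (sm < -cutoff)
  keep <- s != 0
  empty <- data.frame(first = integer(0), last = integer(0), n = integer(0),
                      sum = numeric(0), area = numeric(0), sign = integer(0),
                      cluster = integer(0))
  if (!any(keep)) return(empty)
  newrun <- c(TRUE, s[-1] != s[-n] | clusters[-1] != clusters[-n])
  rid <- cumsum(newrun)
  idx <- which(keep)
  r <- rid[idx]
  first <- idx[!duplicated(r)]
  last <- idx[!duplicated(r, fromLast = TRUE)]
  cnt <- as.integer(rowsum(rep.int(1L, length(idx)), r))
  sums <- as.numeric(rowsum(sm[idx], r))
  areas <- as.numeric(rowsum(abs(sm[idx]), r))
  out <- data.frame(first = first, last = last, n = cnt, sum = sums,
                    area = areas, sign = s[first], cluster = clusters[first])
  out[out$n >= min_probes, , drop = FALSE]
}

#' Call candidate regions from the smoothed effect profile
#'
#' Within each cluster, maximal runs of consecutive probes whose smoothed
#' effect is strictly greater than `+cutoff` (hyper) or strictly less than
#' `-cutoff` (hypo) become candidate regions. Region coordinates are the
#' positions of the first and last probe in the run; `area` is the sum of
#' absolute smoothed effects over the run.
#'
#' @param profile An `effect_profile` with `smoothed` filled, or a numeric
#'   vector of smoothed effects.
#' @param clusters Cluster ids.
#' @param manifest Probe manifest aligned to the profile.
#' @param cutoff Positive effect-size cut-off (M units).
#' @param min_probes Minimum probes per region (default 1).
#' @return Data.frame of candidate regions with unfilled `p_value`, `fdr`,
#'   `fwer` columns.
#' @export
find_candidate_regions <- function(profile, clusters, manifest, cutoff,
                                   min_probes = 1) {
  sm <- if (inherits(profile, "effect_profile")) {
    if (is.null(profile$smoothed)) stopf("profile has not been smoothed")
    profile$smoothed
  } else as.numeric(profile)
  if (length(sm) != nrow(manifest))
    stopf("profile and manifest lengths differ")
  runs <- region_runs(sm, clusters, cutoff, min_probes)
  if (nrow(runs) == 0) return(empty_region_frame())
  data.frame(
    chrom = as.character(manifest$chrom[runs$first]),
    start = manifest$pos[runs$first],
    end = manifest$pos[runs$last],
    cluster_id = runs$cluster,
    n_probes = runs$n,
    avg_delta_m = runs$sum / runs$n,
    area = runs$area,
    direction = ifelse(runs$sign > 0, "hyper", "hypo"),
    probe_ids = vapply(seq_len(nrow(runs)), function(i)
      paste(manifest$probe_id[runs$first[i]:runs$last[i]], collapse = ","),
      character(1)),
    p_value = NA_real_, fdr = NA_real_, fwer = NA_real_,
    stringsAsFactors = FALSE)
}

#' Tabulate null regions at a chosen cut-off
#'
#' Re-scans each bootstrap's smoothed null profile for regions at the given
#' cut-off and records their areas and the per-bootstrap maximum area (0 when
#' a bootstrap yields no region).
#'
#' @param null A `null_dist` from [bootstrap_null()].
#' @param clusters Cluster ids used for the observed data.
#' @param cutoff Positive cut-off from [pick_cutoff()].
#' @param min_probes Minimum probes per region (default 1).
#' @return The `null_dist` with `areas` (list of per-bootstrap area vectors),
#'   `max_area` (length B) and `cutoff` filled.
#' @export
tabulate_null_regions <- function(null, clusters, cutoff, min_probes = 1) {
  B <- null$n_boot
  areas <- vector("list", B)
  mx <- numeric(B)
  for (b in seq_len(B)) {
    a <- region_runs(null$smoothed[, b], clusters, cutoff, min_probes)$area
    areas[[b]] <- a
    mx[b] <- if (length(a)) max(a) else 0
  }
  null$areas <- areas
  null$max_area <- mx
  null$cutoff <- cutoff
  null
}

#' Attach region-level P, FDR and FWER
#'
#' For a region of area A: `p_value` is the proportion of null regions
#' (pooled over all bootstraps) with area >= A (0 when the pool is empty);
#' `fwer` is the proportion of bootstraps whose maximum null area >= A;
#' `fdr` is the Benjamini-Hochberg adjustment of `p_value` across all
#' candidate regions.
#'
#' @param regions Candidate regions from [find_candidate_regions()].
#' @param null A `null_dist` with null areas tabulated.
#' @return The regions with `p_value`, `fdr` and `fwer` filled.
#' @export
score_regions <- function(regions, null) {
  if (is.null(null$areas))
    stopf("null region areas unavailable; run tabulate_null_regions() first")
  pool <- unlist(null$areas, use.names = FALSE)
  A <- regions$area
  p <- if (length(pool)) vapply(A, function(a) mean(pool >= a), numeric(1))
       else rep(0, length(A))
  regions$p_value <- p
  regions$fdr <- stats::p.adjust(p, method = "BH")
  regions$fwer <- vapply(A, function(a) mean(null$max_area >= a), numeric(1))
  regions
}

empty_region_frame <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             cluster_id = integer(0), n_probes = integer(0),
             avg_delta_m = numeric(0), area = numeric(0),
             direction = character(0), probe_ids = character(0),
             p_value = numeric(0), fdr = numeric(0), fwer = numeric(0),
             stringsAsFactors = FALSE)
}
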