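# The user-facing fitting function and its S3 methods. `bumphunt()` runs the
# whole procedure on one cohort: M-transform, design, per-probe effects,
# smoothing, bootstrap null, cut-off, candidate regions, region statistics.

#' Bump-hunting DMR detection on one cohort
#'
#' Orchestrates the full procedure: probes are aligned to the manifest and
#' sorted by (chrom, pos); beta values are logit-transformed to M-values;
#' per-probe case-control differences adjusted for the available covariates
#' are estimated by OLS and smoothed with cluster-wise running medians; a
#' bootstrap empirical null yields the effect-size cut-off (quantile of the
#' pooled absolute smoothed null statistics) and the null region areas from
#' which region-level P, FDR and FWER are computed.
#'
#' @param values Probes-by-samples matrix (rownames = probe ids, colnames =
#'   sample ids), beta or M scale per `scale`.
#' @param manifest Probe manifest covering exactly the probes of `values`.
#' @param samples Sample sheet covering exactly the samples of `values`.
#' @param scale Scale of `values`: `"beta"` (default; transformed internally)
#'   or `"M"`.
#' @param maxgap Maximum within-cluster probe gap in bp (default 500;
#'   sensitivity analysis 1000).
#' @param cutoff_quantile Quantile of the pooled absolute smoothed null
#'   statistics used as cut-off (default 0.95; sensitivity 0.975).
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param smooth_k Odd running-median window (default 5).
#' @param min_probes Minimum probes per candidate region (default 1).
#' @param alpha Region-level significance threshold on P (default 0.05).
#' @param fwer_alpha FWER threshold used in summaries (default 0.1).
#' @param epsilon Beta clamp bound for the logit transform (default 1e-3).
#' @param seed Integer seed for the bootstrap; drawn (and recorded) if `NULL`.
#' @param verbose Emit a one-line results message.
#' @return An object of class `"bumphunt"`: list with `regions` (scored
#'   candidate-region data.frame), `cutoff`, `null`, `profile`, `clusters`,
#'   `manifest`, `design`, `config` and `call`. Methods: `print`, `summary`,
#'   `coef`, `plot`.
#' @examples
#' study <- simulate_study(sim_config(n_clusters = 40, cases = c(12, 12, 12),
#'                                    controls = c(12, 12, 12)), seed = 1)
#' coh <- study$cohorts[[1]]
#' fit <- bumphunt(coh$beta, study$manifest, coh$samples,
#'                 n_boot = 50, seed = 7)
#' fit
#' head(coef(fit))
#' @export
bumphunt <- function(values, manifest, samples, scale = c("beta", "M"),
                     maxgap = 500, cutoff_quantile = 0.95, n_boot = 1000,
                     smooth_k = 5, min_probes = 1, alpha = 0.05,
                     fwer_alpha = 0.1, epsilon = 1e-3, seed = NULL,
                     verbose = FALSE) {
  scale <- match.arg(scale)
  if (cutoff_quantile <= 0 || cutoff_quantile >= 1)
    stopf("cutoff_quantile must lie in (0, 1)")
  if (is.null(rownames(values)))
    stopf("values must carry probe ids as rownames")
  if (!setequal(rownames(values), manifest$probe_id))
    stopf("matrix probes and manifest probes differ; refusing to guess an alignment")
  if (is.null(colnames(values)) || !setequal(colnames(values), samples$sample_id))
    stopf("matrix samples and sample sheet differ")

  manifest <- sort_manifest(manifest)
  mat <- values[manifest$probe_id, , drop = FALSE]
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]

  M <- if (scale == "beta") beta_to_m(mat, epsilon) else {
    validate_methyl_values(mat, "M")
    mat
  }

  design <- build_design(samples)
  clusters <- cluster_probes(manifest, maxgap)
  profile <- fit_probe_effects(M, design)
  profile <- smooth_effects(profile, clusters, smooth_k)

  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  null <- bootstrap_null(M, design, clusters, n_boot = n_boot,
                         smooth_k = smooth_k, seed = seed)
  cutoff <- pick_cutoff(null, cutoff_quantile)

  if (cutoff > 0) {
    null <- tabulate_null_regions(null, clusters, cutoff, min_probes)
    regions <- find_candidate_regions(profile, clusters, manifest, cutoff,
                                      min_probes)
    regions <- score_regions(regions, null)
  } else {
    # degenerate null (e.g. zero residuals): no exceedances are possible
    null$areas <- rep(list(numeric(0)), n_boot)
    null$max_area <- numeric(n_boot)
    null$cutoff <- cutoff
    regions <- empty_region_frame()
  }
  regions <- regions[order(regions$chrom, regions$start, method = "radix"), ,
                     drop = FALSE]
  rownames(regions) <- NULL

  obj <- structure(list(
    regions = regions, cutoff = cutoff, null = null, profile = profile,
    clusters = clusters, manifest = manifest, design = design,
    config = list(scale = scale, maxgap = maxgap,
                  cutoff_quantile = cutoff_quantile, n_boot = n_boot,
                  smooth_k = smooth_k, min_probes = min_probes, alpha = alpha,
                  fwer_alpha = fwer_alpha, epsilon = epsilon, seed = seed),
    n_samples = table(factor(tolower(samples$group), c("case", "control"))),
    call = match.call()), class = "bumphunt")
  if (verbose) message(results_line(obj))
  obj
}

results_line <- function(x) {
  sprintf("%d candidate DMR (cut-off M-value %.3g); %d with P<%g; %d with FWER<%g",
          nrow(x$regions), x$cutoff,
          sum(x$regions$p_value < x$config$alpha),
          x$config$alpha,
          sum(x$regions$fwer < x$config$fwer_alpha),
          x$config$fwer_alpha)
}

#' @export
print.bumphunt <- function(x, ...) {
  cat("Bump-hunting DMR analysis\n")
  cat(sprintf("  probes: %d in %d clusters (maxgap %d bp); samples: %d cases, %d controls\n",
              nrow(x$manifest), max(x$clusters), x$config$maxgap,
              x$n_samples[["case"]], x$n_samples[["control"]]))
  cat(sprintf("  covariates: %s\n",
              if (length(x$design$covariates))
                paste(x$design$covariates, collapse = ", ") else "none"))
  cat(sprintf("  bootstrap: %d samples, seed %d, cut-off quantile %g\n",
              x$config$n_boot, x$config$seed, x$config$cutoff_quantile))
  cat(" ", results_line(x), "\n")
  invisible(x)
}

#' @export
summary.bumphunt <- function(object, ...) {
  r <- object$regions
  sig <- r[r$p_value < object$config$alpha, , drop = FALSE]
  out <- list(
    n_probes = nrow(object$manifest),
    n_clusters = max(object$clusters),
    cutoff = object$cutoff,
    n_candidates = nrow(r),
    n_significant = nrow(sig),
    n_fwer = sum(r$fwer < object$config$fwer_alpha),
    by_direction = table(factor(sig$direction, c("hyper", "hypo"))),
    top = utils::head(r[order(-r$area), , drop = FALSE], 10),
    config = object$config)
  class(out) <- "summary.bumphunt"
  out
}

#' @export
print.summary.bumphunt <- function(x, ...) {
  cat(sprintf("Bump-hunting DMR analysis: %d probes, %d clusters\n",
              x$n_probes, x$n_clusters))
  cat(sprintf("  %d candidate DMR (cut-off M-value %.3g)\n",
              x$n_candidates, x$cutoff))
  cat(sprintf("  %d with P<%g (%d hyper, %d hypo); %d with FWER<%g\n",
              x$n_significant, x$config$alpha,
              x$by_direction[["hyper"]], x$by_direction[["hypo"]],
              x$n_fwer, x$config$fwer_alpha))
  if (nrow(x$top)) {
    cat("  top regions by area:\n")
    print(x$top[, c("chrom", "start", "end", "n_probes", "avg_delta_m",
                    "area", "direction", "p_value", "fdr", "fwer")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.bumphunt <- function(object, ...) {
  data.frame(probe_id = object$manifest$probe_id,
             chrom = object$manifest$chrom,
             pos = object$manifest$pos,
             cluster_id = object$clusters,
             raw_delta_m = as.numeric(object$profile$raw),
             smoothed_delta_m = as.numeric(object$profile$smoothed),
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.bumphunt <- function(x, ...) x$regions

#' Plot the smoothed effect profile of one chromosome
#'
#' Raw per-probe delta-M as grey points, the running-median smooth as a line
#' per cluster, the cut-off as dashed lines, and candidate regions shaded
#' (significant ones darker).
#'
#' @param x A `bumphunt` object.
#' @param chrom Chromosome to draw; defaults to the chromosome of the
#'   largest-area region (or the first chromosome when no regions exist).
#' @param xlim Optional position window.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bumphunt <- function(x, chrom = NULL, xlim = NULL, ...) {
  if (is.null(chrom)) {
    chrom <- if (nrow(x$regions)) x$regions$chrom[which.max(x$regions$area)]
             else x$manifest$chrom[1]
  }
  sel <- x$manifest$chrom == chrom
  if (!any(sel)) stopf("no probes on chromosome '%s'", chrom)
  pos <- x$manifest$pos[sel]
  raw <- x$profile$raw[sel]
  sm <- x$profile$smoothed[sel]
  cl <- x$clusters[sel]
  graphics::plot(pos, raw, col = "grey60", pch = 16, cex = 0.6, xlim = xlim,
                 xlab = sprintf("position on %s (bp)", chrom),
                 ylab = expression(Delta * M), ...)
  for (cc in unique(cl)) {
    ii <- cl == cc
    graphics::lines(pos[ii], sm[ii], col = "steelblue", lwd = 2)
  }
  graphics::abline(h = c(-x$cutoff, x$cutoff), lty = 2, col = "red")
  graphics::abline(h = 0, col = "grey80")
  reg <- x$regions[x$regions$chrom == chrom, , drop = FALSE]
  if (nrow(reg)) {
    usr <- graphics::par("usr")
    shade <- ifelse(reg$p_value < x$config$alpha,
                    grDevices::adjustcolor("firebrick", 0.3),
                    grDevices::adjustcolor("orange", 0.2))
    graphics::rect(reg$start, usr[3], reg$end, usr[4], col = shade, border = NA)
  }
  invisible(x)
}
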