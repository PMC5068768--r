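# Synthetic multi-cohort 450K-like study generator with planted DMRs.
# Emulates the statistical structure the analysis assumes -- cluster-shaped
# probe positions, a bimodal baseline methylation mixture on the M scale,
# additive case-control effects inside planted intervals, covariate effects,
# probe noise -- plus probes planted to fail each filter stage. Ground truth
# travels with the study so every pipeline stage is testable.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: three cohorts of
#' 24/24, 20/23 and 18/15 cases/controls, ~2000 probes in 250 clusters, five
#' shared hyper- and two shared hypo-methylated DMRs of effect 0.7 M units,
#' plus two cohort-private DMRs per cohort.
#'
#' @param n_cohorts Number of cohorts (default 3).
#' @param cases,controls Per-cohort group sizes.
#' @param n_clusters Number of probe clusters (default 250).
#' @param probes_per_cluster Inclusive range of cluster sizes, sampled
#'   uniformly (default 4-12).
#' @param gap_within Inclusive range of within-cluster probe gaps in bp
#'   (default 20-400).
#' @param gap_between Gap between consecutive clusters in bp (default 5000;
#'   must exceed any `maxgap` the analysis will use).
#' @param baseline_means M-value means of the unmethylated / intermediate /
#'   methylated baseline components (default -3, 0, +3).
#' @param baseline_weights Mixture weights of the baseline components
#'   (default 0.45, 0.10, 0.45).
#' @param noise_sd Per-probe, per-sample noise sd in M units (default 0.5).
#' @param n_shared_hyper,n_shared_hypo Shared (all-cohort) planted DMR counts
#'   (defaults 5 and 2).
#' @param n_private Cohort-private planted DMRs per cohort (default 2).
#' @param effect_size Planted |delta-M| (default 0.7).
#' @param dmr_probes Inclusive range of probes per planted DMR (default 4-10).
#' @param sex_effect,age_effect,pmi_effect Additive covariate effects in M
#'   units (per unit of the centred covariate; defaults 0.2, 0.01, 0.01).
#' @param frac_detection_fail,frac_snp,frac_sex_chrom,frac_celltype Fractions
#'   of probes planted to fail the respective filter stages.
#' @param cohort_shift Global per-cohort baseline shift in M units (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 3,
                       cases = c(24, 20, 18),
                       controls = c(24, 23, 15),
                       n_clusters = 250,
                       probes_per_cluster = c(4, 12),
                       gap_within = c(20, 400),
                       gap_between = 5000,
                       baseline_means = c(-3, 0, 3),
                       baseline_weights = c(0.45, 0.10, 0.45),
                       noise_sd = 0.5,
                       n_shared_hyper = 5,
                       n_shared_hypo = 2,
                       n_private = 2,
                       effect_size = 0.7,
                       dmr_probes = c(4, 10),
                       sex_effect = 0.2,
                       age_effect = 0.01,
                       pmi_effect = 0.01,
                       frac_detection_fail = 0.01,
                       frac_snp = 0.02,
                       frac_sex_chrom = 0.03,
                       frac_celltype = 0.02,
                       cohort_shift = 0) {
  if (length(cases) != n_cohorts || length(controls) != n_cohorts)
    stopf("cases and controls must each have length n_cohorts")
  if (any(cases < 2) || any(controls < 2))
    stopf("each cohort needs at least 2 cases and 2 controls")
  if (!is.finite(effect_size)) stopf("effect_size must be finite")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a probe manifest with cluster structure
#'
#' Lays `n_clusters` clusters of probes on chromosomes chr1-chr22 (plus
#' chrX/chrY for the configured sex-chromosome fraction), with within-cluster
#' gaps drawn from `gap_within` and clusters separated by `gap_between` bp.
#' A `frac_snp` fraction of autosomal probes gets SNP offsets drawn from
#' \{0, 1, 2\}.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A sorted probe manifest; the generating cluster ids are recoverable
#'   with `cluster_probes(manifest, maxgap = config$gap_within[2])`.
#' @export
simulate_manifest <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  nc <- config$n_clusters
  sizes <- safe_sample(config$probes_per_cluster[1]:config$probes_per_cluster[2],
                       nc, replace = TRUE)
  n_sex <- round(config$frac_sex_chrom * nc)
  cluster_chrom <- c(
    sample(paste0("chr", 1:22), nc - n_sex, replace = TRUE),
    sample(c("chrX", "chrY"), n_sex, replace = TRUE))

  chrom <- character(0)
  pos <- integer(0)
  for (ch in unique(cluster_chrom)) {
    at <- 10000L
    for (ci in which(cluster_chrom == ch)) {
      gaps <- safe_sample(config$gap_within[1]:config$gap_within[2],
                          sizes[ci] - 1, replace = TRUE)
      p <- at + c(0L, cumsum(gaps))
      chrom <- c(chrom, rep(ch, sizes[ci]))
      pos <- c(pos, p)
      at <- p[length(p)] + config$gap_between
    }
  }
  man <- data.frame(probe_id = "", chrom = chrom, pos = pos,
                    snp_offsets = "", stringsAsFactors = FALSE)
  man <- sort_manifest(man)
  man$probe_id <- sprintf("cg%07d", seq_len(nrow(man)))

  auto <- which(!is_sex_chrom(man$chrom))
  n_snp <- round(config$frac_snp * length(auto))
  if (n_snp > 0) {
    snp_probes <- sample(auto, n_snp)
    man$snp_offsets[snp_probes] <- vapply(
      snp_probes,
      function(i) paste(sort(sample(0:2, sample(1:2, 1))), collapse = ","),
      character(1))
  }
  validate_probe_manifest(man)
  man
}

# Choose planted-DMR intervals inside eligible clusters (autosomal, SNP-free,
# large enough) and return the truth table.
plant_dmrs <- function(manifest, clusters, config) {
  offs <- parse_snp_offsets(manifest$snp_offsets)
  has_snp <- lengths(offs) > 0
  eligible <- integer(0)
  spl <- split(seq_len(nrow(manifest)), clusters)
  ok <- vapply(spl, function(ii)
    !any(has_snp[ii]) && !any(is_sex_chrom(manifest$chrom[ii])) &&
      length(ii) >= config$dmr_probes[1], logical(1))
  eligible <- as.integer(names(spl))[ok]

  n_needed <- config$n_shared_hyper + config$n_shared_hypo +
    config$n_private * config$n_cohorts
  if (n_needed == 0)
    return(data.frame(dmr_id = integer(0), scope = character(0),
                      direction = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), delta_m = numeric(0),
                      probe_ids = character(0), stringsAsFactors = FALSE))
  if (length(eligible) < n_needed)
    stopf("only %d clusters eligible for planting but %d DMRs requested",
          length(eligible), n_needed)
  chosen <- safe_sample(eligible, n_needed)

  scope <- c(rep("shared", config$n_shared_hyper + config$n_shared_hypo),
             rep(paste0("cohort", seq_len(config$n_cohorts)),
                 each = config$n_private))
  direction <- c(rep("hyper", config$n_shared_hyper),
                 rep("hypo", config$n_shared_hypo),
                 sample(c("hyper", "hypo"),
                        config$n_private * config$n_cohorts, replace = TRUE))

  rows <- lapply(seq_along(chosen), function(d) {
    ii <- spl[[as.character(chosen[d])]]
    m <- safe_sample(config$dmr_probes[1]:min(config$dmr_probes[2], length(ii)), 1)
    at <- sample(length(ii) - m + 1, 1)
    probes <- ii[at:(at + m - 1)]
    data.frame(dmr_id = d, scope = scope[d], direction = direction[d],
               chrom = manifest$chrom[probes[1]],
               start = manifest$pos[probes[1]],
               end = manifest$pos[probes[m]],
               n_probes = m,
               delta_m = ifelse(direction[d] == "hyper", 1, -1) * config$effect_size,
               probe_ids = paste(manifest$probe_id[probes], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate one cohort from a manifest and planted truth
#'
#' Builds M-values as `baseline + group * delta(probe) + covariate effects +
#' noise`, converts to betas by inverse logit, and emits a detection-P matrix
#' whose planted failure probes draw from U(0.05, 1\] (U(0, 0.01\] elsewhere).
#'
#' @param manifest Probe manifest.
#' @param n_case,n_control Group sizes (>= 2 each).
#' @param delta Per-probe planted effect vector (0 outside planted DMRs).
#' @param fail_probes Probe ids planted to fail detection in this cohort.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param label Cohort label used in sample ids.
#' @return `list(beta =, detp =, samples =)`.
#' @export
simulate_cohort <- function(manifest, n_case, n_control, delta = NULL,
                            fail_probes = character(0),
                            config = sim_config(), seed = 1,
                            label = "cohort1") {
  set.seed(seed)
  p <- nrow(manifest)
  n <- n_case + n_control
  if (is.null(delta)) delta <- numeric(p)
  samples <- data.frame(
    sample_id = sprintf("%s_S%02d", label, seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::runif(n, 30, 90), 1),
    pmi = round(stats::runif(n, 5, 40), 1),
    stringsAsFactors = FALSE)

  comp <- sample.int(3, p, replace = TRUE, prob = config$baseline_weights)
  baseline <- config$baseline_means[comp]
  cov_eff <- config$sex_effect * (samples$sex == "M") +
    config$age_effect * (samples$age - 60) +
    config$pmi_effect * (samples$pmi - 22.5)
  M <- matrix(baseline, p, n) +
    outer(delta, as.numeric(samples$group == "case")) +
    matrix(cov_eff, p, n, byrow = TRUE) +
    config$cohort_shift
  if (config$noise_sd > 0)
    M <- M + matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
  beta <- m_to_beta(M)
  dimnames(beta) <- list(manifest$probe_id, samples$sample_id)

  detp <- matrix(stats::runif(p * n, 0, 0.01), p, n,
                 dimnames = dimnames(beta))
  fail <- rownames(detp) %in% fail_probes
  if (any(fail))
    detp[fail, ] <- stats::runif(sum(fail) * n, 0.05, 1)
  list(beta = beta, detp = detp, samples = samples)
}

#' Simulate a complete multi-cohort study with ground truth
#'
#' One manifest is shared by all cohorts; shared DMRs occupy identical
#' coordinates everywhere, private DMRs are planted in exactly one cohort,
#' and filter-failure probes (detection, SNP, sex chromosome, cell-type list)
#' never intersect planted DMRs.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; per-cohort seeds are derived from it.
#' @return A `sim_study` list: `manifest`, `cohorts` (named list of
#'   [simulate_cohort()] outputs), `truth` (planted DMR table, cell-type
#'   probe list, per-cohort detection-failure lists, covariate coefficients)
#'   and `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  manifest <- simulate_manifest(config, seed)
  set.seed(seed + 500000L)
  clusters <- cluster_probes(manifest, maxgap = config$gap_within[2])
  dmrs <- plant_dmrs(manifest, clusters, config)

  dmr_probe_ids <- unlist(strsplit(dmrs$probe_ids, ","), use.names = FALSE)
  free <- setdiff(manifest$probe_id, dmr_probe_ids)
  celltype <- sample(free, round(config$frac_celltype * nrow(manifest)))
  fail_lists <- lapply(seq_len(config$n_cohorts), function(i)
    sample(free, round(config$frac_detection_fail * nrow(manifest))))

  delta_for <- function(cohort_label) {
    d <- numeric(nrow(manifest))
    names(d) <- manifest$probe_id
    sel <- dmrs$scope %in% c("shared", cohort_label)
    for (r in which(sel)) {
      ids <- strsplit(dmrs$probe_ids[r], ",")[[1]]
      d[ids] <- dmrs$delta_m[r]
    }
    unname(d)
  }

  cohorts <- lapply(seq_len(config$n_cohorts), function(i) {
    label <- paste0("cohort", i)
    simulate_cohort(manifest, config$cases[i], config$controls[i],
                    delta = delta_for(label), fail_probes = fail_lists[[i]],
                    config = config, seed = seed + i, label = label)
  })
  names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
  names(fail_lists) <- names(cohorts)

  structure(list(
    manifest = manifest,
    cohorts = cohorts,
    truth = list(dmrs = dmrs, celltype_probes = celltype,
                 detection_fail = fail_lists,
                 covariates = c(sex = config$sex_effect,
                                age = config$age_effect,
                                pmi = config$pmi_effect)),
    config = config, seed = seed), class = "sim_study")
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Creates `manifest.tsv`, `celltype_probes.txt` and `truth.json` at the top
#' level and, per cohort, a subdirectory with `beta.tsv`, `detection_p.tsv`
#' and `samples.tsv`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_probe_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  writeLines(study$truth$celltype_probes, file.path(dir, "celltype_probes.txt"))
  jsonlite::write_json(
    list(dmrs = study$truth$dmrs,
         detection_fail = study$truth$detection_fail,
         covariates = as.list(study$truth$covariates),
         seed = study$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(study$cohorts)) {
    cd <- file.path(dir, nm)
    dir.create(cd, showWarnings = FALSE)
    coh <- study$cohorts[[nm]]
    write_methyl_matrix(coh$beta, file.path(cd, "beta.tsv"))
    write_methyl_matrix(coh$detp, file.path(cd, "detection_p.tsv"))
    utils::write.table(coh$samples, file.path(cd, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
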