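# Core bump-hunting operations: clustering, design, per-probe effects,
# running-median smoothing, cut-off selection, region calling and scoring.

test_that("probe clustering follows the maxgap rule", {
  man <- tiny_manifest(c(100L, 550L, 1200L))
  expect_identical(cluster_probes(man, 500), c(1L, 1L, 2L))   # gaps 450, 650
  expect_identical(cluster_probes(man, 1000), c(1L, 1L, 1L))  # sensitivity
  man2 <- tiny_manifest(c(100L, 101L), chrom = c("chr1", "chr2"))
  expect_identical(cluster_probes(man2, 500), c(1L, 2L))      # chrom boundary
  unsorted <- man[c(2, 1, 3), ]
  expect_error(cluster_probes(unsorted, 500), "sorted")
})

test_that("coarsening maxgap never splits an existing cluster", {
  set.seed(21)
  for (rep in 1:20) {
    pos <- cumsum(sample(50:2000, 60, replace = TRUE))
    man <- tiny_manifest(as.integer(pos),
                         chrom = rep(c("chr1", "chr2"), each = 30),
                         ids = sprintf("q%03d", 1:60))
    fine <- cluster_probes(man, 500)
    coarse <- cluster_probes(man, 1000)
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v)) == 1)))
  }
})

test_that("design matrix carries intercept, group and available covariates", {
  sheet <- tiny_sheet(3, 3, sex = c("F", "M", "F", "M", "F", "M"),
                      age = c(40, 50, 60, 45, 55, 65),
                      pmi = c(10, 25, 30, 12, 22, 31))
  d <- build_design(sheet)
  expect_identical(colnames(d$X),
                   c("(Intercept)", "group", "sex", "age", "pmi"))
  expect_equal(sum(d$X[, "age"]), 0)  # centred
  expect_identical(d$X[, "group"], setNames(rep(c(1, 0), each = 3),
                                            sheet$sample_id))

  sheet$pmi[2] <- NA
  expect_warning(d2 <- build_design(sheet), "pmi.*dropped")
  expect_identical(colnames(d2$X), c("(Intercept)", "group", "sex", "age"))
  expect_identical(d2$dropped, "pmi")

  confounded <- tiny_sheet(3, 3, sex = c("M", "M", "M", "F", "F", "F"))
  expect_error(build_design(confounded), "rank deficient.*sex")
  expect_error(build_design(tiny_sheet(1, 3)), "at least 2")
})

test_that("per-probe effects reduce to group-mean differences and match lm()", {
  # no covariates: exact closed-form identity
  mat <- tiny_matrix(c(2, 2, 0, 0), "p1", sprintf("S%02d", 1:4))
  sheet <- tiny_sheet(2, 2)
  prof <- fit_probe_effects(mat, build_design(sheet))
  expect_equal(unname(prof$raw), 2)

  # covariate orthogonal to group leaves the effect unchanged
  sheet2 <- tiny_sheet(2, 2, age = c(40, 60, 40, 60))  # balanced across groups
  prof2 <- fit_probe_effects(mat, build_design(sheet2))
  expect_equal(unname(prof2$raw), 2, tolerance = 1e-12)

  # constructed coefficients recovered exactly; lm() as independent oracle
  sheet3 <- tiny_sheet(3, 3, age = c(41, 52, 63, 44, 55, 66))
  d3 <- build_design(sheet3)
  y <- 0.3 + 1.5 * d3$X[, "group"] + 0.02 * d3$X[, "age"]
  mat3 <- tiny_matrix(y, "p1", sheet3$sample_id)
  prof3 <- fit_probe_effects(mat3, d3)
  expect_equal(unname(prof3$raw), 1.5, tolerance = 1e-9)
  lmfit <- lm(y ~ 0 + d3$X)
  expect_equal(unname(prof3$raw), unname(coef(lmfit)[2]), tolerance = 1e-9)

  # random matrices against lm(), probe by probe
  set.seed(33)
  mat4 <- tiny_matrix(rnorm(5 * 6), sprintf("r%d", 1:5), sheet3$sample_id)
  prof4 <- fit_probe_effects(mat4, d3)
  for (i in 1:5)
    expect_equal(unname(prof4$raw[i]),
                 unname(coef(lm(mat4[i, ] ~ 0 + d3$X))[2]), tolerance = 1e-9)

  expect_error(fit_probe_effects(mat3[, 1:2, drop = FALSE], d3), "samples")
})

test_that("running-median smoothing uses truncated windows within clusters", {
  # hand-enumerated truncated windows: medians of (0,5), (0,5,0), (5,0,0), (0,0)
  expect_equal(smooth_effects(c(0, 5, 0, 0), rep(1L, 4), k = 3),
               c(2.5, 0, 0, 0), ignore_attr = TRUE)
  # constants are fixed points
  expect_equal(smooth_effects(rep(3.3, 5), rep(1L, 5), k = 5), rep(3.3, 5),
               ignore_attr = TRUE)
  # clusters below the window size keep raw values
  expect_equal(smooth_effects(c(1, 9), c(1L, 1L), k = 5), c(1, 9),
               ignore_attr = TRUE)
  expect_error(smooth_effects(1:4, rep(1L, 4), k = 4), "odd")
})

test_that("smoothing matches the window-enumeration oracle and stays in range", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    k <- sample(c(3, 5, 7), 1)
    x <- rnorm(n)
    cl <- sort(sample(1:3, n, replace = TRUE))
    got <- smooth_effects(x, cl, k = k)
    want <- unlist(lapply(split(x, cl), function(v)
      if (length(v) >= k) oracle_runmed(v, k) else v), use.names = FALSE)
    expect_equal(got, want, ignore_attr = TRUE)
    # each smoothed value lies within [min, max] of its window's raw values
    h <- (k - 1) / 2
    for (i in seq_len(n)) {
      ii <- which(cl == cl[i] & abs(seq_len(n) - i) <= h)
      expect_gte(got[i], min(x[ii]) - 1e-12)
      expect_lte(got[i], max(x[ii]) + 1e-12)
    }
  }
})

test_that("cut-off selection is the interpolated quantile and is monotone in q", {
  expect_equal(pick_cutoff(seq(0.1, 1.0, by = 0.1), 1.0), 1.0)
  expect_equal(pick_cutoff(rep(0.42, 7), 0.5), 0.42)
  expect_equal(pick_cutoff((1:100) * 0.01, 0.95), 0.9505)
  set.seed(9)
  pool <- rexp(201)
  for (q in c(0.2, 0.5, 0.9, 0.95, 0.975))
    expect_equal(pick_cutoff(pool, q), oracle_quantile(abs(pool), q))
  qs <- sort(runif(10))
  cuts <- vapply(qs, function(q) pick_cutoff(pool, q), numeric(1))
  expect_true(all(diff(cuts) >= 0))
  expect_error(pick_cutoff(numeric(0), 0.95), "empty")
})

test_that("candidate regions are maximal same-sign runs above the cut-off", {
  man <- tiny_manifest(c(100L, 200L, 900L))
  r <- find_candidate_regions(c(0.3, 0.3, 0.1), c(1L, 1L, 1L), man, 0.2)
  expect_identical(nrow(r), 1L)
  expect_identical(r$start, 100L)
  expect_identical(r$end, 200L)
  expect_identical(r$n_probes, 2L)
  expect_equal(r$avg_delta_m, 0.3)
  expect_equal(r$area, 0.6)
  expect_identical(r$direction, "hyper")
  expect_identical(r$probe_ids, "p001,p002")

  # sign change splits runs
  man2 <- tiny_manifest(c(100L, 200L))
  r2 <- find_candidate_regions(c(-0.3, 0.3), c(1L, 1L), man2, 0.2)
  expect_identical(r2$direction, c("hypo", "hyper"))
  expect_identical(r2$n_probes, c(1L, 1L))

  # cluster boundary splits runs even without a sign change
  r3 <- find_candidate_regions(c(0.3, 0.3), c(1L, 2L), man2, 0.2)
  expect_identical(nrow(r3), 2L)

  # values exactly at the cut-off are excluded (strict inequality)
  r4 <- find_candidate_regions(c(0.2, 0.3), c(1L, 1L), man2, 0.2)
  expect_identical(nrow(r4), 1L)
  expect_identical(r4$start, 200L)
})

test_that("region calling matches brute-force run enumeration", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    sm <- round(rnorm(n, 0, 0.4), 3)
    cl <- cumsum(c(1L, sample(0:1, n - 1, replace = TRUE,
                              prob = c(0.8, 0.2))))
    man <- tiny_manifest(as.integer(seq_len(n) * 100))
    cutoff <- runif(1, 0.05, 0.6)
    minp <- sample(1:2, 1)
    got <- find_candidate_regions(sm, cl, man, cutoff, min_probes = minp)
    want <- oracle_regions(sm, cl, man, cutoff, min_probes = minp)
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
    # invariants: consistent sign, area identity, disjointness
    if (nrow(got)) {
      expect_equal(got$area, abs(got$avg_delta_m) * got$n_probes,
                   tolerance = 1e-12)
      expect_true(all(got$start <= got$end))
    }
  }
})

test_that("region scoring counts null areas and bootstrap maxima", {
  null <- structure(list(areas = list(c(1, 2), c(3, 4)), max_area = c(3, 4),
                         n_boot = 2L, cutoff = 0.1), class = "null_dist")
  reg <- data.frame(area = c(2.5, 3.5), stringsAsFactors = FALSE)
  scored <- score_regions(reg, null)
  expect_equal(scored$p_value, c(2 / 4, 1 / 4))  # pooled-null proportions
  expect_equal(scored$fwer, c(1, 1 / 2))         # per-bootstrap maxima
  # p and fwer are non-increasing in area
  areas <- seq(0.5, 5, by = 0.5)
  sc <- score_regions(data.frame(area = areas), null)
  expect_true(all(diff(sc$p_value) <= 0))
  expect_true(all(diff(sc$fwer) <= 0))
  # empty pool gives p = 0
  null0 <- structure(list(areas = list(numeric(0)), max_area = 0,
                          n_boot = 1L, cutoff = 0.1), class = "null_dist")
  expect_equal(score_regions(data.frame(area = 1), null0)$p_value, 0)
})

test_that("bootstrap null is deterministic under seed and degenerate when residuals vanish", {
  set.seed(2)
  sheet <- tiny_sheet(4, 4)
  d <- build_design(sheet)
  man <- tiny_manifest(as.integer(cumsum(c(100, rep(150, 19)))))
  cl <- cluster_probes(man, 500)
  M <- tiny_matrix(rnorm(20 * 8), man$probe_id, sheet$sample_id)

  n1 <- bootstrap_null(M, d, cl, n_boot = 20, seed = 99)
  n2 <- bootstrap_null(M, d, cl, n_boot = 20, seed = 99)
  expect_identical(n1$smoothed, n2$smoothed)

  # data equal to the null fit: all null smoothed stats are 0
  X0 <- d$X[, -d$group_col, drop = FALSE]
  Mfit <- M %*% t(solve(crossprod(X0), t(X0))) %*% t(X0)
  dimnames(Mfit) <- dimnames(M)
  n0 <- bootstrap_null(Mfit, d, cl, n_boot = 10, seed = 1)
  expect_lt(max(abs(n0$smoothed)), 1e-10)
  tab <- tabulate_null_regions(n0, cl, cutoff = 0.05)
  expect_true(all(lengths(tab$areas) == 0))
  expect_equal(tab$max_area, rep(0, 10))
})

test_that("null exceedance rate at the 95% cut-off is about 5% by construction", {
  set.seed(4)
  cfg <- sim_config(n_cohorts = 1, cases = 8, controls = 8, n_clusters = 25,
                    n_shared_hyper = 0, n_shared_hypo = 0, n_private = 0,
                    frac_detection_fail = 0, frac_snp = 0, frac_sex_chrom = 0,
                    frac_celltype = 0)
  study <- simulate_study(cfg, seed = 6)
  coh <- study$cohorts[[1]]
  M <- beta_to_m(coh$beta)
  d <- build_design(coh$samples)
  cl <- cluster_probes(study$manifest, 500)
  null <- bootstrap_null(M, d, cl, n_boot = 100, seed = 10)
  cutoff <- pick_cutoff(null, 0.95)
  prof <- smooth_effects(fit_probe_effects(M, d), cl, 5)
  frac <- mean(abs(prof$smoothed) > cutoff)
  expect_lt(abs(frac - 0.05), 0.05)  # Monte-Carlo slack
})
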