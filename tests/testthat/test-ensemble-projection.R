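test_that("TSS evaluation enumerates cuts exactly and satisfies its identity", {
  res <- eval_tss(c(0.9, 0.8), c(0.7, 0.1))
  expect_equal(res$threshold, 0.8)
  expect_equal(res$tss, 1)

  perfect <- eval_tss(runif(20, 0.6, 1), runif(30, 0, 0.5))
  expect_equal(perfect$tss, 1)

  expect_warning(flat <- eval_tss(rep(0.4, 5), rep(0.4, 7)), "constant")
  expect_equal(flat$tss, 0)

  set.seed(12)
  for (k in 1:20) {
    r <- eval_tss(runif(15), runif(25))
    expect_equal(r$tss, r$sensitivity + r$specificity - 1)
    expect_gte(r$tss, -1); expect_lte(r$tss, 1)
  }
})

test_that("a random-score map has no skill on average", {
  set.seed(31)
  # at the *optimal* cut the finite-sample TSS of a skill-less map is
  # positively biased (a KS-statistic); at a fixed cut it is unbiased
  tss_opt <- replicate(100, eval_tss(runif(40), runif(40))$tss)
  expect_lt(mean(tss_opt), 0.35)
  expect_gt(mean(tss_opt), 0)
  tss_fixed <- replicate(100, {
    p <- runif(40); b <- runif(40)
    mean(p >= 0.5) + mean(b < 0.5) - 1
  })
  expect_lt(abs(mean(tss_fixed)), 0.1)
})

test_that("replicate runs produce algorithms x reps maps with held-out TSS", {
  sys <- separable_system()
  maps <- suppressWarnings(
    run_replicates(sys$occ, sys$bg, sys$stack, n_rep = 10, seed = 5))
  expect_length(maps, 40)
  expect_equal(sort(unique(vapply(maps, function(m) m$algorithm, ""))),
               c("bioclim", "domain", "maxent", "svm"))
  tss <- vapply(maps, function(m) m$tss, numeric(1))
  expect_gt(min(tss), 0.9)   # strongly separable fixture

  again <- suppressWarnings(
    run_replicates(sys$occ, sys$bg, sys$stack, n_rep = 10, seed = 5))
  expect_equal(tss, vapply(again, function(m) m$tss, numeric(1)))

  expect_error(
    run_replicates(sys$occ[1:8, ], sys$bg, sys$stack, n_rep = 2, seed = 1),
    class = "palmsdm_invalid_argument")
})

test_that("the TSS-weighted ensemble matches its closed form", {
  mk <- function(vals, tss) {
    suitability_map(matrix(vals, 3, 1), c(0, 1, 0, 3), algorithm = "x",
                    replicate_id = 1L, tss = tss)
  }
  ens <- ensemble(list(mk(c(0, 0.5, 1), 0.8), mk(c(1, 0.5, 0), 0.6)),
                  tss_min = 0.5)
  expect_equal(as.vector(ens$mean), c(0.6 / 1.4, 0.5, 0.8 / 1.4),
               tolerance = 1e-6)
  expect_equal(ens$n_contributing, 2)

  # one passing map -> the ensemble is that map rescaled
  one <- ensemble(list(mk(c(0.1, 0.4, 0.7), 0.9), mk(c(1, 0, 0), 0.2)))
  expect_equal(as.vector(one$mean), c(0, 0.5, 1))

  # identical maps -> zero dispersion
  same <- ensemble(list(mk(c(0, 0.5, 1), 0.7), mk(c(0, 0.5, 1), 0.8)))
  expect_true(all(same$dispersion == 0))

  expect_error(ensemble(list(mk(c(0, 1, 0), 0.3))),
               class = "palmsdm_empty_ensemble")
})

test_that("threshold rules match their definitions on training presences", {
  pres <- seq(0.2, 1, by = 0.1)          # nine ascending suitabilities
  bg <- runif(50, 0, 0.6)
  suppressWarnings(thr <- compute_thresholds(pres, bg))
  expect_equal(unname(thr["MTP"]), 0.2)
  expect_true(mean(pres >= thr["MTP"]) == 1)       # MTP keeps all presences

  set.seed(2)
  pres2 <- runif(40, 0.3, 1)
  thr2 <- compute_thresholds(pres2, bg)
  expect_gte(mean(pres2 >= thr2["P10"]), 0.9)      # P10 keeps >= 90%
  ss <- eval_tss(pres2, bg)
  expect_equal(unname(thr2["maxSS"]), ss$threshold)
})

test_that("binary ranges, areas and overlaps follow the spherical cell model", {
  # 2x2 grid of ~1 km2 cells near the equator
  dlon <- 1 / 111.320; dlat <- 1 / 110.574
  ext <- c(0, 2 * dlon, 0, 2 * dlat)
  m1 <- suitability_map(matrix(c(1, 1, 1, 0), 2, 2), ext, tss = 1)
  m2 <- suitability_map(matrix(c(1, 1, 0, 1), 2, 2), ext, tss = 1)
  r1 <- binarize(m1, 0.5, "maxSS")
  r2 <- binarize(m2, 0.5, "maxSS")
  expect_equal(r1$area_km2, 3, tolerance = 1e-3)
  ov <- overlap_area(r1, r2)
  expect_equal(ov$overlap_km2, 2, tolerance = 1e-3)
  expect_equal(ov$pct_of_r1, 100 * 2 / 3, tolerance = 0.1)

  self <- overlap_area(r1, r1)
  expect_equal(self$pct_of_r1, 100)
  expect_equal(overlap_area(r1, binarize(m1, 2, "x"))$overlap_km2, 0)

  other <- binarize(suitability_map(matrix(1, 3, 3), ext), 0.5)
  expect_error(overlap_area(r1, other), class = "palmsdm_invalid_argument")
})

test_that("projection reuses fitted models and follows climate displacement", {
  sys <- separable_system()
  maps <- suppressWarnings(run_replicates(sys$occ, sys$bg, sys$stack,
                                          algorithms = c("bioclim", "domain"),
                                          n_rep = 5, seed = 5))
  ens <- ensemble(maps, tss_min = 0.5)

  # projecting onto the identical stack reproduces the ensemble
  same <- project_ensemble(ens, sys$stack)
  expect_equal(same$mean, ens$mean, tolerance = 1e-12)

  # warming every layer beyond the envelope empties a bioclim-only ensemble
  bio_only <- ensemble(Filter(function(m) m$algorithm == "bioclim", maps),
                       tss_min = 0.5)
  hot <- env_stack(lapply(sys$stack$layers, function(m) m + 50),
                   extent = sys$stack$extent)
  hot_ens <- project_ensemble(bio_only, hot)
  expect_equal(binarize(hot_ens, 0.5)$area_km2, 0)
})

test_that("uncertainty maps are per-cell SDs of rescaled replicates", {
  ext <- c(0, 1, 0, 1)
  a <- suitability_map(matrix(c(0, 1), 1, 2), ext)
  b <- suitability_map(matrix(c(1, 0), 1, 2), ext)
  u <- uncertainty_map(list(a, b))
  expect_equal(as.vector(u$values), c(sqrt(0.5), sqrt(0.5)), tolerance = 1e-6)
  expect_equal(uncertainty_map(list(b, a))$values, u$values)
  expect_true(all(uncertainty_map(list(a, a))$values == 0))
  expect_error(uncertainty_map(list(a)), class = "palmsdm_degenerate_input")
})
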