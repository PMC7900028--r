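test_that("generated stacks are deterministic, correlated and autocorrelated as requested", {
  st1 <- gen_env_stack(50, 50, n_layers = 3, layer_corr = 0.4, seed = 7)
  st2 <- gen_env_stack(50, 50, n_layers = 3, layer_corr = 0.4, seed = 7)
  expect_identical(st1, st2)

  # empirical inter-layer correlation is imposed exactly by construction
  cm <- cor(env_values(st1))
  expect_equal(unname(cm[lower.tri(cm)]), rep(0.4, 3), tolerance = 1e-10)

  st0 <- gen_env_stack(200, 200, n_layers = 2, layer_corr = 0, seed = 3)
  expect_lt(abs(cor(env_values(st0))[1, 2]), 0.1)

  smooth <- gen_env_stack(80, 80, 2, autocorr_length = 20, seed = 5)
  rough <- gen_env_stack(80, 80, 2, autocorr_length = 1, seed = 5)
  expect_gt(moran_i(smooth$layers[[1]]), moran_i(rough$layers[[1]]))

  expect_error(gen_env_stack(0, 10, 2), class = "palmsdm_invalid_argument")
  expect_error(gen_env_stack(10, 10, 1), class = "palmsdm_invalid_argument")
  expect_error(gen_env_stack(10, 10, 2, layer_corr = 1),
               class = "palmsdm_invalid_argument")
})

test_that("virtual species suitability is Gaussian with mode at the niche center", {
  st <- test_stack()
  env <- bg_table(st)
  mu <- env[417, ]  # an arbitrary cell's environment
  vs <- gen_virtual_species(st, virtual_species("sp", mu, 0.4))
  expect_equal(as.vector(vs$suitability)[417], 1.0)
  expect_true(all(vs$suitability <= 1 & vs$suitability >= 0))

  # quadrupling the covariance strictly widens the niche
  narrow <- gen_virtual_species(st, virtual_species("sp", mu, 0.4))
  wide <- gen_virtual_species(st, virtual_species("sp", mu, 1.6))
  expect_gt(sum(wide$suitability > 0.5), sum(narrow$suitability > 0.5))

  # prevalence calibration hits the requested suitable fraction exactly
  # (the boundary cell itself sits at suitability 0.5)
  vp <- gen_virtual_species(st, virtual_species("sp", mu, 0.4,
                                                prevalence = 0.25))
  expect_equal(mean(vp$suitability >= 0.5), 0.25, tolerance = 1e-9)

  bad_sigma <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(virtual_species("sp", mu, bad_sigma),
               class = "palmsdm_invalid_argument")
})

test_that("sampled occurrences track the niche center and only occupy suitable cells", {
  st <- test_stack(n = 60)
  env <- bg_table(st)
  mu <- env[which.min(rowSums(env^2)), ]  # near the environmental centroid
  vs <- gen_virtual_species(st, virtual_species("sp", mu, 0.5))
  occ <- sample_occurrences(vs, st, n = 500, seed = 11)
  expect_gt(nrow(occ), 300)
  e <- extract_env(st, occ$lon, occ$lat)
  for (k in seq_len(ncol(e))) {
    se <- sd(e[, k]) / sqrt(nrow(e))
    expect_lt(abs(mean(e[, k]) - mu[k]), 2 * se + 0.05)
  }
  s_at <- vs$suitability[cbind(
    palmsdm:::cell_row_col(st, occ$lon, occ$lat)$row,
    palmsdm:::cell_row_col(st, occ$lon, occ$lat)$col)]
  expect_true(all(s_at > 0))
  expect_identical(occ, sample_occurrences(vs, st, n = 500, seed = 11))
})

test_that("brute-force Schoener's D oracle matches hand cases and its invariances", {
  st <- test_stack()
  env <- bg_table(st)
  vs1 <- gen_virtual_species(st, virtual_species("a", env[100, ], 0.4))
  expect_equal(true_overlap_d(vs1, vs1), 1.0)

  # hand evaluation on a 2-cell surface
  p1 <- fake_species(matrix(c(0.6, 0.4), 1))
  p2 <- fake_species(matrix(c(0.4, 0.6), 1))
  expect_equal(true_overlap_d(p1, p2), 0.8)

  disj1 <- fake_species(matrix(c(1, 0, 0, 0), 2))
  disj2 <- fake_species(matrix(c(0, 0, 0, 1), 2))
  expect_equal(true_overlap_d(disj1, disj2), 0)

  # symmetry and positive-rescaling invariance across random surfaces
  set.seed(99)
  for (k in 1:20) {
    a <- fake_species(matrix(runif(16), 4))
    b <- fake_species(matrix(runif(16), 4))
    expect_equal(true_overlap_d(a, b), true_overlap_d(b, a))
    a_scaled <- fake_species(a$suitability * 7.3)
    expect_equal(true_overlap_d(a_scaled, b), true_overlap_d(a, b),
                 tolerance = 1e-12)
  }
  zero <- fake_species(matrix(0, 2, 2))
  expect_error(true_overlap_d(zero, disj1), class = "palmsdm_degenerate_input")
})

test_that("interaction generator reproduces requested shared/unique structure", {
  tabs <- gen_interactions(3, 2, 3, seed = 5)
  sets <- species_sets(tabs$interactions)
  expect_length(sets$set_a, 5)
  expect_length(sets$set_b, 6)
  expect_length(intersect(sets$set_a, sets$set_b), 3)
  # every bird has exactly one trait row, all traits positive
  birds <- unique(tabs$interactions$bird)
  expect_setequal(tabs$traits$bird, birds)
  expect_false(any(duplicated(tabs$traits$bird)))
  expect_true(all(as.matrix(tabs$traits[-1]) > 0))
  expect_identical(tabs, gen_interactions(3, 2, 3, seed = 5))
  expect_error(gen_interactions(0, 0, 0), class = "palmsdm_invalid_argument")
  expect_error(gen_interactions(-1, 2, 3), class = "palmsdm_invalid_argument")
})
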