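test_that("ordination standardizes, centers and orders variance correctly", {
  set.seed(1)
  x <- rnorm(200)
  dup <- cbind(a = x, b = x)                 # rank-1: axis 1 carries all variance
  ord <- fit_ordination(dup)
  expect_equal(ord$explained[1], 1, tolerance = 1e-12)

  big <- cbind(u = rnorm(10000), v = rnorm(10000))
  ord2 <- fit_ordination(big)
  expect_equal(unname(ord2$explained), c(0.5, 0.5), tolerance = 0.02)
  expect_true(all(diff(ord2$explained) <= 0))

  # the variable means project to the origin
  ctr <- ord_scores(ord2, matrix(ord2$means, 1,
                                 dimnames = list(NULL, names(ord2$means))))
  expect_equal(as.numeric(ctr), c(0, 0), tolerance = 1e-12)

  const <- cbind(u = rnorm(50), v = rnorm(50), w = rep(1, 50))
  expect_warning(fit_ordination(const), "constant")
  expect_error(fit_ordination(cbind(a = 1:2, b = 2:1)),
               class = "palmsdm_invalid_argument")
})

test_that("occupancy grids are proper availability-masked densities", {
  st <- test_stack(n = 50)
  bg <- bg_table(st)
  ord <- fit_ordination(bg)

  g <- occupancy_grid(ord, bg[1:200, ], bg, R = 100)
  expect_equal(dim(g$z), c(100, 100))
  expect_equal(sum(g$z), 1, tolerance = 1e-9)
  expect_equal(sum(g$a), 1, tolerance = 1e-9)
  expect_true(all(g$z >= 0))
  expect_true(all(g$z[g$a == 0] == 0))

  # all occurrences at one environmental point -> density peaks there
  one <- bg[rep(703, 5), ]
  g1 <- occupancy_grid(ord, one, bg, R = 60)
  pk <- which(g1$z == max(g1$z), arr.ind = TRUE)[1, ]
  sc <- ord_scores(ord, one[1, , drop = FALSE])
  bx <- g1$bounds$x; by <- g1$bounds$y
  expect_equal(unname(pk["row"]),
               ceiling((sc[1] - bx[1]) / diff(bx) * 60), tolerance = 1)
  expect_equal(unname(pk["col"]),
               ceiling((sc[2] - by[1]) / diff(by) * 60), tolerance = 1)

  # occurrences distributed exactly like the background (one record per
  # background point) reproduce the availability density
  gu <- occupancy_grid(ord, bg, bg, R = 100)
  expect_lt(max(abs(gu$z - gu$a)), 0.1 / 100^2)

  # an independent availability-shaped sample agrees to kernel accuracy
  idx <- withr::with_seed(5, sample.int(nrow(bg), 10000, replace = TRUE))
  gs <- occupancy_grid(ord, bg[idx, ], bg, R = 100)
  expect_lt(max(abs(gs$z - gs$a)), 25 * 0.1 / 100^2)

  # availability correction flattens a background-shaped sample
  gc <- occupancy_grid(ord, bg[idx, ], bg, R = 100, availability_correct = TRUE)
  expect_gt(sum(gc$z > 0.5 * max(gc$z)), sum(gs$z > 0.5 * max(gs$z)))
})

test_that("Schoener's D matches hand values, is symmetric and permutation-invariant", {
  z1 <- occupancy_grid_raw(matrix(c(0.6, 0.4), 1))
  z2 <- occupancy_grid_raw(matrix(c(0.4, 0.6), 1))
  expect_equal(schoener_d(z1, z2), 0.8)
  expect_equal(schoener_d(z1, z1), 1)

  da <- occupancy_grid_raw(matrix(c(1, 0, 0, 0), 2))
  db <- occupancy_grid_raw(matrix(c(0, 0, 0, 1), 2))
  expect_equal(schoener_d(da, db), 0)

  set.seed(4)
  for (k in 1:10) {
    a <- matrix(runif(36), 6)
    b <- matrix(runif(36), 6)
    ga <- occupancy_grid_raw(a); gb <- occupancy_grid_raw(b)
    expect_equal(schoener_d(ga, gb), schoener_d(gb, ga))
    perm <- sample(36)
    gap <- occupancy_grid_raw(matrix(as.vector(a)[perm], 6))
    gbp <- occupancy_grid_raw(matrix(as.vector(b)[perm], 6))
    expect_equal(schoener_d(gap, gbp), schoener_d(ga, gb), tolerance = 1e-12)
  }

  wrong <- occupancy_grid_raw(matrix(runif(16), 4))
  expect_error(schoener_d(z1, wrong), class = "palmsdm_invalid_argument")
})

test_that("grid D equals the brute-force oracle when built from raw suitabilities", {
  st <- test_stack(n = 30)
  env <- bg_table(st)
  set.seed(21)
  for (k in 1:10) {
    v1 <- gen_virtual_species(st, virtual_species("a", env[sample.int(900, 1), ], 0.5))
    v2 <- gen_virtual_species(st, virtual_species("b", env[sample.int(900, 1), ], 0.5))
    g1 <- occupancy_grid_raw(v1$suitability)
    g2 <- occupancy_grid_raw(v2$suitability)
    expect_equal(schoener_d(g1, g2), true_overlap_d(v1, v2), tolerance = 1e-12)
  }
})

test_that("similarity test detects identity and respects its rank-based p floor", {
  st <- test_stack(n = 40)
  bg <- bg_table(st)
  ord <- fit_ordination(bg)
  vs <- gen_virtual_species(st, virtual_species("a", bg[800, ], 0.4))
  occ <- sample_occurrences(vs, st, n = 120, seed = 3)
  g <- occupancy_grid(ord, extract_env(st, occ$lon, occ$lat), bg, R = 60)
  res <- similarity_test(g, g, n_reps = 199, seed = 9)
  expect_equal(res$D, 1)
  expect_lte(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / 200)   # +1-corrected rank floor
  expect_equal(tidy(res)$D, 1)

  expect_error(similarity_test(g, g, n_reps = 50),
               class = "palmsdm_invalid_argument")
  tiny <- occupancy_grid_raw(matrix(c(1, 0, 0, 0), 2),
                             a = matrix(c(1, 0, 0, 0), 2))
  expect_error(similarity_test(tiny, tiny, n_reps = 99),
               class = "palmsdm_degenerate_input")
})

test_that("functional overlap tracks trait-space similarity, not species identity", {
  # identical sets -> identical grids -> D = 1
  tabs <- gen_interactions(10, 5, 5, seed = 2)
  sets <- species_sets(tabs$interactions)
  res <- functional_overlap(tabs$traits, sets$set_a, sets$set_a,
                            n_reps = 99, seed = 1)
  expect_equal(res$D, 1)

  # disjoint, well-separated trait clusters -> near-zero overlap
  traits <- tibble::tibble(
    bird = sprintf("b%02d", 1:40),
    body_mass_g = c(rep(10, 20), rep(4000, 20)) * exp(rnorm(40, 0, 0.05)),
    bill_width_mm = c(rep(4, 20), rep(40, 20)) * exp(rnorm(40, 0, 0.05)),
    wing_length_mm = c(rep(50, 20), rep(400, 20)) * exp(rnorm(40, 0, 0.05)))
  far <- functional_overlap(traits, traits$bird[1:20], traits$bird[21:40],
                            n_reps = 99, seed = 1)
  expect_lt(far$D, 0.05)

  # compositionally dissimilar sets drawn from one trait pool still overlap
  # strongly in function (the invasion-ecology signal this module targets)
  pool <- gen_interactions(20, 17, 17, seed = 6)   # beta_sor ~ 0.46
  ps <- species_sets(pool$interactions)
  beta <- sorensen_partition(ps$set_a, ps$set_b)
  shared_fun <- functional_overlap(pool$traits, ps$set_a, ps$set_b,
                                   n_reps = 99, seed = 1)
  expect_gt(shared_fun$D, 1 - beta$beta_sor)

  expect_error(
    functional_overlap(tabs$traits[-1, ], sets$set_a, sets$set_b, n_reps = 99),
    class = "palmsdm_missing_traits")
})
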