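test_that("variable selection keeps one representative per latent factor", {
  set.seed(3)
  n <- 400
  base <- rnorm(n)
  x <- cbind(a = base, b = base + rnorm(n, 0, 0.05),
             c = base + rnorm(n, 0, 0.05), d = rnorm(n))
  sel <- select_variables(x)
  expect_length(sel$selected, 2)        # one copy-factor rep + the lone var
  expect_true("d" %in% sel$selected)

  ortho <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  sel_o <- select_variables(ortho)
  expect_length(sel_o$selected, sel_o$n_factors)

  # engineered latent structure: k factors -> k selected variables
  for (k in c(5, 6)) {
    set.seed(10 + k)
    f <- matrix(rnorm(n * k), n, k)
    idx <- rep(seq_len(k), length.out = 19)  # round-robin factor membership
    x19 <- sapply(seq_len(19), function(j) f[, idx[j]] + rnorm(n, 0, 0.45))
    colnames(x19) <- paste0("bio", 1:19)
    sel_k <- select_variables(x19)
    expect_equal(sel_k$n_factors, k)
    expect_length(sel_k$selected, k)
    cm <- cor(x19[, sel_k$selected])
    expect_true(all(abs(cm[lower.tri(cm)]) < 0.7))
  }
})

test_that("correlated representatives are substituted by the next contributor", {
  loadings <- matrix(c(0.9, 0.1, 0.05,
                       0.2, 0.85, 0.80), 3, 2,
                     dimnames = list(c("v1", "v2", "v3"), c("F1", "F2")))
  cormat <- matrix(c(1, 0.75, 0.1,
                     0.75, 1, 0.2,
                     0.1, 0.2, 1), 3, 3,
                   dimnames = list(c("v1", "v2", "v3"), c("v1", "v2", "v3")))
  picked <- palmsdm:::pick_representatives(loadings, cormat, r_max = 0.7)
  expect_equal(picked$selected, c("v1", "v3"))  # v2 rejected (r = 0.75 with v1)
  expect_equal(picked$rejected$var, "v2")
  expect_equal(picked$rejected$r, 0.75)
})

test_that("bioclim envelope scores follow the mean-rank percentile convention", {
  m <- fit_bioclim(data.frame(bio1 = c(1, 2, 3, 4, 5)))
  expect_equal(predict(m, data.frame(bio1 = 3)), 1)      # median
  expect_equal(predict(m, data.frame(bio1 = 2)), 0.5)    # p = 0.25
  expect_equal(predict(m, data.frame(bio1 = 6)), 0)      # beyond max
  expect_equal(predict(m, data.frame(bio1 = 0.5)), 0)    # below min

  # zero-set equals the complement of the training envelope exactly
  set.seed(2)
  tr <- data.frame(a = runif(30, 2, 4), b = runif(30, -1, 1))
  mb <- fit_bioclim(tr)
  qu <- data.frame(a = c(1.9, 4.1, 3, 3), b = c(0, 0, -1.1, 0.2))
  sc <- predict(mb, qu)
  expect_equal(sc[1:3], c(0, 0, 0))
  expect_gt(sc[4], 0)
  expect_error(fit_bioclim(data.frame(a = 1:2)),
               class = "palmsdm_invalid_argument")
})

test_that("domain suitability is 1 minus the nearest Gower distance", {
  m <- fit_domain(data.frame(v = c(0, 10)))
  expect_equal(predict(m, data.frame(v = 5)), 0.5)
  expect_equal(predict(m, data.frame(v = 0)), 1)

  # moving away from all training points never increases suitability
  m2 <- fit_domain(data.frame(a = c(0, 1, 2), b = c(0, 0.5, 1)))
  path <- data.frame(a = seq(2, 8, by = 0.5), b = 1)
  expect_true(all(diff(predict(m2, path)) <= 1e-12))

  expect_warning(fit_domain(data.frame(a = c(1, 2), b = c(3, 3))), "zero-range")
  expect_error(fit_domain(data.frame(a = numeric(0))),
               class = "palmsdm_invalid_argument")
})

test_that("svm separates separable data, stays in [0,1], and reverses under label swap", {
  set.seed(7)
  pres <- matrix(rnorm(120, 5), 60, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(rnorm(400, 0), 200, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_svm(pres[1:40, ], bg[1:150, ], seed = 1)
  held <- predict(m, pres[41:60, ])
  expect_gt(mean(held), 0.9)
  expect_true(all(held >= 0 & held <= 1))

  rand <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  pr <- predict(m, rand)
  expect_true(all(pr >= 0 & pr <= 1))

  swap <- fit_svm(bg[1:150, ], pres[1:40, ], seed = 1)
  expect_gt(cor(predict(swap, rbind(pres, bg)),
                1 - predict(m, rbind(pres, bg))), 0.9)

  expect_identical(predict(fit_svm(pres[1:40, ], bg[1:150, ], seed = 1), rand),
                   pr)
  expect_error(fit_svm(pres[1:5, ], bg, seed = 1),
               class = "palmsdm_invalid_argument")
})

test_that("maxent-style model recovers a 1D Gaussian optimum and obeys its penalty", {
  st <- test_stack(n = 40, layers = 2)
  env <- bg_table(st)
  mu <- env[which.min(abs(env[, 1]) + abs(env[, 2])), ]
  vs <- gen_virtual_species(st, virtual_species("sp", mu, 0.4))
  occ <- sample_occurrences(vs, st, n = 150, seed = 4)
  pe <- extract_env(st, occ$lon, occ$lat)
  set.seed(5)
  be <- env[sample.int(nrow(env), 800), ]

  m <- fit_maxent(pe, be, seed = 1)
  pred <- predict(m, env)
  best <- env[which.max(pred), ]
  # optimum recovered to within one cell's environmental spacing
  expect_lt(sqrt(sum((best - mu)^2)), 0.35)

  # no signal -> near-constant map
  set.seed(6)
  unif <- env[sample.int(nrow(env), 150), ]
  m0 <- fit_maxent(unif, be, seed = 1)
  p0 <- predict(m0, env)
  expect_lt(sd(p0) / mean(p0), 0.1)

  # ten-fold regularization never grows the coefficient L1 norm
  m10 <- fit_maxent(pe, be, reg_mult = 10, seed = 1)
  expect_lte(coef_l1(m10), coef_l1(m))
  expect_true(all(pred >= 0 & pred <= 1))
  expect_error(fit_maxent(pe, be[1:10, ], seed = 1),
               class = "palmsdm_invalid_argument")
})

test_that("stack prediction propagates nodata and demands matching layers", {
  st <- test_stack(n = 20, layers = 2)
  st$layers$bio1[3, 4] <- NA
  st$mask[3, 4] <- FALSE
  m <- fit_domain(bg_table(test_stack(n = 20, layers = 2)))
  sm <- predict_stack(m, st)
  expect_true(is.na(sm$values[3, 4]))
  expect_true(all(sm$values >= 0 & sm$values <= 1, na.rm = TRUE))

  st1 <- test_stack(n = 20, layers = 1 + 1)
  names(st1$layers) <- c("x1", "x2")
  expect_error(predict_stack(m, st1), class = "palmsdm_invalid_argument")
})
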