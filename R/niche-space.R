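#' Fit the background ordination (PCA-env / PCA-trait)
#'
#' Principal components of the standardized background table (correlation
#' matrix PCA, appropriate for mixed-unit variables). The first two axes
#' define the space in which occupancy densities and Schoener's D are
#' computed. Constant variables cannot be standardized and are dropped with
#' a warning.
#'
#' @param background_values Data frame or matrix, points x variables, no
#'   missing values, >= 3 points and >= 2 (non-constant) variables.
#' @return An `ordination` object with `means`, `sds`, `loadings`
#'   (orthonormal columns), `explained` (variance fractions, non-increasing).
#' @examples
#' ord <- fit_ordination(matrix(rnorm(200), 100, 2))
#' ord$explained
#' @export
fit_ordination <- function(background_values) {
  x <- as.matrix(background_values)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (nrow(x) < 3L) stop_invalid("need >= 3 points")
  if (anyNA(x)) stop_invalid("missing values in background table")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste("dropping constant variable(s):",
               paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop_invalid("need >= 2 non-constant variables")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  structure(
    list(means = pc$center, sds = pc$scale, loadings = pc$rotation,
         explained = pc$sdev^2 / sum(pc$sdev^2)),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d variables; first two axes explain %.1f%%\n",
              nrow(x$loadings), 100 * sum(x$explained[1:2])))
  invisible(x)
}

#' @rdname fit_ordination
#' @param x An `ordination` object.
#' @param ... Unused.
#' @export
tidy.ordination <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$explained),
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' Project points into ordination space
#'
#' @param model An [fit_ordination()] model.
#' @param values Points x variables table with the model's variables.
#' @param axes Which axes (default first two).
#' @return Score matrix, points x axes.
#' @export
ord_scores <- function(model, values, axes = 1:2) {
  x <- as.matrix(values)[, names(model$means), drop = FALSE]
  x <- sweep(sweep(x, 2, model$means), 2, model$sds, "/")
  x %*% model$loadings[, axes, drop = FALSE]
}

silverman_bw <- function(x) {
  b <- stats::bw.nrd0(x)
  if (!is.finite(b) || b <= 0) NA_real_ else b
}

#' Gridded occupancy density in ordination space
#'
#' Projects occurrences and background onto the first two ordination axes,
#' grids the plane into `R x R` cells bounded by the background score
#' ranges, and computes a product-Gaussian kernel density for the species
#' (`z`) and the background availability (`a`), each normalized to sum to
#' one. Bandwidths follow Silverman's rule per axis on the respective
#' scores; a species with too few distinct scores borrows the background
#' bandwidth.
#'
#' With `availability_correct = TRUE` the occurrence density is divided by
#' the availability density (floored at `1e-8` of its maximum) and
#' renormalized, down-weighting environments that are common in the
#' background; the default (`FALSE`) keeps the plain occurrence density,
#' whose Schoener's D estimates the cell-level overlap of the occurrence
#' processes.
#'
#' @param model An [fit_ordination()] model.
#' @param occ_values Occurrence environment table (points x variables).
#' @param background_values Background environment table.
#' @param R Grid resolution per axis (default 100).
#' @param availability_correct Divide by availability? See Details.
#' @return An `occupancy_grid`: `R`, `bounds`, `z`, `a` (both `R x R`,
#'   summing to 1; matrix rows index axis 1, columns axis 2).
#' @export
occupancy_grid <- function(model, occ_values, background_values, R = 100,
                           availability_correct = FALSE) {
  if (R < 2) stop_invalid("`R` must be >= 2")
  occ <- ord_scores(model, occ_values)
  if (nrow(occ) == 0L) stop_invalid("no occurrences")
  bg <- ord_scores(model, background_values)
  bounds <- list(x = range(bg[, 1]), y = range(bg[, 2]))
  if (diff(bounds$x) <= 0 || diff(bounds$y) <= 0) {
    stop_degenerate("background collapses to a point/line in ordination space")
  }
  bw_bg <- c(silverman_bw(bg[, 1]), silverman_bw(bg[, 2]))
  bw_occ <- c(silverman_bw(occ[, 1]), silverman_bw(occ[, 2]))
  bw_occ[is.na(bw_occ)] <- bw_bg[is.na(bw_occ)]
  # MASS::kde2d uses sd = h/4, so h = 4 * Silverman bandwidth.
  kd <- function(pts, bw) {
    d <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bw, n = R,
                     lims = c(bounds$x, bounds$y))
    d$z / sum(d$z)
  }
  a <- kd(bg, bw_bg)
  z <- kd(occ, bw_occ)
  z[a == 0] <- 0
  if (availability_correct) {
    z <- ifelse(a > 0, z / pmax(a, 1e-8 * max(a)), 0)
  }
  z <- z / sum(z)
  # Empirical support: cells actually holding background scores (used by the
  # similarity-test null, which relocates niches within the background).
  bin <- function(v, rng) pmin(pmax(ceiling((v - rng[1]) / diff(rng) * R), 1L), R)
  support <- matrix(0L, R, R)
  ij <- cbind(bin(bg[, 1], bounds$x), bin(bg[, 2], bounds$y))
  for (k in seq_len(nrow(ij))) support[ij[k, 1], ij[k, 2]] <-
    support[ij[k, 1], ij[k, 2]] + 1L
  structure(list(R = R, bounds = bounds, z = z, a = a, support = support,
                 bw_occ = bw_occ, bw_bg = bw_bg),
            class = "occupancy_grid")
}

#' Build an occupancy grid from precomputed densities
#'
#' Bypasses the kernel step: any non-negative density matrix (for example a
#' virtual species' suitability surface) is normalized into `z`. Used to
#' show that grid-based Schoener's D equals the brute-force oracle when no
#' smoothing intervenes.
#'
#' @param z Non-negative matrix (occurrence density, unnormalized ok).
#' @param a Non-negative matrix of the same shape (availability); default
#'   uniform.
#' @param bounds List with `x`, `y` range vectors (default unit square).
#' @param support Optional matrix of background counts per cell (drives the
#'   similarity-test null); defaults to the cells where `a > 0`.
#' @return An `occupancy_grid`.
#' @export
occupancy_grid_raw <- function(z, a = NULL, bounds = NULL, support = NULL) {
  z <- as.matrix(z)
  if (any(z < 0) || sum(z) <= 0) stop_invalid("`z` must be non-negative, not all zero")
  if (is.null(a)) a <- matrix(1, nrow(z), ncol(z))
  if (!identical(dim(a), dim(z))) stop_invalid("`a` must match `z` in shape")
  if (is.null(bounds)) bounds <- list(x = c(0, 1), y = c(0, 1))
  if (is.null(support)) support <- (a > 0) * 1L
  structure(list(R = nrow(z), bounds = bounds, z = z / sum(z), a = a / sum(a),
                 support = support, bw_occ = NULL, bw_bg = NULL),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> %d x %d; sum z = %.6f\n",
              nrow(x$z), ncol(x$z), sum(x$z)))
  invisible(x)
}

#' @rdname occupancy_grid
#' @param x An `occupancy_grid`.
#' @param ... Unused.
#' @export
as_tibble.occupancy_grid <- function(x, ...) {
  grid <- expand.grid(i = seq_len(nrow(x$z)), j = seq_len(ncol(x$z)))
  tibble::tibble(i = grid$i, j = grid$j,
                 z = as.vector(x$z), a = as.vector(x$a))
}

#' @rdname occupancy_grid
#' @param object An `occupancy_grid`.
#' @export
autoplot.occupancy_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "axis 1 bin", y = "axis 2 bin", fill = "density")
}

check_same_grid <- function(g1, g2) {
  if (!identical(dim(g1$z), dim(g2$z)) ||
      !isTRUE(all.equal(g1$bounds, g2$bounds, tolerance = 1e-8))) {
    stop_invalid("occupancy grids must share resolution and bounds")
  }
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the shared grid; 0 means complete
#' discordance, 1 identical niches. Symmetric in its arguments.
#'
#' @param g1,g2 [occupancy_grid()]s with identical resolution and bounds.
#' @return `D` in `[0, 1]`.
#' @export
schoener_d <- function(g1, g2) {
  check_same_grid(g1, g2)
  max(0, 1 - 0.5 * sum(abs(g1$z - g2$z)))
}

# Translate a density by (di, dj) cells, truncating at the grid edge, and
# renormalize. Returns NULL if everything fell off the grid.
shift_density <- function(z, di, dj) {
  R1 <- nrow(z); R2 <- ncol(z)
  out <- matrix(0, R1, R2)
  src_i <- seq_len(R1) - di
  src_j <- seq_len(R2) - dj
  oi <- which(src_i >= 1 & src_i <= R1)
  oj <- which(src_j >= 1 & src_j <= R2)
  if (length(oi) == 0L || length(oj) == 0L) return(NULL)
  out[oi, oj] <- z[src_i[oi], src_j[oj]]
  s <- sum(out)
  if (s <= 0) return(NULL)
  out / s
}

density_centroid <- function(z) {
  i <- round(sum(row(z) * z) / sum(z))
  j <- round(sum(col(z) * z) / sum(z))
  c(pmin(pmax(i, 1L), nrow(z)), pmin(pmax(j, 1L), ncol(z)))
}

#' Niche similarity randomization test
#'
#' Tests whether the observed Schoener's D between two occupancy grids is
#' larger (by default) than expected if one species' niche sat at a random
#' position in the available background. Each null replicate relocates the
#' second species' observed density so its centroid lands on a cell of the
#' background's empirical support, drawn with probability proportional to
#' the background mass in that cell - a random *geographic* background
#' location, mapped into niche space (translation with truncation at the
#' grid edge, then renormalization) - and recomputes D. The p-value uses the
#' +1-corrected rank, `p = (1 + #{null >= observed}) / (1 + n_reps)`, so its
#' lower bound is `1 / (n_reps + 1)`.
#'
#' @param g1,g2 [occupancy_grid()]s on the same grid.
#' @param n_reps Number of null replicates (>= 99; default 1000).
#' @param alternative `"greater"` (similarity, default), `"less"`, or
#'   `"two.sided"`.
#' @param seed Integer seed.
#' @param shift Relocate only the `"second"` density per null replicate
#'   (default) or `"both"`.
#' @return An `overlap_result` with `D`, `p_value`, `n_reps`,
#'   `null_quantiles` and the null sample.
#' @export
similarity_test <- function(g1, g2, n_reps = 1000,
                            alternative = c("greater", "less", "two.sided"),
                            seed = 1, shift = c("second", "both")) {
  check_same_grid(g1, g2)
  alternative <- match.arg(alternative)
  shift <- match.arg(shift)
  if (n_reps < 99) stop_invalid("`n_reps` must be >= 99")
  supp <- if (!is.null(g2$support)) g2$support else (g2$a > 0) * 1L
  avail <- which(supp > 0, arr.ind = TRUE)
  wts <- supp[supp > 0]
  if (nrow(avail) < 2L) stop_degenerate("background support has < 2 cells")
  obs <- schoener_d(g1, g2)
  ctr1 <- density_centroid(g1$z)
  ctr2 <- density_centroid(g2$z)
  relocate <- function(z, ctr) {
    repeat {
      tgt <- avail[sample.int(nrow(avail), 1L, prob = wts), ]
      zs <- shift_density(z, tgt[1] - ctr[1], tgt[2] - ctr[2])
      if (!is.null(zs)) return(zs)
    }
  }
  null_d <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      z1 <- if (shift == "both") relocate(g1$z, ctr1) else g1$z
      z2 <- relocate(g2$z, ctr2)
      max(0, 1 - 0.5 * sum(abs(z1 - z2)))
    }, numeric(1))
  })
  p_greater <- (1 + sum(null_d >= obs - 1e-12)) / (1 + n_reps)
  p_less <- (1 + sum(null_d <= obs + 1e-12)) / (1 + n_reps)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  structure(
    list(D = obs, p_value = p, n_reps = n_reps, alternative = alternative,
         null_quantiles = quantile(null_d, c(0.05, 0.25, 0.5, 0.75, 0.95)),
         null = null_d, seed = seed),
    class = "overlap_result"
  )
}

#' Randomly relocate an occupancy grid within its background
#'
#' Draws one support-weighted background cell and translates the grid's
#' occurrence density so its centroid lands there (truncation at the grid
#' edge, renormalization) - a single draw from the [similarity_test()]
#' null. Useful for building calibration simulations whose data are
#' generated under that null.
#'
#' @param g An [occupancy_grid()].
#' @param seed Integer seed.
#' @return A new `occupancy_grid` with the relocated density (same
#'   availability, bounds and support).
#' @export
relocate_grid <- function(g, seed = 1) {
  supp <- if (!is.null(g$support)) g$support else (g$a > 0) * 1L
  avail <- which(supp > 0, arr.ind = TRUE)
  if (nrow(avail) < 2L) stop_degenerate("background support has < 2 cells")
  ctr <- density_centroid(g$z)
  zs <- with_seed(seed, {
    repeat {
      tgt <- avail[sample.int(nrow(avail), 1L, prob = supp[supp > 0]), ]
      out <- shift_density(g$z, tgt[1] - ctr[1], tgt[2] - ctr[2])
      if (!is.null(out)) break
    }
    out
  })
  occupancy_grid_raw(zs, a = g$a, bounds = g$bounds, support = supp)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> D = %.3f, p = %.4g (%s, %d reps)\n",
              x$D, x$p_value, x$alternative, x$n_reps))
  invisible(x)
}

#' @rdname similarity_test
#' @param x,object An `overlap_result`.
#' @param ... Unused.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(D = x$D, p_value = x$p_value, n_reps = x$n_reps,
                 alternative = x$alternative,
                 null_median = unname(x$null_quantiles["50%"]))
}

#' @rdname similarity_test
#' @export
glance.overlap_result <- function(x, ...) tidy(x)

#' Functional-role overlap of two palms in frugivore trait space
#'
#' Treats each palm's functional role as the multidimensional trait space
#' of the birds it interacts with (body mass, bill width, wing length).
#' The trait table of all interacting birds is the background; an
#' ordination is fitted on it, each palm's bird set becomes an occupancy
#' grid, and overlap is quantified with Schoener's D plus the similarity
#' test.
#'
#' @param traits Tibble with a `bird` column plus numeric trait columns.
#' @param set_a,set_b Character vectors of bird species per palm.
#' @param R Grid resolution (default 100).
#' @param n_reps Similarity-test replicates (default 199).
#' @param seed Integer seed.
#' @param log_mass Log10-transform `body_mass_g` before ordination (body
#'   mass spans orders of magnitude; the linear traits do not)?
#' @return An `overlap_result` (with the ordination and grids attached as
#'   `ordination`, `grid_a`, `grid_b`).
#' @export
functional_overlap <- function(traits, set_a, set_b, R = 100, n_reps = 199,
                               seed = 1, log_mass = TRUE) {
  traits <- tibble::as_tibble(traits)
  trait_cols <- setdiff(names(traits), "bird")
  missing <- setdiff(union(set_a, set_b), traits$bird)
  bad <- traits$bird[!complete.cases(traits[trait_cols])]
  bad <- union(missing, intersect(bad, union(set_a, set_b)))
  if (length(bad) > 0) {
    abort(paste("species missing trait values:", paste(bad, collapse = ", ")),
          class = "palmsdm_missing_traits", species = bad)
  }
  m <- as.matrix(traits[trait_cols])
  rownames(m) <- traits$bird
  if (log_mass && "body_mass_g" %in% colnames(m)) {
    m[, "body_mass_g"] <- log10(m[, "body_mass_g"])
  }
  ord <- fit_ordination(m)
  g_a <- occupancy_grid(ord, m[rownames(m) %in% set_a, , drop = FALSE], m, R = R)
  g_b <- occupancy_grid(ord, m[rownames(m) %in% set_b, , drop = FALSE], m, R = R)
  res <- similarity_test(g_a, g_b, n_reps = n_reps, seed = seed)
  res$ordination <- ord
  res$grid_a <- g_a
  res$grid_b <- g_b
  res
}
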