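#' Generate a synthetic bioclimatic raster stack
#'
#' Builds spatially autocorrelated climate-like layers on a shared grid.
#' Each layer starts as white noise smoothed with a Gaussian filter of
#' standard deviation `autocorr_length` (in cells); the smoothed fields are
#' then orthogonalized and mixed through the Cholesky factor of a
#' compound-symmetric correlation matrix so that every layer pair has
#' empirical correlation `layer_corr` (exact up to floating point, because
#' mixing acts on empirically orthonormal fields). Layers are standardized
#' to mean 0, SD 1; they play the role of standardized bioclim variables.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param n_layers Number of layers (>= 2); named `bio1`, `bio2`, ...
#' @param autocorr_length Gaussian filter SD in cells; larger values give
#'   smoother fields (higher Moran's I).
#' @param layer_corr Target pairwise inter-layer correlation, |r| < 1.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param extent Geographic extent `c(xmin, xmax, ymin, ymax)`.
#' @return An [env_stack()].
#' @examples
#' st <- gen_env_stack(40, 40, n_layers = 3, seed = 1)
#' cor(env_values(st))[1, 2]
#' @export
gen_env_stack <- function(n_rows, n_cols, n_layers = 19,
                          autocorr_length = 5, layer_corr = 0, seed = 1,
                          extent = c(-50, -40, -25, -15)) {
  if (n_rows < 2 || n_cols < 2) stop_invalid("grid dimensions must be >= 2")
  if (n_layers < 2) stop_invalid("`n_layers` must be >= 2")
  if (abs(layer_corr) >= 1) stop_invalid("|layer_corr| must be < 1")
  if (autocorr_length < 0) stop_invalid("`autocorr_length` must be >= 0")
  with_seed(seed, {
    fields <- replicate(n_layers, {
      z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
      gauss_smooth(z, autocorr_length)
    }, simplify = FALSE)
    x <- vapply(fields, as.vector, numeric(n_rows * n_cols))
    x <- scale(x, center = TRUE, scale = FALSE)
    # Empirical orthonormal basis of the smoothed fields, then Cholesky
    # mixing: the result has *exact* sample correlation layer_corr.
    q <- qr.Q(qr(x))
    cmat <- matrix(layer_corr, n_layers, n_layers)
    diag(cmat) <- 1
    y <- q %*% chol(cmat)
    y <- scale(y)
    layers <- lapply(seq_len(n_layers), function(k) {
      matrix(y[, k], n_rows, n_cols)
    })
    names(layers) <- paste0("bio", seq_len(n_layers))
    env_stack(layers, extent = extent)
  })
}

# Separable Gaussian smoothing by dense row/column kernel matrices;
# kernels are row-normalized so edges are handled by renormalization.
gauss_smooth <- function(z, len) {
  if (len <= 1e-9) return(z)
  kern <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    k <- exp(-0.5 * (d / len)^2)
    k / rowSums(k)
  }
  kern(nrow(z)) %*% z %*% t(kern(ncol(z)))
}

#' Define a virtual species with a Gaussian niche
#'
#' @param name Species label.
#' @param mu Niche center, one value per environmental layer (environment
#'   units).
#' @param sigma Niche covariance matrix (symmetric positive definite), or a
#'   single number for an isotropic niche.
#' @param prevalence Optional target fraction of cells with suitability
#'   > 0.5, in (0, 1). When set, the Mahalanobis scale is calibrated on the
#'   stack so the realized fraction matches exactly (up to cell counts).
#' @return A `virtual_species_spec` (parameters only; realized on a stack by
#'   [gen_virtual_species()]).
#' @export
virtual_species <- function(name, mu, sigma, prevalence = NULL) {
  if (is.null(dim(sigma))) sigma <- diag(rep(sigma, length(mu)), length(mu))
  if (!isTRUE(all.equal(sigma, t(sigma))) ||
      inherits(try(chol(sigma), silent = TRUE), "try-error")) {
    stop_invalid("`sigma` must be symmetric positive definite")
  }
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1)) {
    stop_invalid("`prevalence` must be in (0, 1)")
  }
  structure(list(name = name, mu = as.numeric(mu), sigma = sigma,
                 prevalence = prevalence),
            class = "virtual_species_spec")
}

#' Realize a virtual species on a stack
#'
#' Suitability is Gaussian in environmental space:
#' `s = exp(-d2 / (2 c))` with `d2` the squared Mahalanobis distance of a
#' cell's environment from the niche center `mu`. `c = 1` by default; when
#' the spec carries a target `prevalence`, `c` is calibrated so that the
#' fraction of valid cells with `s > 0.5` equals it. Suitability is 1
#' exactly where the environment equals `mu`.
#'
#' @param stack An [env_stack()]; its layer count must equal `length(mu)`.
#' @param spec A [virtual_species()].
#' @return A `virtual_species` object holding the suitability matrix (in
#'   `[0, 1]`, nodata propagated), the spec, and the originating extent.
#' @export
gen_virtual_species <- function(stack, spec) {
  if (!inherits(spec, "virtual_species_spec")) {
    stop_invalid("`spec` must come from virtual_species()")
  }
  if (length(spec$mu) != n_layers(stack)) {
    stop_invalid("`mu` dimension must equal the number of stack layers")
  }
  env <- env_values(stack)
  d2 <- rep(NA_real_, nrow(env))
  ok <- as.vector(stack$mask)
  d2[ok] <- mahalanobis(env[ok, , drop = FALSE], spec$mu, spec$sigma)
  cc <- 1
  if (!is.null(spec$prevalence)) {
    q <- quantile(d2[ok], probs = spec$prevalence, names = FALSE, type = 1)
    cc <- q / (2 * log(2))
    if (cc <= 0) cc <- .Machine$double.eps
  }
  s <- matrix(exp(-d2 / (2 * cc)), nrow(stack$layers[[1]]))
  structure(list(name = spec$name, spec = spec, suitability = s,
                 extent = stack$extent, scale = cc),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> '%s': %d x %d suitability grid, max %.3f\n",
              x$name, nrow(x$suitability), ncol(x$suitability),
              max(x$suitability, na.rm = TRUE)))
  invisible(x)
}

#' Sample occurrence records from a virtual species
#'
#' Bernoulli sampling per cell with probability `suitability * effort`, one
#' record per success at the cell center plus a small uniform jitter
#' (strictly less than half a cell) so that graticule disaggregation has
#' something to undo. When `n` is given, `effort` is set to `n / sum(s)` so
#' the expected record count is `n` (capped so probabilities stay <= 1).
#'
#' @param vs A realized [gen_virtual_species()] object.
#' @param stack The [env_stack()] the species was realized on.
#' @param n Target expected number of records (mutually exclusive with
#'   `effort`).
#' @param effort Per-cell sampling effort multiplier.
#' @param seed Integer seed.
#' @param year_range Years sampled uniformly for the `year` column.
#' @return Occurrence tibble: `species`, `lon`, `lat`, `year`, `source`.
#' @export
sample_occurrences <- function(vs, stack, n = NULL, effort = NULL, seed = 1,
                               year_range = c(1970L, 2020L)) {
  s <- vs$suitability
  s[is.na(s)] <- 0
  tot <- sum(s)
  if (tot <= 0) stop_degenerate("species has all-zero suitability")
  if (is.null(effort)) {
    if (is.null(n)) stop_invalid("supply `n` or `effort`")
    effort <- n / tot
  }
  p <- pmin(as.vector(s) * effort, 1)
  with_seed(seed, {
    hit <- which(rbinom(length(p), 1L, p) == 1L)
    cc <- cell_centers(stack)[hit, ]
    rs <- res_xy(stack)
    m <- length(hit)
    tibble::tibble(
      species = vs$name,
      lon = cc$lon + runif(m, -0.49, 0.49) * rs[1],
      lat = cc$lat + runif(m, -0.49, 0.49) * rs[2],
      year = sample(seq(year_range[1], year_range[2]), m, replace = TRUE),
      source = "synthetic"
    )
  })
}

#' Brute-force Schoener's D between two virtual species
#'
#' The ground-truth overlap oracle: each suitability surface is normalized
#' to sum to one over valid cells and
#' `D = 1 - 0.5 * sum(|p1 - p2|)`. `D` is 1 for identical niches, 0 for
#' disjoint ones, symmetric, and invariant to positive rescaling of either
#' surface.
#'
#' @param vs1,vs2 Realized [gen_virtual_species()] objects on the same stack.
#' @return `D` in `[0, 1]`.
#' @export
true_overlap_d <- function(vs1, vs2) {
  if (!identical(dim(vs1$suitability), dim(vs2$suitability)) ||
      !isTRUE(all.equal(vs1$extent, vs2$extent))) {
    stop_invalid("species must be realized on the same stack")
  }
  p1 <- as.vector(vs1$suitability)
  p2 <- as.vector(vs2$suitability)
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  if (sum(p1) <= 0 || sum(p2) <= 0) {
    stop_degenerate("all-zero suitability surface")
  }
  1 - 0.5 * sum(abs(p1 / sum(p1) - p2 / sum(p2)))
}

#' Generate a synthetic frugivory interaction and trait table pair
#'
#' Emulates a two-palm frugivore assemblage with controlled composition:
#' `n_shared` bird species interact with both palms, `n_only_a` only with
#' the first, `n_only_b` only with the second, so the downstream Sorensen
#' components are known by construction. Traits (body mass g, bill width
#' mm, wing length mm) are drawn lognormal - all three are strictly
#' positive in real birds.
#'
#' @param n_shared,n_only_a,n_only_b Non-negative species counts; their sum
#'   must be >= 1.
#' @param palms Length-2 character vector of palm labels.
#' @param trait_meanlog,trait_sdlog Lognormal parameters, one per trait, in
#'   order body mass, bill width, wing length. Defaults sketch a tropical
#'   frugivore assemblage (median ~60 g, ~8 mm, ~90 mm).
#' @param n_sites Number of site labels interactions are spread over.
#' @param seed Integer seed.
#' @return List with `interactions` (tibble: `palm`, `bird`, `site`,
#'   `source`) and `traits` (tibble: `bird`, `body_mass_g`, `bill_width_mm`,
#'   `wing_length_mm`).
#' @examples
#' tabs <- gen_interactions(3, 2, 3, seed = 1)
#' dplyr::count(tabs$interactions, palm)
#' @export
gen_interactions <- function(n_shared, n_only_a, n_only_b,
                             palms = c("palm_a", "palm_b"),
                             trait_meanlog = log(c(60, 8, 90)),
                             trait_sdlog = c(0.8, 0.25, 0.35),
                             n_sites = 10, seed = 1) {
  if (min(n_shared, n_only_a, n_only_b) < 0) stop_invalid("counts must be >= 0")
  if (n_shared + n_only_a + n_only_b < 1) {
    stop_invalid("at least one bird species is required")
  }
  if (any(trait_sdlog <= 0)) stop_invalid("`trait_sdlog` must be > 0")
  n_birds <- n_shared + n_only_a + n_only_b
  birds <- sprintf("bird_%03d", seq_len(n_birds))
  grp <- rep(c("shared", "only_a", "only_b"), c(n_shared, n_only_a, n_only_b))
  with_seed(seed, {
    sites <- sprintf("site_%02d", sample.int(n_sites, n_birds, replace = TRUE))
    rows <- dplyr::bind_rows(
      tibble::tibble(palm = palms[1], bird = birds[grp != "only_b"]),
      tibble::tibble(palm = palms[2], bird = birds[grp != "only_a"])
    )
    rows$site <- sites[match(rows$bird, birds)]
    rows$source <- "synthetic"
    traits <- tibble::tibble(
      bird = birds,
      body_mass_g = stats::rlnorm(n_birds, trait_meanlog[1], trait_sdlog[1]),
      bill_width_mm = stats::rlnorm(n_birds, trait_meanlog[2], trait_sdlog[2]),
      wing_length_mm = stats::rlnorm(n_birds, trait_meanlog[3], trait_sdlog[3])
    )
    list(interactions = rows, traits = traits)
  })
}
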