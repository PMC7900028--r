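# Shared fixtures, built in code at test time.

# Small climate stack reused across tests (deterministic).
test_stack <- function(n = 40, layers = 3, seed = 42, autocorr = 5) {
  gen_env_stack(n, n, n_layers = layers, autocorr_length = autocorr,
                layer_corr = 0.3, seed = seed)
}

bg_table <- function(stack) {
  bg <- env_values(stack)
  colnames(bg) <- layer_names(stack)
  bg
}

# Rectangle covering a stack's full extent.
full_region <- function(stack) {
  e <- stack$extent
  background_region(rbind(c(e[1], e[3]), c(e[2], e[3]),
                          c(e[2], e[4]), c(e[1], e[4])))
}

# Wrap a bare suitability matrix as a minimal virtual_species object so the
# brute-force overlap oracle can be exercised on hand-built surfaces.
fake_species <- function(suitability, extent = c(0, 1, 0, 1), name = "toy") {
  structure(list(name = name, suitability = as.matrix(suitability),
                 extent = extent),
            class = "virtual_species")
}

# A strongly separable study system reused across ensemble tests: a
# distinct climate block (bio1 jumps by 8 SD) occupied by the species.
separable_system <- function(seed = 1) {
  n <- 30
  set.seed(913)
  bio1 <- matrix(rnorm(n * n, 0, 0.3), n, n)
  bio2 <- matrix(rnorm(n * n, 0, 1), n, n)
  # the block's climate is tight so any training subset of its cells spans
  # the envelope of the rest
  bio1[1:6, 1:6] <- rnorm(36, 8, 0.05)
  bio2[1:6, 1:6] <- rnorm(36, 0, 0.05)
  st <- env_stack(list(bio1 = bio1, bio2 = bio2))
  cc <- cell_centers(st)
  block <- which(as.vector(row(bio1) <= 6 & col(bio1) <= 6))
  occ <- withr::with_seed(seed, {
    # every block cell recorded four times, so any 75/25 bootstrap split
    # almost surely spans the full climate envelope of the block
    pick <- sample(rep(block, 4))
    tibble::tibble(species = "sp", lon = cc$lon[pick], lat = cc$lat[pick],
                   year = 2000L, source = "t")
  })
  # background excludes the block (hole ring, even-odd rule): the species'
  # climate is absent from the background, making the classes separable
  e <- st$extent
  rs <- palmsdm:::res_xy(st)
  hole <- rbind(c(e[1], e[4] - 6 * rs[2]), c(e[1] + 6 * rs[1], e[4] - 6 * rs[2]),
                c(e[1] + 6 * rs[1], e[4]), c(e[1], e[4]))
  outer <- rbind(c(e[1], e[3]), c(e[2], e[3]), c(e[2], e[4]), c(e[1], e[4]))
  bg <- sample_background(background_region(list(outer, hole)), st,
                          n_points = 400, seed = seed + 1)
  list(stack = st, occ = occ, bg = bg)
}

# Exhaustive maximum-independent-set oracle for spatial thinning on small
# instances: largest subset with all pairwise distances >= min_dist_km.
max_retention_oracle <- function(occ, min_dist_km) {
  n <- nrow(occ)
  stopifnot(n <= 20)
  d <- as.matrix(geosphere::distHaversine(
    cbind(rep(occ$lon, each = n), rep(occ$lat, each = n)),
    cbind(rep(occ$lon, times = n), rep(occ$lat, times = n)),
    r = 6371000)) / 1000
  dm <- matrix(d, n, n)
  best <- 0L
  grow <- function(chosen, candidates) {
    if (length(chosen) + length(candidates) <= best) return(invisible())
    if (length(candidates) == 0L) {
      best <<- max(best, length(chosen))
      return(invisible())
    }
    i <- candidates[1]
    rest <- candidates[-1]
    ok <- rest[vapply(rest, function(j) dm[i, j] >= min_dist_km, logical(1))]
    grow(c(chosen, i), ok)   # include i
    grow(chosen, rest)       # exclude i
  }
  grow(integer(0), seq_len(n))
  best
}
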