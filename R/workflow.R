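#' Default pipeline configuration
#'
#' A nested list with every tunable the staged workflow uses; user configs
#' (YAML via [read_run_config()] or plain lists) are merged over it. Paths
#' are filled in by `simulate` or supplied by the user.
#'
#' @return Named list of stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(stack = NULL, future_stack = NULL,
                 occurrences_a = NULL, occurrences_b = NULL,
                 background = NULL, interactions = NULL, traits = NULL,
                 classes = NULL),
    simulate = list(n_rows = 60L, n_cols = 60L, n_layers = 5L,
                    autocorr_length = 6, layer_corr = 0.3,
                    mu_a = c(0.5, 0.5, 0, 0, 0), mu_b = c(-0.5, -0.5, 0, 0, 0),
                    sigma = 0.35, prevalence = 0.3, n_occ = 200L,
                    n_shared = 30L, n_only_a = 10L, n_only_b = 15L,
                    future_shift = 0.75),
    prep = list(year_min = 1970L, year_max = 2020L, cell_size = 2.5,
                min_dist_km = 10),
    niche = list(R = 100L, n_reps = 1000L, availability_correct = FALSE),
    functional = list(R = 100L, n_reps = 199L, log_mass = TRUE),
    sdm = list(algorithms = c("bioclim", "domain", "svm", "maxent"),
               n_rep = 10L, train_frac = 0.75, tss_min = 0.5, r_max = 0.7,
               n_background = 2000L,
               threshold_rule = list(native = "P10", invader = "MTP"))
  )
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file path.
#' @return Config list (user values merged over [default_config()]).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(config, need_paths = character(0)) {
  for (p in need_paths) {
    v <- config$paths[[p]]
    ok <- !is.null(v) && all(file.exists(v))
    if (!ok) {
      abort(sprintf("config paths$%s missing or does not exist", p),
            class = "palmsdm_config_error")
    }
  }
  if (!is.numeric(config$seed)) {
    abort("config seed must be an integer", class = "palmsdm_config_error")
  }
  invisible(config)
}

write_manifest <- function(out_dir, stage, config, outputs) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    version = as.character(utils::packageVersion("palmsdm")),
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Orchestrates the package's modules as reproducible stages writing plain
#' artifacts (CSV, ASCII grids, JSON) plus a manifest recording the seed
#' and MD5 of every output. Stages: `simulate` (synthetic climate, two
#' virtual species, occurrences, interaction/trait tables), `prep`
#' (filter, disaggregate, rarefy), `niche-overlap`, `functional-overlap`,
#' `sdm` (replicate fits + TSS table), `ensemble` (ensemble + thresholds +
#' binary ranges + overlap areas), `project` (future-climate ensemble and
#' areas), `beta` (frugivore-set partition).
#'
#' @param stage Stage name (see Details).
#' @param config Config list (see [default_config()]) or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of artifact paths (including the manifest).
#' @export
run_stage <- function(stage, config = default_config(), out_dir = tempdir()) {
  stage <- match.arg(stage, c("simulate", "prep", "niche-overlap",
                              "functional-overlap", "sdm", "ensemble",
                              "project", "beta"))
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(stage,
    "simulate" = stage_simulate(config, out_dir),
    "prep" = stage_prep(config, out_dir),
    "niche-overlap" = stage_niche(config, out_dir),
    "functional-overlap" = stage_functional(config, out_dir),
    "sdm" = stage_sdm(config, out_dir, ensemble_too = FALSE),
    "ensemble" = stage_sdm(config, out_dir, ensemble_too = TRUE),
    "project" = stage_project(config, out_dir),
    "beta" = stage_beta(config, out_dir)
  )
  manifest <- write_manifest(out_dir, stage, config, outputs)
  invisible(c(outputs, manifest = manifest))
}

sim_species_pair <- function(config) {
  sc <- config$simulate
  stack <- gen_env_stack(sc$n_rows, sc$n_cols, sc$n_layers,
                         autocorr_length = sc$autocorr_length,
                         layer_corr = sc$layer_corr, seed = config$seed)
  pad <- function(mu) c(mu, rep(0, sc$n_layers))[seq_len(sc$n_layers)]
  vs_a <- gen_virtual_species(stack, virtual_species(
    "invader", pad(sc$mu_a), sc$sigma, prevalence = sc$prevalence))
  vs_b <- gen_virtual_species(stack, virtual_species(
    "native", pad(sc$mu_b), sc$sigma, prevalence = sc$prevalence))
  list(stack = stack, vs_a = vs_a, vs_b = vs_b)
}

stage_simulate <- function(config, out_dir) {
  sc <- config$simulate
  sim <- sim_species_pair(config)
  stack_dir <- file.path(out_dir, "stack")
  write_env_stack(sim$stack, stack_dir, seed = config$seed)
  occ_a <- sample_occurrences(sim$vs_a, sim$stack, n = sc$n_occ,
                              seed = config$seed + 1)
  occ_b <- sample_occurrences(sim$vs_b, sim$stack, n = sc$n_occ,
                              seed = config$seed + 2)
  tabs <- gen_interactions(sc$n_shared, sc$n_only_a, sc$n_only_b,
                           seed = config$seed + 3)
  paths <- c(
    occurrences_a = write_occurrences(occ_a, file.path(out_dir, "occurrences_a.csv")),
    occurrences_b = write_occurrences(occ_b, file.path(out_dir, "occurrences_b.csv")),
    interactions = {
      p <- file.path(out_dir, "interactions.csv")
      write.csv(tabs$interactions, p, row.names = FALSE); p
    },
    traits = {
      p <- file.path(out_dir, "traits.csv")
      write.csv(tabs$traits, p, row.names = FALSE); p
    }
  )
  c(paths, list.files(stack_dir, full.names = TRUE))
}

resolve_sim_paths <- function(config, out_dir) {
  # Stages default to the artifacts `simulate` writes into out_dir.
  defaults <- list(
    stack = file.path(out_dir, "stack"),
    occurrences_a = file.path(out_dir, "occurrences_a.csv"),
    occurrences_b = file.path(out_dir, "occurrences_b.csv"),
    interactions = file.path(out_dir, "interactions.csv"),
    traits = file.path(out_dir, "traits.csv")
  )
  for (nm in names(defaults)) {
    if (is.null(config$paths[[nm]])) config$paths[[nm]] <- defaults[[nm]]
  }
  config
}

load_stack_dir <- function(dir) {
  read_env_stack(sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE)))
}

stage_prep <- function(config, out_dir) {
  config <- resolve_sim_paths(config, out_dir)
  validate_config(config, c("occurrences_a", "occurrences_b"))
  pc <- config$prep
  out <- character(0)
  for (side in c("a", "b")) {
    occ <- read_occurrences(config$paths[[paste0("occurrences_", side)]])
    occ <- filter_records(occ, pc$year_min, pc$year_max)
    occ <- disaggregate(occ, pc$cell_size)
    occ <- rarefy(occ, pc$min_dist_km, seed = config$seed)
    p <- file.path(out_dir, sprintf("occurrences_%s_clean.csv", side))
    write_occurrences(occ, p)
    out <- c(out, p)
  }
  out
}

clean_or_raw <- function(config, out_dir, side) {
  clean <- file.path(out_dir, sprintf("occurrences_%s_clean.csv", side))
  if (file.exists(clean)) clean else config$paths[[paste0("occurrences_", side)]]
}

stage_niche <- function(config, out_dir) {
  config <- resolve_sim_paths(config, out_dir)
  validate_config(config, "stack")
  stack <- load_stack_dir(config$paths$stack)
  bg <- env_values(stack, valid_only = TRUE)
  colnames(bg) <- layer_names(stack)
  ord <- fit_ordination(bg)
  grids <- lapply(c("a", "b"), function(side) {
    occ <- read_occurrences(clean_or_raw(config, out_dir, side))
    occupancy_grid(ord, extract_env(stack, occ$lon, occ$lat), bg,
                   R = config$niche$R,
                   availability_correct = config$niche$availability_correct)
  })
  res <- similarity_test(grids[[1]], grids[[2]], n_reps = config$niche$n_reps,
                         seed = config$seed)
  p <- file.path(out_dir, "niche_overlap.json")
  jsonlite::write_json(
    list(D = res$D, p_value = res$p_value, n_reps = res$n_reps,
         seed = config$seed,
         explained_first_two = sum(ord$explained[1:2])),
    p, auto_unbox = TRUE, digits = NA)
  p
}

stage_functional <- function(config, out_dir) {
  config <- resolve_sim_paths(config, out_dir)
  validate_config(config, c("interactions", "traits"))
  inter <- tibble::as_tibble(read.csv(config$paths$interactions))
  traits <- tibble::as_tibble(read.csv(config$paths$traits))
  sets <- species_sets(inter)
  res <- functional_overlap(traits, sets$set_a, sets$set_b,
                            R = config$functional$R,
                            n_reps = config$functional$n_reps,
                            seed = config$seed,
                            log_mass = config$functional$log_mass)
  p <- file.path(out_dir, "functional_overlap.json")
  jsonlite::write_json(
    list(D = res$D, p_value = res$p_value, n_reps = res$n_reps,
         seed = config$seed),
    p, auto_unbox = TRUE, digits = NA)
  p
}

stage_sdm <- function(config, out_dir, ensemble_too = FALSE) {
  config <- resolve_sim_paths(config, out_dir)
  validate_config(config, c("stack", "occurrences_a"))
  sc <- config$sdm
  bad <- setdiff(sc$algorithms, c("bioclim", "domain", "svm", "maxent"))
  if (length(bad) > 0) {
    abort(sprintf("config sdm$algorithms: unknown algorithm '%s'", bad[1]),
          class = "palmsdm_config_error")
  }
  stack <- load_stack_dir(config$paths$stack)
  region <- background_region(rbind(
    c(stack$extent[1], stack$extent[3]), c(stack$extent[2], stack$extent[3]),
    c(stack$extent[2], stack$extent[4]), c(stack$extent[1], stack$extent[4])))
  bg <- sample_background(region, stack, n_points = sc$n_background,
                          seed = config$seed)
  bg_env <- extract_env(stack, bg$lon, bg$lat)
  sel <- select_variables(bg_env[complete.cases(bg_env), , drop = FALSE],
                          r_max = sc$r_max)
  out <- character(0)
  for (side in c("a", "b")) {
    occ <- read_occurrences(clean_or_raw(config, out_dir, side))
    maps <- run_replicates(occ, bg, stack, vars = sel$selected,
                           algorithms = sc$algorithms, n_rep = sc$n_rep,
                           train_frac = sc$train_frac, seed = config$seed)
    tab <- tibble::tibble(
      species = occ$species[1],
      algorithm = vapply(maps, function(m) m$algorithm, character(1)),
      replicate = vapply(maps, function(m) m$replicate_id, integer(1)),
      tss = vapply(maps, function(m) m$tss, numeric(1)))
    p <- file.path(out_dir, sprintf("replicates_%s.csv", side))
    write.csv(tab, p, row.names = FALSE)
    out <- c(out, p)
    if (ensemble_too) {
      ens <- ensemble(maps, tss_min = sc$tss_min)
      pres <- suitability_at(ens, occ$lon, occ$lat)
      bgs <- suitability_at(ens, bg$lon, bg$lat)
      thr <- compute_thresholds(pres, bgs)
      rule <- if (side == "a") sc$threshold_rule$invader else sc$threshold_rule$native
      br <- binarize(ens, thr[[rule]], rule = rule)
      ep <- file.path(out_dir, sprintf("ensemble_%s.json", side))
      jsonlite::write_json(
        list(species = occ$species[1], n_contributing = ens$n_contributing,
             thresholds = as.list(thr), rule = rule,
             area_km2 = br$area_km2, seed = config$seed),
        ep, auto_unbox = TRUE, digits = NA)
      out <- c(out, ep)
    }
  }
  out
}

stage_project <- function(config, out_dir) {
  config <- resolve_sim_paths(config, out_dir)
  validate_config(config, c("stack", "occurrences_a"))
  sc <- config$sdm
  stack <- load_stack_dir(config$paths$stack)
  future <- if (!is.null(config$paths$future_stack)) {
    load_stack_dir(config$paths$future_stack)
  } else {
    # Synthetic "future": shift every layer by the configured climate delta.
    shifted <- lapply(stack$layers, function(m) m + config$simulate$future_shift)
    env_stack(shifted, extent = stack$extent)
  }
  region <- background_region(rbind(
    c(stack$extent[1], stack$extent[3]), c(stack$extent[2], stack$extent[3]),
    c(stack$extent[2], stack$extent[4]), c(stack$extent[1], stack$extent[4])))
  bg <- sample_background(region, stack, n_points = sc$n_background,
                          seed = config$seed)
  rows <- list()
  ranges <- list()
  for (side in c("a", "b")) {
    occ <- read_occurrences(clean_or_raw(config, out_dir, side))
    maps <- run_replicates(occ, bg, stack, algorithms = sc$algorithms,
                           n_rep = sc$n_rep, train_frac = sc$train_frac,
                           seed = config$seed)
    ens <- ensemble(maps, tss_min = sc$tss_min)
    thr <- compute_thresholds(suitability_at(ens, occ$lon, occ$lat),
                              suitability_at(ens, bg$lon, bg$lat))
    rule <- if (side == "a") sc$threshold_rule$invader else sc$threshold_rule$native
    fut <- project_ensemble(ens, future)
    # Thresholds selected under current climate are reused in the future.
    ranges[[side]] <- list(current = binarize(ens, thr[[rule]], rule),
                           future = binarize(fut, thr[[rule]], rule))
  }
  areas <- dplyr::bind_rows(lapply(c("current", "future"), function(scn) {
    ov <- overlap_area(ranges$b[[scn]], ranges$a[[scn]])
    dplyr::mutate(ov, scenario = scn, .before = 1)
  }))
  p <- file.path(out_dir, "areas.csv")
  write.csv(areas, p, row.names = FALSE)
  p
}

stage_beta <- function(config, out_dir) {
  config <- resolve_sim_paths(config, out_dir)
  validate_config(config, "interactions")
  inter <- tibble::as_tibble(read.csv(config$paths$interactions))
  sets <- species_sets(inter)
  beta <- sorensen_partition(sets$set_a, sets$set_b)
  res <- list(a = beta$a, b = beta$b, c = beta$c, beta_sor = beta$beta_sor,
              beta_sim = beta$beta_sim, beta_nes = beta$beta_nes)
  if (!is.null(config$paths$classes) && file.exists(config$paths$classes)) {
    classes <- tibble::as_tibble(read.csv(config$paths$classes))
    props <- breadth_proportions(sets$set_a, sets$set_b, classes)
    res$breadth <- props
  }
  p <- file.path(out_dir, "beta.json")
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
  p
}
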