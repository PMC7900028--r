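#' True-skill-statistic evaluation at the optimal cut
#'
#' Scans every achievable threshold (the sorted unique predicted scores of
#' test presences and background) and reports sensitivity, specificity and
#' TSS = sensitivity + specificity - 1 at the cut maximizing
#' sensitivity + specificity (ties resolved to the lowest cut). Background
#' points serve as pseudo-absences. A constant map gets TSS 0 with a
#' warning.
#'
#' @param presence_scores Predicted suitabilities at test presences.
#' @param background_scores Predicted suitabilities at background points.
#' @return Tibble: `sensitivity`, `specificity`, `tss`, `threshold`.
#' @examples
#' eval_tss(c(0.9, 0.8), c(0.7, 0.1))
#' @export
eval_tss <- function(presence_scores, background_scores) {
  p <- presence_scores[!is.na(presence_scores)]
  b <- background_scores[!is.na(background_scores)]
  if (length(p) < 1L || length(b) < 1L) {
    stop_invalid("need >= 1 presence and >= 1 background score")
  }
  if (length(unique(c(p, b))) == 1L) {
    warn("constant suitability map; TSS = 0")
    return(tibble::tibble(sensitivity = 1, specificity = 0, tss = 0,
                          threshold = p[1]))
  }
  cuts <- sort(unique(c(p, b)))
  stats_at <- function(t) {
    c(sens = mean(p >= t), spec = mean(b < t))
  }
  s <- vapply(cuts, stats_at, numeric(2))
  tss <- s["sens", ] + s["spec", ] - 1
  best <- which(tss == max(tss))[1]   # cuts sorted: first max = lowest cut
  tibble::tibble(sensitivity = unname(s["sens", best]),
                 specificity = unname(s["spec", best]),
                 tss = unname(tss[best]), threshold = cuts[best])
}

#' Fit, evaluate and map bootstrap replicates of each algorithm
#'
#' For each replicate, presences (and background) are partitioned 75/25
#' into training and test sets; each requested algorithm is fitted on the
#' training data, predicted over the stack, and scored with [eval_tss()]
#' on its own held-out test set. A failing algorithm/replicate is skipped
#' with a warning. With the defaults this yields
#' `n_rep x length(algorithms)` suitability maps.
#'
#' @param occ Occurrence tibble (`lon`, `lat`).
#' @param background Background tibble (`lon`, `lat`).
#' @param stack An [env_stack()].
#' @param vars Layer names to use (default all; normally the
#'   [select_variables()] result).
#' @param algorithms Subset of `c("bioclim", "domain", "svm", "maxent")`.
#' @param n_rep Replicates per algorithm (default 10).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed; replicate partitions are deterministic in it.
#' @return List of `suitability_map`s (each carrying its fitted model, TSS
#'   and replicate id).
#' @export
run_replicates <- function(occ, background, stack, vars = layer_names(stack),
                           algorithms = c("bioclim", "domain", "svm",
                                          "maxent"),
                           n_rep = 10, train_frac = 0.75, seed = 1) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  pe <- extract_env(stack, occ$lon, occ$lat, vars)
  be <- extract_env(stack, background$lon, background$lat, vars)
  pe <- pe[complete.cases(pe), , drop = FALSE]
  be <- be[complete.cases(be), , drop = FALSE]
  n_test <- nrow(pe) - floor(train_frac * nrow(pe))
  if (n_test < 5L) stop_invalid("too few presences: test split < 5")
  maps <- list()
  for (r in seq_len(n_rep)) {
    part <- with_seed(seed + r, {
      list(p = sample.int(nrow(pe), floor(train_frac * nrow(pe))),
           b = sample.int(nrow(be), floor(train_frac * nrow(be))))
    })
    ptr <- pe[part$p, , drop = FALSE]; pte <- pe[-part$p, , drop = FALSE]
    btr <- be[part$b, , drop = FALSE]; bte <- be[-part$b, , drop = FALSE]
    for (alg in algorithms) {
      m <- tryCatch({
        model <- switch(alg,
          bioclim = fit_bioclim(ptr),
          domain = fit_domain(ptr),
          svm = fit_svm(ptr, btr, seed = seed + r),
          maxent = fit_maxent(ptr, btr, seed = seed + r)
        )
        ev <- eval_tss(predict(model, pte), predict(model, bte))
        sm <- predict_stack(model, stack, algorithm = alg, replicate_id = r,
                            tss = ev$tss)
        sm$model <- model
        sm$eval <- ev
        sm
      }, error = function(e) {
        warn(sprintf("replicate %d, %s failed: %s", r, alg,
                     conditionMessage(e)))
        NULL
      })
      if (!is.null(m)) maps[[length(maps) + 1L]] <- m
    }
  }
  maps
}

rescale01 <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    # an all-zero map means "nowhere suitable" and must stay zero (envelope
    # models outside their training range); other constants carry no ranking
    # information and sit at mid-scale
    if (rng[1] == 0) return(v)
    warn("constant map rescaled to 0.5 everywhere")
    v[!is.na(v)] <- 0.5
    return(v)
  }
  (v - rng[1]) / diff(rng)
}

#' TSS-weighted ensemble of suitability maps
#'
#' Keeps the replicates with TSS strictly greater than `tss_min`, min-max
#' rescales each to `[0, 1]`, and averages them per cell with weights equal
#' to their TSS. The ensemble also carries the per-cell SD of the rescaled
#' contributing maps (the uncertainty surface).
#'
#' @param maps List of `suitability_map`s (from [run_replicates()]).
#' @param tss_min TSS filter (default 0.5; maps with TSS <= `tss_min` are
#'   excluded).
#' @return An `ensemble_map`: `mean`, `dispersion` (matrices), `weights`,
#'   `n_contributing`, `members` (metadata tibble), `extent`.
#' @export
ensemble <- function(maps, tss_min = 0.5) {
  keep <- Filter(function(m) isTRUE(m$tss > tss_min), maps)
  if (length(keep) == 0L) {
    abort("no replicate passed the TSS filter", class = "palmsdm_empty_ensemble")
  }
  resc <- lapply(keep, function(m) rescale01(m$values))
  w <- vapply(keep, function(m) m$tss, numeric(1))
  arr <- simplify2array(resc)
  wmean <- apply(arr, c(1, 2), function(v) sum(v * w) / sum(w))
  disp <- if (length(keep) >= 2L) apply(arr, c(1, 2), sd) else arr[, , 1] * 0
  structure(
    list(mean = wmean, dispersion = disp, weights = w,
         n_contributing = length(keep),
         members = tibble::tibble(
           algorithm = vapply(keep, function(m) m$algorithm, character(1)),
           replicate_id = vapply(keep, function(m) m$replicate_id, integer(1)),
           tss = w),
         models = lapply(keep, function(m) m$model),
         extent = keep[[1]]$extent),
    class = "ensemble_map"
  )
}

#' @export
print.ensemble_map <- function(x, ...) {
  cat(sprintf("<ensemble_map> %d contributing replicates, %d x %d cells\n",
              x$n_contributing, nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' @rdname ensemble
#' @param x,object An `ensemble_map`.
#' @param ... Unused.
#' @export
glance.ensemble_map <- function(x, ...) {
  tibble::tibble(n_contributing = x$n_contributing,
                 mean_tss = mean(x$weights),
                 min_tss = min(x$weights),
                 max_dispersion = max(x$dispersion, na.rm = TRUE))
}

#' @rdname ensemble
#' @export
tidy.ensemble_map <- function(x, ...) x$members

#' @rdname ensemble
#' @export
as_tibble.ensemble_map <- function(x, ...) {
  cc <- cell_centers(structure(list(layers = list(x$mean), extent = x$extent,
                                    mask = !is.na(x$mean)),
                               class = "env_stack"))
  tibble::tibble(lon = cc$lon, lat = cc$lat,
                 suitability = as.vector(x$mean),
                 dispersion = as.vector(x$dispersion))
}

#' @rdname ensemble
#' @export
autoplot.ensemble_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "suitability")
}

#' Suitability values of a map at point locations
#'
#' @param map An `ensemble_map` or `suitability_map`.
#' @param lon,lat Coordinates.
#' @return Numeric vector.
#' @export
suitability_at <- function(map, lon, lat) {
  vals <- if (inherits(map, "ensemble_map")) map$mean else map$values
  fake <- structure(list(layers = list(s = vals), extent = map$extent,
                         mask = !is.na(vals)), class = "env_stack")
  extract_env(fake, lon, lat)[, 1]
}

#' Binarization thresholds for a suitability map
#'
#' Computes the four standard presence-absence thresholds from the map's
#' suitability at training presences (and background, for the
#' discrimination-based rules): `MTP` (minimum training presence), `P10`
#' (10th percentile of training-presence suitability), `maxSS` (the cut
#' maximizing sensitivity + specificity, as in [eval_tss()]) and `eqSS`
#' (the cut minimizing |sensitivity - specificity|, lowest cut on ties).
#'
#' @param presence_scores Suitability at training presences (>= 10 for
#'   P10).
#' @param background_scores Suitability at background points.
#' @return Named numeric vector `MTP`, `P10`, `maxSS`, `eqSS`.
#' @export
compute_thresholds <- function(presence_scores, background_scores) {
  p <- presence_scores[!is.na(presence_scores)]
  b <- background_scores[!is.na(background_scores)]
  if (length(p) < 10L) warn("P10 is unstable with < 10 training presences")
  cuts <- sort(unique(c(p, b)))
  sens <- vapply(cuts, function(t) mean(p >= t), numeric(1))
  spec <- vapply(cuts, function(t) mean(b < t), numeric(1))
  maxss <- cuts[which(sens + spec == max(sens + spec))[1]]
  eqss <- cuts[which(abs(sens - spec) == min(abs(sens - spec)))[1]]
  c(MTP = min(p), P10 = unname(quantile(p, 0.1)), maxSS = maxss, eqSS = eqss)
}

#' Threshold a map into a binary range
#'
#' Presence is `suitability >= threshold_value`. Area sums per-cell
#' spherical areas ([cell_areas_km2()]) over presence cells.
#'
#' @param map An `ensemble_map` or `suitability_map`.
#' @param threshold_value Suitability cut.
#' @param rule Label of the threshold rule (`"MTP"`, `"P10"`, `"maxSS"`,
#'   `"eqSS"` or free text).
#' @return A `binary_range`: `presence` (logical matrix), `rule`,
#'   `threshold_value`, `area_km2`, `extent`.
#' @export
binarize <- function(map, threshold_value, rule = NA_character_) {
  vals <- if (inherits(map, "ensemble_map")) map$mean else map$values
  pres <- !is.na(vals) & vals >= threshold_value
  areas <- cell_areas_km2(list(extent = map$extent), dims = dim(vals))
  structure(
    list(presence = pres, rule = rule, threshold_value = threshold_value,
         area_km2 = sum(areas[pres]), extent = map$extent),
    class = "binary_range"
  )
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("<binary_range> rule %s @ %.3f: %d cells, %.0f km2\n",
              x$rule, x$threshold_value, sum(x$presence), x$area_km2))
  invisible(x)
}

#' Range overlap between two binary ranges
#'
#' @param r1,r2 Co-registered [binarize()] results.
#' @return Tibble: `area1_km2`, `area2_km2`, `overlap_km2`, `pct_of_r1`
#'   (overlap as a percentage of `r1`'s area).
#' @export
overlap_area <- function(r1, r2) {
  if (!identical(dim(r1$presence), dim(r2$presence)) ||
      !isTRUE(all.equal(r1$extent, r2$extent))) {
    stop_invalid("binary ranges must be co-registered")
  }
  areas <- cell_areas_km2(list(extent = r1$extent), dims = dim(r1$presence))
  both <- r1$presence & r2$presence
  ov <- sum(areas[both])
  tibble::tibble(area1_km2 = r1$area_km2, area2_km2 = r2$area_km2,
                 overlap_km2 = ov,
                 pct_of_r1 = ifelse(r1$area_km2 > 0, 100 * ov / r1$area_km2,
                                    NA_real_))
}

#' Project an ensemble onto a future climate stack
#'
#' Re-predicts every contributing replicate's fitted model on the future
#' layers and re-ensembles with the TSS weights earned on current-climate
#' test data (weights are not re-estimated in the future, where no truth
#' exists).
#'
#' @param ens An [ensemble()] result whose members carry fitted models.
#' @param future_stack An [env_stack()] with the same selected variables.
#' @return An `ensemble_map` on the future stack.
#' @export
project_ensemble <- function(ens, future_stack) {
  if (length(ens$models) == 0L || is.null(ens$models[[1]])) {
    stop_invalid("ensemble members carry no fitted models")
  }
  maps <- purrr::pmap(
    list(ens$models, ens$members$algorithm, ens$members$replicate_id,
         ens$weights),
    function(model, alg, rep, tss) {
      m <- predict_stack(model, future_stack, algorithm = alg,
                         replicate_id = rep, tss = tss)
      m$model <- model
      m
    }
  )
  ensemble(maps, tss_min = -Inf)
}

#' Per-cell uncertainty across replicate maps
#'
#' The SD, per cell, of the min-max rescaled contributing maps; high values
#' flag regions where replicates disagree and predictions should be read
#' with caution.
#'
#' @param maps List of >= 2 `suitability_map`s.
#' @return A `suitability_map`-like object whose `values` are SDs.
#' @export
uncertainty_map <- function(maps) {
  if (length(maps) < 2L) stop_degenerate("need >= 2 maps for uncertainty")
  arr <- simplify2array(lapply(maps, function(m) rescale01(m$values)))
  suitability_map(pmin(apply(arr, c(1, 2), sd), 1), maps[[1]]$extent,
                  algorithm = "uncertainty")
}
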