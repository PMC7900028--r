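#' Factor-analysis variable selection
#'
#' Reduces a bank of collinear bioclimatic variables to one representative
#' per retained factor. Factors come from the eigendecomposition of the
#' correlation matrix; the number retained follows the Kaiser criterion
#' (eigenvalue > 1, applied with a small boundary tolerance so a
#' population-level unit eigenvalue is not discarded by sampling noise).
#' Loadings of the retained factors are varimax-rotated, and for each
#' factor the variable with the largest absolute loading is selected. If a
#' candidate correlates at `|r| >= r_max` with an already-selected
#' variable, it is discarded and the next-strongest contributor to that
#' factor is tried (recorded in `rejected_pairs`).
#'
#' @param background_env Points x variables table (n points > n variables).
#' @param r_max Pairwise correlation ceiling among selected variables
#'   (default 0.7).
#' @param kaiser_tol Retain factors with eigenvalue > `1 - kaiser_tol`.
#' @return A `variable_selection` list: `selected` (ordered layer names),
#'   `factor_loadings` (variables x retained factors, varimax-rotated),
#'   `rejected_pairs` (tibble `var`, `conflicts_with`, `r`), `eigenvalues`.
#' @examples
#' x <- matrix(rnorm(600), 200, 3)
#' select_variables(cbind(a = x[, 1], b = x[, 1] + 0.01 * x[, 3], c = x[, 2]))
#' @export
select_variables <- function(background_env, r_max = 0.7, kaiser_tol = 0.05) {
  x <- as.matrix(background_env)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (ncol(x) < 2L) stop_invalid("need >= 2 variables")
  if (nrow(x) <= ncol(x)) stop_invalid("need more points than variables")
  cm <- cor(x)
  eig <- eigen(cm, symmetric = TRUE)
  k <- sum(eig$values > 1 - kaiser_tol)
  k <- max(1L, k)
  load <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  if (k >= 2L) load <- stats::varimax(load)$loadings[, , drop = FALSE]
  load <- matrix(as.numeric(load), ncol = k,
                 dimnames = list(colnames(x), paste0("F", seq_len(k))))
  picked <- pick_representatives(load, cm, r_max)
  if (length(picked$selected) == 0L) {
    warn("all variables mutually correlated above r_max; keeping the best one")
    picked$selected <- colnames(x)[which.max(abs(load[, 1]))]
  }
  structure(
    list(selected = picked$selected, factor_loadings = load,
         rejected_pairs = picked$rejected, eigenvalues = eig$values,
         n_factors = k),
    class = "variable_selection"
  )
}

# Greedy per-factor representative choice with correlation-based
# substitution; separated out so the policy is testable on hand matrices.
pick_representatives <- function(loadings, cormat, r_max) {
  selected <- character(0)
  rejected <- tibble::tibble(var = character(0), conflicts_with = character(0),
                             r = numeric(0))
  for (f in seq_len(ncol(loadings))) {
    cands <- rownames(loadings)[order(-abs(loadings[, f]))]
    cands <- setdiff(cands, selected)
    for (v in cands) {
      if (length(selected) > 0) {
        rs <- cormat[v, selected]
        if (any(abs(rs) >= r_max)) {
          j <- which.max(abs(rs))
          rejected <- dplyr::bind_rows(rejected, tibble::tibble(
            var = v, conflicts_with = selected[j], r = unname(rs[j])))
          next
        }
      }
      selected <- c(selected, v)
      break
    }
  }
  list(selected = selected, rejected = rejected)
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("<variable_selection> %d factor(s) -> %s\n", x$n_factors,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @rdname select_variables
#' @param x A `variable_selection`.
#' @param ... Unused.
#' @export
tidy.variable_selection <- function(x, ...) {
  tibble::tibble(factor = paste0("F", seq_len(x$n_factors)),
                 selected = x$selected[seq_len(min(x$n_factors,
                                                   length(x$selected)))])
}

new_sdm_model <- function(algorithm, ...) {
  structure(list(algorithm = algorithm, ...),
            class = c(paste0("sdm_", algorithm), "sdm_model"))
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> algorithm: %s\n", x$algorithm))
  invisible(x)
}

as_env_matrix <- function(env) {
  x <- as.matrix(env)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  x
}

#' Bioclim envelope-score model
#'
#' Classic climate-envelope scoring. For each variable the query value gets
#' a percentile `p` within the training distribution, computed with the
#' mean-rank convention `p = (rank - 1) / (n - 1)` (ties averaged). The
#' cell score is `min over variables of 2 * min(p, 1 - p)`, clipped to
#' `[0, 1]`; a query outside any variable's training min-max scores 0. A
#' query at every training median scores 1.
#'
#' @param train_env Training presence environments (>= 3 points).
#' @return An `sdm_model` (instance-based: retains sorted training values).
#' @examples
#' m <- fit_bioclim(data.frame(bio1 = c(1, 2, 3, 4, 5)))
#' predict(m, data.frame(bio1 = c(2, 3, 6)))
#' @export
fit_bioclim <- function(train_env) {
  x <- as_env_matrix(train_env)
  if (nrow(x) < 3L) stop_invalid("bioclim needs >= 3 training points")
  new_sdm_model("bioclim",
                training = apply(x, 2, sort),
                vars = colnames(x))
}

#' @export
predict.sdm_bioclim <- function(object, newdata, ...) {
  x <- as_env_matrix(newdata)[, object$vars, drop = FALSE]
  tr <- object$training
  n <- nrow(tr)
  score <- rep(1, nrow(x))
  for (v in object$vars) {
    xv <- x[, v]
    tv <- tr[, v]
    nless <- findInterval(xv, tv, left.open = TRUE)   # #{t < q}
    nleq <- findInterval(xv, tv)                      # #{t <= q}
    r <- nless + (nleq - nless + 1) / 2
    p <- (r - 1) / (n - 1)
    sv <- 2 * pmin(p, 1 - p)
    sv[xv < tv[1] | xv > tv[n]] <- 0
    score <- pmin(score, sv)
    score[is.na(xv)] <- NA
  }
  pmin(pmax(score, 0), 1)
}

#' Domain (Gower distance) model
#'
#' Instance-based suitability: the Gower distance between a query and a
#' training point is the mean over variables of `|x - y| / range_v`, with
#' ranges taken from the training data. Suitability is `max over training
#' points of (1 - d)`, clipped to `[0, 1]`; a query equal to any training
#' point scores 1. Zero-range variables are dropped with a warning.
#'
#' @param train_env Training presence environments (non-empty).
#' @return An `sdm_model`.
#' @export
fit_domain <- function(train_env) {
  x <- as_env_matrix(train_env)
  if (nrow(x) == 0L) stop_invalid("domain needs training points")
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (any(rng == 0)) {
    warn(paste("dropping zero-range variable(s):",
               paste(colnames(x)[rng == 0], collapse = ", ")))
    x <- x[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
    if (ncol(x) == 0L) stop_invalid("no variable has positive training range")
  }
  new_sdm_model("domain", training = x, ranges = rng, vars = colnames(x))
}

#' @export
predict.sdm_domain <- function(object, newdata, ...) {
  x <- as_env_matrix(newdata)[, object$vars, drop = FALSE]
  xs <- sweep(x, 2, object$ranges, "/")
  ts <- sweep(object$training, 2, object$ranges, "/")
  out <- vapply(seq_len(nrow(xs)), function(i) {
    if (anyNA(xs[i, ])) return(NA_real_)
    d <- rowMeans(abs(sweep(ts, 2, xs[i, ])))
    1 - min(d)
  }, numeric(1))
  pmin(pmax(out, 0), 1)
}

#' Support-vector-machine presence-background model
#'
#' Two-class RBF-kernel SVM (presence vs background); background
#' observations are down-weighted in inverse proportion to their count so
#' the classes carry equal total weight. Suitability is the decision value
#' passed through a Platt-style logistic calibration fitted on the training
#' data, giving a score in `[0, 1]`. Deterministic given `seed` (which
#' fixes the kernel-width heuristic).
#'
#' @param presence_env,background_env Environment tables (>= 10 rows each).
#' @param kernel kernlab kernel name (default `"rbfdot"`).
#' @param seed Integer seed.
#' @return An `sdm_model` wrapping the kernlab fit.
#' @export
fit_svm <- function(presence_env, background_env, kernel = "rbfdot", seed = 1) {
  xp <- as_env_matrix(presence_env)
  xb <- as_env_matrix(background_env)
  if (nrow(xp) < 10L || nrow(xb) < 10L) {
    stop_invalid("svm needs >= 10 presences and >= 10 background points")
  }
  x <- rbind(xp, xb)
  y <- factor(rep(c("presence", "background"), c(nrow(xp), nrow(xb))),
              levels = c("presence", "background"))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  fit <- with_seed(seed, {
    kernlab::ksvm(xs, y, kernel = kernel, C = 1,
                  class.weights = c(presence = 1,
                                    background = nrow(xp) / nrow(xb)))
  })
  # Platt-style calibration of the decision values, fitted on the training
  # data; also absorbs kernlab's class-order sign convention.
  d <- as.numeric(kernlab::predict(fit, xs, type = "decision"))
  cal <- suppressWarnings(
    stats::glm((y == "presence") ~ d, family = stats::binomial())
  )
  new_sdm_model("svm", fit = fit, calibration = stats::coef(cal),
                center = ctr, scale = scl, vars = colnames(x), seed = seed)
}

#' @export
predict.sdm_svm <- function(object, newdata, ...) {
  x <- as_env_matrix(newdata)[, object$vars, drop = FALSE]
  out <- rep(NA_real_, nrow(x))
  ok <- complete.cases(x)
  if (any(ok)) {
    xs <- scale(x[ok, , drop = FALSE], object$center, object$scale)
    d <- as.numeric(kernlab::predict(object$fit, xs, type = "decision"))
    out[ok] <- stats::plogis(object$calibration[1] + object$calibration[2] * d)
  }
  pmin(pmax(out, 0), 1)
}

#' Maximum-entropy-style penalized logistic model
#'
#' L1-regularized logistic regression of presence vs background on a
#' linear + quadratic feature expansion (the glmnet-style equivalent of
#' the maximum-entropy model family with those feature classes).
#' Features are standardized on the pooled data; the penalty is
#' `reg_mult * lambda_max / 100`, where `lambda_max` is the smallest
#' penalty that zeroes every coefficient, so larger `reg_mult` shrinks the
#' coefficient L1 norm. Suitability uses the complementary log-log
#' transform `1 - exp(-exp(eta))` of the linear predictor, mapping onto
#' `(0, 1)`.
#'
#' @param presence_env,background_env Environment tables; >= 10 presences,
#'   background at least as many rows as presences.
#' @param features Feature classes, subset of `c("linear", "quadratic")`.
#' @param reg_mult Regularization multiplier (default 1).
#' @param seed Integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @return An `sdm_model` with the coefficient vector.
#' @export
fit_maxent <- function(presence_env, background_env,
                       features = c("linear", "quadratic"), reg_mult = 1,
                       seed = 1) {
  xp <- as_env_matrix(presence_env)
  xb <- as_env_matrix(background_env)
  if (nrow(xp) < 10L) stop_invalid("maxent needs >= 10 presences")
  if (nrow(xb) < nrow(xp)) stop_invalid("background must be >= presences")
  features <- match.arg(features, several.ok = TRUE)
  vars <- colnames(xp)
  expand <- function(x) {
    out <- NULL
    if ("linear" %in% features) out <- cbind(out, x)
    if ("quadratic" %in% features) {
      q <- x^2
      colnames(q) <- paste0(colnames(x), "_sq")
      out <- cbind(out, q)
    }
    out
  }
  f <- expand(rbind(xp, xb))
  ctr <- colMeans(f)
  scl <- apply(f, 2, sd)
  scl[scl == 0] <- 1
  fs <- scale(f, ctr, scl)
  y <- rep(1:0, c(nrow(xp), nrow(xb)))
  # glmnet's lambda_max: smallest penalty with all coefficients zero. The
  # fit walks a warm-started path down to the target penalty (a single small
  # lambda can fail to converge under complete separation).
  lambda_max <- max(abs(crossprod(fs, y - mean(y)))) / length(y)
  lambda <- reg_mult * lambda_max / 100
  path <- exp(seq(log(lambda_max), log(min(lambda, lambda_max)),
                  length.out = 30))
  fit <- glmnet::glmnet(fs, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE)
  if (fit$jerr != 0 || length(fit$lambda) < length(path)) {
    abort(sprintf("maxent fit did not converge (glmnet jerr = %d)", fit$jerr),
          class = "palmsdm_nonconvergence")
  }
  new_sdm_model("maxent",
                coef = as.numeric(stats::coef(fit, s = min(path))),
                feature_names = colnames(f), center = ctr, scale = scl,
                vars = vars, features = features, reg_mult = reg_mult,
                lambda = lambda, expand = NULL)
}

maxent_features <- function(object, x) {
  out <- NULL
  if ("linear" %in% object$features) out <- cbind(out, x)
  if ("quadratic" %in% object$features) {
    q <- x^2
    colnames(q) <- paste0(colnames(x), "_sq")
    out <- cbind(out, q)
  }
  out[, object$feature_names, drop = FALSE]
}

#' @export
predict.sdm_maxent <- function(object, newdata, ...) {
  x <- as_env_matrix(newdata)[, object$vars, drop = FALSE]
  f <- maxent_features(object, x)
  fs <- scale(f, object$center, object$scale)
  eta <- object$coef[1] + as.numeric(fs %*% object$coef[-1])
  out <- 1 - exp(-exp(eta))
  out[!complete.cases(x)] <- NA
  pmin(pmax(out, 0), 1)
}

#' Coefficient L1 norm of a maxent-style model
#' @param model An `sdm_maxent` model.
#' @return Sum of absolute feature coefficients (intercept excluded).
#' @export
coef_l1 <- function(model) sum(abs(model$coef[-1]))

#' Predict a suitability surface over a stack
#'
#' @param model An `sdm_model`.
#' @param stack An [env_stack()].
#' @param algorithm,replicate_id,tss Metadata carried on the map.
#' @return A `suitability_map`: matrix of suitabilities in `[0, 1]` with
#'   nodata propagated, plus metadata.
#' @export
predict_stack <- function(model, stack, algorithm = model$algorithm,
                          replicate_id = NA_integer_, tss = NA_real_) {
  miss <- setdiff(model$vars, layer_names(stack))
  if (length(miss) > 0) {
    stop_invalid(paste("stack is missing layer(s):", paste(miss, collapse = ", ")))
  }
  env <- env_values(stack)[, model$vars, drop = FALSE]
  vals <- rep(NA_real_, nrow(env))
  ok <- as.vector(stack$mask)
  vals[ok] <- predict(model, env[ok, , drop = FALSE])
  suitability_map(matrix(vals, nrow(stack$layers[[1]])), stack$extent,
                  algorithm = algorithm, replicate_id = replicate_id,
                  tss = tss)
}

#' Suitability map container
#'
#' @param values Matrix of suitabilities in `[0, 1]` (NA = nodata).
#' @param extent Geographic extent `c(xmin, xmax, ymin, ymax)`.
#' @param algorithm,replicate_id,tss Metadata.
#' @param model Optional fitted model (kept for future projection).
#' @return A `suitability_map`.
#' @export
suitability_map <- function(values, extent, algorithm = NA_character_,
                            replicate_id = NA_integer_, tss = NA_real_,
                            model = NULL) {
  v <- as.matrix(values)
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
    stop_invalid("suitability values must lie in [0, 1]")
  }
  structure(list(values = v, extent = as.numeric(extent),
                 algorithm = algorithm, replicate_id = replicate_id,
                 tss = tss, model = model),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s (rep %s), %d x %d, TSS %s\n",
              x$algorithm, x$replicate_id, nrow(x$values), ncol(x$values),
              ifelse(is.na(x$tss), "NA", sprintf("%.2f", x$tss))))
  invisible(x)
}
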