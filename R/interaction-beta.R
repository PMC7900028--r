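normalize_name <- function(x) tolower(trimws(x))

#' Per-palm frugivore species sets
#'
#' Aggregates an interaction table to the set of distinct bird species
#' recorded with each palm (names matched after trimming and
#' case-folding; duplicate records do not inflate the sets).
#'
#' @param interactions Tibble with columns `palm`, `bird` (plus optional
#'   `site`, `source`).
#' @param palms Length-2 character vector declaring the palm pair; rows
#'   with any other palm label raise an error.
#' @return List: `set_a`, `set_b` (character vectors), `records` (tibble of
#'   record counts per palm).
#' @export
species_sets <- function(interactions, palms = NULL) {
  tab <- tibble::as_tibble(interactions)
  if (nrow(tab) == 0L) stop_invalid("interaction table is empty")
  tab$palm <- normalize_name(tab$palm)
  tab$bird <- normalize_name(tab$bird)
  if (is.null(palms)) palms <- sort(unique(tab$palm))
  palms <- normalize_name(palms)
  if (length(palms) != 2L) stop_invalid("exactly two palm labels are required")
  unknown <- setdiff(unique(tab$palm), palms)
  if (length(unknown) > 0) {
    stop_invalid(paste("unknown palm label(s):", paste(unknown, collapse = ", ")))
  }
  list(
    set_a = sort(unique(tab$bird[tab$palm == palms[1]])),
    set_b = sort(unique(tab$bird[tab$palm == palms[2]])),
    records = dplyr::count(tab, .data$palm, name = "n_records")
  )
}

#' Sorensen dissimilarity and its turnover/nestedness partition
#'
#' For species sets with `a` shared and `b`, `c` unique members:
#' `beta_SOR = (b + c) / (2a + b + c)` (Sorensen dissimilarity),
#' `beta_SIM = min(b, c) / (a + min(b, c))` (Simpson turnover), and
#' `beta_NES = beta_SOR - beta_SIM` (nestedness-resultant component).
#' The identity `beta_SOR = beta_SIM + beta_NES` holds exactly and the
#' result is symmetric in its arguments.
#'
#' @param set_a,set_b Character vectors (at least one non-empty).
#' @return A `beta_result` tibble row: `a`, `b`, `c`, `beta_sor`,
#'   `beta_sim`, `beta_nes`.
#' @examples
#' sorensen_partition(as.character(1:5), as.character(3:8))
#' @export
sorensen_partition <- function(set_a, set_b) {
  set_a <- unique(normalize_name(set_a))
  set_b <- unique(normalize_name(set_b))
  if (length(set_a) + length(set_b) == 0L) {
    stop_degenerate("both species sets are empty")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  beta_sor <- if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
  beta_sim <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  out <- tibble::tibble(a = a, b = b, c = cc, beta_sor = beta_sor,
                        beta_sim = beta_sim, beta_nes = beta_sor - beta_sim)
  class(out) <- c("beta_result", class(out))
  out
}

#' @export
print.beta_result <- function(x, ...) {
  cat(sprintf(
    "<beta_result> a=%d b=%d c=%d | beta_SOR=%.3f = %.3f (turnover) + %.3f (nestedness)\n",
    x$a, x$b, x$c, x$beta_sor, x$beta_sim, x$beta_nes))
  invisible(x)
}

#' Diet-breadth class proportions per palm
#'
#' @param set_a,set_b Bird sets per palm (see [species_sets()]).
#' @param classes Tibble with columns `bird`, `class` (e.g. generalist /
#'   specialist). Unclassified birds are excluded from the proportions and
#'   reported in the `unclassified` attribute.
#' @param palms Labels for the output `palm` column.
#' @return Tibble: `palm`, `class`, `n`, `proportion` (proportions sum to 1
#'   per palm over classified birds).
#' @export
breadth_proportions <- function(set_a, set_b, classes,
                                palms = c("palm_a", "palm_b")) {
  classes <- tibble::as_tibble(classes)
  classes$bird <- normalize_name(classes$bird)
  one <- function(set, palm) {
    set <- unique(normalize_name(set))
    cl <- classes$class[match(set, classes$bird)]
    known <- !is.na(cl)
    out <- dplyr::count(tibble::tibble(class = cl[known]), .data$class)
    out$proportion <- out$n / sum(out$n)
    out$palm <- palm
    attr(out, "unclassified") <- set[!known]
    out
  }
  res_a <- one(set_a, palms[1])
  res_b <- one(set_b, palms[2])
  out <- dplyr::bind_rows(res_a, res_b)[, c("palm", "class", "n", "proportion")]
  attr(out, "unclassified") <- list(
    setNames(list(attr(res_a, "unclassified"), attr(res_b, "unclassified")),
             palms)
  )[[1]]
  out
}
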