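#' Tidy a clone map into a per-spot tibble
#'
#' @param x A [map_clones()] result.
#' @param ... Unused.
#' @return Tibble with one row per spot: `spot_id`, `clone`, `clone_score`,
#'   `margin`, `concordant_with_control`.
#' @method tidy clone_map
#' @export
tidy.clone_map <- function(x, ...) x$assignments

#' One-row summary of a clone map
#'
#' @param x A [map_clones()] result.
#' @param ... Unused.
#' @return Tibble with `n_spots`, `n_clone_A`, `n_clone_B`,
#'   `mean_score_A`, `mean_score_B`, `concordance`, `n_genes_used`.
#' @method glance clone_map
#' @export
glance.clone_map <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_spots = nrow(a),
    n_clone_A = sum(a$clone == "A"),
    n_clone_B = sum(a$clone == "B"),
    mean_score_A = mean(a$clone_score[a$clone == "A"]),
    mean_score_B = mean(a$clone_score[a$clone == "B"]),
    concordance = x$concordance,
    n_genes_used = x$params$n_informative_used
  )
}

#' Tidy a segmentation into a per-spot tibble
#'
#' @param x A [segment_spatial()] / [cluster_expression()] result.
#' @param ... Unused.
#' @return Tibble with `spot_id`, `cluster`.
#' @method tidy segmentation_result
#' @export
tidy.segmentation_result <- function(x, ...) x$labels

#' One-row summary of a segmentation
#'
#' @param x A segmentation result.
#' @param ... Unused.
#' @return Tibble with `K`, `n_spots`, `energy`, `n_iter`, `method`.
#' @method glance segmentation_result
#' @export
glance.segmentation_result <- function(x, ...) {
  tibble(K = x$K, n_spots = nrow(x$labels), energy = x$energy,
         n_iter = length(x$n_changed_per_iter),
         method = x$params$method)
}

#' Tidy FISH validation tests
#'
#' @param x A [validate_with_fish()] result.
#' @param ... Unused.
#' @return The per-probe test tibble.
#' @method tidy fish_validation
#' @export
tidy.fish_validation <- function(x, ...) x$tests
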