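#' Area-filter a structure table
#'
#' Applies the post-classification filters: structures classified as cells
#' are kept when their area is at least `cell_min` (structures below 10 um^2
#' are excluded, boundary inclusive for keeping), and structures classified
#' as microtubes are kept when their area is strictly greater than
#' `mt_min` (2 um^2). Idempotent.
#'
#' @param structures Structure tibble (`sample_id`, `crop_id`, `class`,
#'   `area_um2`).
#' @param cell_min Minimum retained cell area (kept if `>=`), um^2.
#' @param mt_min Microtube area threshold (kept if `>`), um^2.
#' @return Filtered tibble.
#' @export
filter_structures <- function(structures, cell_min = 10, mt_min = 2) {
  stopifnot(all(c("class", "area_um2") %in% names(structures)))
  dplyr::filter(structures,
                (.data$class == "cell" & .data$area_um2 >= cell_min) |
                  (.data$class == "microtube" & .data$area_um2 > mt_min))
}

#' Microtube area per cell
#'
#' Per crop: the summed microtube area divided by the number of retained
#' cells (a crop with no microtubes scores 0; a crop with no retained cells
#' is excluded with a warning). The per-sample value aggregates crops by
#' their mean (`aggregate = "mean"`) or pools structures across crops
#' (`aggregate = "pool"`: total microtube area / total cells).
#'
#' @param structures A filtered structure tibble ([filter_structures()]).
#' @param aggregate `"mean"` or `"pool"`.
#' @return List with `per_crop` (tibble `sample_id`, `crop_id`, `n_cells`,
#'   `microtube_area`, `area_per_cell`) and `per_sample` (tibble
#'   `sample_id`, `area_per_cell`).
#' @export
microtube_area_per_cell <- function(structures,
                                    aggregate = c("mean", "pool")) {
  aggregate <- match.arg(aggregate)
  per_crop <- structures |>
    dplyr::group_by(.data$sample_id, .data$crop_id) |>
    dplyr::summarise(
      n_cells = sum(.data$class == "cell"),
      microtube_area = sum(.data$area_um2[.data$class == "microtube"]),
      .groups = "drop"
    )
  empty <- per_crop$n_cells == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " crop(s) with no retained cells excluded"))
    per_crop <- per_crop[!empty, ]
  }
  if (nrow(per_crop) == 0) abort("no crop with retained cells")
  per_crop$area_per_cell <- per_crop$microtube_area / per_crop$n_cells
  per_sample <- if (aggregate == "mean") {
    per_crop |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(area_per_cell = mean(.data$area_per_cell),
                       .groups = "drop")
  } else {
    per_crop |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(area_per_cell = sum(.data$microtube_area) /
                         sum(.data$n_cells), .groups = "drop")
  }
  list(per_crop = per_crop, per_sample = per_sample)
}

#' Compare per-sample values between groups (Welch t-tests)
#'
#' Welch two-sample t-test for every pair of groups, with BH correction
#' when there are more than two groups. One-tailed alternatives refer to
#' the first group of the pair.
#'
#' @param values Tibble with one row per sample: a value column and a group
#'   column.
#' @param value,group Column names (strings).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return Tibble with `group1`, `group2`, `t`, `df`, `p`, `q`.
#' @export
compare_groups <- function(values, value = "area_per_cell",
                           group = "group",
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  v <- values[[value]]
  g <- as.character(values[[group]])
  groups <- unique(g)
  if (length(groups) < 2) abort("need at least two groups")
  sizes <- table(g)
  if (any(sizes < 2)) abort("every group needs at least 2 samples")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    ht <- t.test(v[g == pr[1]], v[g == pr[2]],
                 alternative = alternative, var.equal = FALSE)
    tibble(group1 = pr[1], group2 = pr[2],
           t = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value)
  })
  out$q <- bh_adjust(out$p)
  out
}
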