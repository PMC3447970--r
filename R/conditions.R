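#' Build the experimental condition table
#'
#' The design crosses three target positions with three obstacle costs
#' (nine conditions). Each target is a vertical strip on the screen; the
#' virtual obstacle is a half-plane at the midway depth whose left edge sits a
#' fixed distance to the right of the target centre. Hitting the target earns
#' `target_reward`; passing right of the obstacle edge costs
#' `obstacle_costs` points.
#'
#' Screen-absolute coordinates appear only in this table; everywhere else the
#' package works obstacle-relative (excursion `x1`, negative = left of the
#' edge) and target-relative (endpoint error `x2`).
#'
#' @param target_centers_mm Screen x of target centres, mm right of screen
#'   centre. Default `c(0, 38, 75)`.
#' @param obstacle_costs_points Point costs for passing through the obstacle
#'   (negative). Default `c(-1, -2, -5)`.
#' @param target_reward_points Points earned for a target hit. Default `2`.
#' @param target_width_mm Width of the rewarded target strip, mm. Default
#'   `6.5`. Assumed equal to the visible strip; configurable.
#' @param obstacle_offset_mm Distance from target centre to the obstacle's
#'   left edge, mm. Default `6.6`.
#'
#' @return A tibble with one row per condition: `condition_id`,
#'   `target_center_mm`, `obstacle_edge_mm`, `obstacle_cost_points`,
#'   `target_reward_points`, `target_width_mm`, `obstacle_location_index`.
#' @export
#' @examples
#' reach_conditions()
reach_conditions <- function(target_centers_mm = c(0, 38, 75),
                             obstacle_costs_points = c(-1, -2, -5),
                             target_reward_points = 2,
                             target_width_mm = 6.5,
                             obstacle_offset_mm = 6.6) {
  stopifnot(
    all(is.finite(target_centers_mm)),
    all(is.finite(obstacle_costs_points)), all(obstacle_costs_points < 0),
    is.finite(target_reward_points), target_reward_points > 0,
    is.finite(target_width_mm), target_width_mm > 0,
    is.finite(obstacle_offset_mm)
  )
  grid <- tidyr::expand_grid(
    obstacle_location_index = seq_along(target_centers_mm),
    obstacle_cost_points = obstacle_costs_points
  )
  tibble::tibble(
    condition_id = sprintf(
      "T%d_V%d", grid$obstacle_location_index,
      match(grid$obstacle_cost_points, obstacle_costs_points)
    ),
    target_center_mm = target_centers_mm[grid$obstacle_location_index],
    obstacle_edge_mm = target_centers_mm[grid$obstacle_location_index] +
      obstacle_offset_mm,
    obstacle_cost_points = grid$obstacle_cost_points,
    target_reward_points = target_reward_points,
    target_width_mm = target_width_mm,
    obstacle_location_index = grid$obstacle_location_index
  )
}

#' Classify the outcome of a reach
#'
#' A reach hits the obstacle iff its obstacle-plane excursion is strictly
#' right of the edge (`excursion_mm > 0`) and hits the target iff its
#' endpoint lies within the target strip (`|endpoint_mm| <= width/2`,
#' boundary inclusive). Both events can occur on one reach.
#'
#' @param excursion_mm Obstacle-relative crossing x1, mm (vectorised).
#' @param endpoint_mm Target-relative endpoint x2, mm (vectorised).
#' @param condition A one-row condition (as from [reach_conditions()]) or any
#'   list with a `target_width_mm` element.
#'
#' @return Character vector with levels `hit_both`, `hit_target_only`,
#'   `hit_obstacle_only`, `miss_both`.
#' @export
#' @examples
#' cond <- reach_conditions()[1, ]
#' classify_outcome(c(-5, 0.1, 1), c(0, 4, 3.25), cond)
classify_outcome <- function(excursion_mm, endpoint_mm, condition) {
  if (!all(is.finite(excursion_mm)) || !all(is.finite(endpoint_mm))) {
    stop("classify_outcome(): coordinates must be finite", call. = FALSE)
  }
  w <- condition$target_width_mm
  stopifnot(length(w) == 1, is.finite(w), w > 0)
  obstacle <- excursion_mm > 0
  target <- abs(endpoint_mm) <= w / 2
  dplyr::case_when(
    obstacle & target ~ "hit_both",
    target ~ "hit_target_only",
    obstacle ~ "hit_obstacle_only",
    .default = "miss_both"
  )
}

outcome_levels <- function() {
  c("hit_both", "hit_target_only", "hit_obstacle_only", "miss_both")
}
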