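#' Ecosystem-service x SDG support matrix
#'
#' `G[i, j]` counts the SDG targets of goal j supported by ecosystem
#' service i. Only the per-service marginals of this mapping are published
#' (habitat quality: 10 goals / 29 targets; carbon storage: 7 / 19; water
#' yield: 10 / 25; soil retention: 2 / 9; 12 goals supported in total), so
#' the shipped default matrix is a synthetic reconstruction that
#' distributes target counts across goals consistently with every one of
#' those marginals. It ships as editable data
#' (`inst/extdata/sdg_support_matrix_synthetic.csv`); replace it with a
#' target-level mapping if you have one.
#'
#' @return 4 x 17 integer matrix, rows named by ES, columns SDG1..SDG17.
#' @export
default_support_matrix <- function() {
  G <- matrix(0L, nrow = 4, ncol = 17,
              dimnames = list(c("habitat_quality", "carbon_storage",
                                "water_yield", "soil_retention"),
                              paste0("SDG", 1:17)))
  G["habitat_quality", c(1, 2, 3, 6, 8, 11, 12, 13, 14, 15)] <-
    c(2L, 4L, 2L, 3L, 2L, 3L, 3L, 2L, 4L, 4L)
  G["carbon_storage", c(2, 7, 9, 11, 12, 13, 15)] <-
    c(2L, 4L, 2L, 2L, 3L, 4L, 2L)
  G["water_yield", c(1, 2, 3, 6, 7, 9, 11, 12, 14, 15)] <-
    c(2L, 3L, 2L, 5L, 2L, 2L, 3L, 2L, 2L, 2L)
  G["soil_retention", c(6, 15)] <- c(4L, 5L)
  G
}

#' Load and validate a support matrix from CSV
#'
#' Expects one row per ecosystem service (first column the ES name) and up
#' to 17 SDG columns of non-negative integer target counts. An all-zero
#' matrix is rejected.
#'
#' @param path CSV path; `NULL` loads the shipped default reconstruction.
#' @return validated integer matrix.
#' @export
load_support_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sdg_support_matrix_synthetic.csv",
                        package = "esluc", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  if (ncol(df) > 17L)
    stop("validation error: more than 17 SDG columns", call. = FALSE)
  G <- as.matrix(df)
  if (any(G < 0) || any(G != round(G)))
    stop("validation error: support counts must be non-negative integers",
         call. = FALSE)
  if (all(G == 0))
    stop("validation error: all-zero support matrix (no supported goals)",
         call. = FALSE)
  storage.mode(G) <- "integer"
  G
}

#' Marginals of a support matrix
#'
#' Per ecosystem service, the number of supported goals (nonzero columns)
#' and total supported targets (row sum), plus the count of goals supported
#' by at least one service.
#'
#' @param G support matrix.
#' @return list with data.frame `per_es` (`es`, `n_goals`, `n_targets`) and
#'   scalar `n_goals_union`.
#' @export
support_marginals <- function(G) {
  per_es <- data.frame(
    es = rownames(G),
    n_goals = apply(G, 1, function(r) sum(r > 0)),
    n_targets = rowSums(G),
    row.names = NULL)
  list(per_es = per_es, n_goals_union = sum(colSums(G) > 0))
}

#' Score one SDG from normalised ecosystem services
#'
#' `SDG_j = sum_i(ES~_i x G_ij) / sum_i(G_ij)`: the G-weighted mean of the
#' normalised ES surfaces, bounded [0, 1]. Goals with zero column sum have
#' no defined score and are refused here (the composite simply skips them).
#'
#' @param panel named list of normalised ES raster_grids; names must cover
#'   the rownames of `G`.
#' @param G support matrix.
#' @param goal column name (e.g. `"SDG6"`) or index.
#' @return raster_grid in [0, 1].
#' @export
sdg_goal_score <- function(panel, G, goal) {
  miss <- setdiff(rownames(G), names(panel))
  if (length(miss))
    stop("validation error: panel lacks ES layer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- G[, goal]
  if (sum(g) <= 0)
    stop(sprintf("validation error: goal %s has zero total support",
                 as.character(goal)), call. = FALSE)
  acc <- 0
  for (es in rownames(G)) acc <- acc + g[[es]] * panel[[es]]$values
  grid_like(panel[[1L]], acc / sum(g))
}

#' Score all supported SDGs
#'
#' @param panel named list of normalised ES raster_grids.
#' @param G support matrix (default the shipped reconstruction).
#' @return named list of raster_grids, one per goal with positive support.
#' @export
sdg_scores <- function(panel, G = default_support_matrix()) {
  supported <- colnames(G)[colSums(G) > 0]
  skipped <- setdiff(colnames(G), supported)
  if (length(skipped))
    message("sdg_scores: ", length(skipped),
            " goal(s) with zero support excluded from scoring")
  out <- lapply(supported, function(j) sdg_goal_score(panel, G, j))
  names(out) <- supported
  out
}

#' Composite SDG index
#'
#' Unweighted arithmetic mean of the per-goal score surfaces over the m
#' supported goals (every goal and every ES counted equally), plus the
#' regional mean over valid cells.
#'
#' @param goal_scores named list of per-goal raster_grids from
#'   [sdg_scores()].
#' @return list with `grid` (raster_grid in [0, 1]), `regional_mean`, and
#'   `m` (number of goals averaged).
#' @export
sdg_composite <- function(goal_scores) {
  m <- length(goal_scores)
  if (m < 1L)
    stop("validation error: empty goal set", call. = FALSE)
  check_coregistered(goal_scores)
  acc <- 0
  for (g in goal_scores) acc <- acc + g$values
  comp <- grid_like(goal_scores[[1L]], acc / m)
  list(grid = comp,
       regional_mean = mean(comp$values[is.finite(comp$values)]),
       m = m)
}
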