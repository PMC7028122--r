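#' Geometry of the visual-search grid
#'
#' Builds the 7-row by 9-column grid of stimulus cells tiling the tablet
#' screen (26 cm wide, 17.3 cm tall, landscape), and converts each cell
#' centre to degrees of visual angle at the working viewing distance
#' (50 cm). The central cell (column 5, row 4) holds the reference image
#' and is never a target, so exactly 62 cells are schedulable.
#'
#' Locations are indexed 1-based, row-major from the top-left corner;
#' screen-centred x/y coordinates (cm) are stored alongside to avoid
#' ambiguity. Eccentricity is \code{atan(planar distance / viewing
#' distance)} in degrees.
#'
#' @param n_cols,n_rows grid dimensions.
#' @param screen_w,screen_h screen size in cm.
#' @param viewing_distance viewing distance in cm.
#' @return an object of class \code{search_grid}: a list with the geometry
#'   scalars and \code{cells}, a data.frame with one row per cell
#'   (\code{loc}, \code{col}, \code{row}, \code{x_cm}, \code{y_cm},
#'   \code{ecc_deg}, \code{is_center}).
#' @examples
#' g <- search_grid()
#' sum(!g$cells$is_center)          # 62 target locations
#' g$cells$ecc_deg[g$cells$is_center]  # 0
#' @export
search_grid <- function(n_cols = 9, n_rows = 7,
                        screen_w = 26, screen_h = 17.3,
                        viewing_distance = 50) {
  for (nm in c("n_cols", "n_rows", "screen_w", "screen_h",
               "viewing_distance"))
    assert_scalar_number(get(nm), nm, positive = TRUE)
  if (n_cols %% 2 == 0 || n_rows %% 2 == 0)
    stop("grid dimensions must be odd so a central reference cell exists",
         call. = FALSE)
  cw <- screen_w / n_cols
  ch <- screen_h / n_rows
  cells <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  cells <- cells[order(cells$row, cells$col), ]
  cells$loc <- seq_len(nrow(cells))
  cells$x_cm <- (cells$col - (n_cols + 1) / 2) * cw
  cells$y_cm <- ((n_rows + 1) / 2 - cells$row) * ch
  r <- sqrt(cells$x_cm^2 + cells$y_cm^2)
  cells$ecc_deg <- atan(r / viewing_distance) * 180 / pi
  cells$is_center <- cells$col == (n_cols + 1) / 2 &
    cells$row == (n_rows + 1) / 2
  rownames(cells) <- NULL
  structure(list(n_cols = n_cols, n_rows = n_rows,
                 screen_w = screen_w, screen_h = screen_h,
                 viewing_distance = viewing_distance,
                 cell_w = cw, cell_h = ch,
                 cells = cells[, c("loc", "col", "row", "x_cm", "y_cm",
                                   "ecc_deg", "is_center")]),
            class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf(paste0("<search_grid: %d x %d cells on %.3g x %.3g cm at ",
                     "%.3g cm, ecc up to %.2f deg>\n"),
              x$n_rows, x$n_cols, x$screen_w, x$screen_h,
              x$viewing_distance, max(x$cells$ecc_deg)))
  invisible(x)
}

#' Refined 22-location subset
#'
#' A documented, centre-symmetric layout of 22 target locations spanning
#' all eccentricity bands of the grid: 4 on the inner ring (orthogonal
#' neighbours of the centre), 8 at mid eccentricity (diagonal neighbours
#' and distance-2 orthogonals) and 10 on the outer edge (corners, edge
#' midpoints and one symmetric off-corner pair). The published deployment
#' used a 22-point subset whose exact membership was shown only graphically,
#' so this layout is a reconstruction, not canonical; any analysis accepts
#' an explicit location vector instead.
#'
#' @param grid a \code{search_grid} (must be the default 9 x 7 layout).
#' @return integer vector of 22 location indices.
#' @export
refined_subset <- function(grid = search_grid()) {
  if (grid$n_cols != 9 || grid$n_rows != 7)
    stop("the built-in refined subset is defined for the 9 x 7 grid only",
         call. = FALSE)
  pairs <- rbind(
    # inner ring (4)
    c(4, 4), c(6, 4), c(5, 3), c(5, 5),
    # mid band (8)
    c(4, 3), c(6, 3), c(4, 5), c(6, 5),
    c(3, 4), c(7, 4), c(5, 2), c(5, 6),
    # outer band (10)
    c(1, 1), c(9, 1), c(1, 7), c(9, 7),
    c(1, 4), c(9, 4), c(5, 1), c(5, 7),
    c(3, 1), c(7, 7))
  loc <- mapply(function(cc, rr) {
    grid$cells$loc[grid$cells$col == cc & grid$cells$row == rr]
  }, pairs[, 1], pairs[, 2])
  sort(as.integer(loc))
}

resolve_subset <- function(grid, subset) {
  cells <- grid$cells
  if (is.character(subset) && length(subset) == 1L) {
    subset <- switch(subset,
                     all = cells$loc[!cells$is_center],
                     refined = refined_subset(grid),
                     stop("'subset' must be \"all\", \"refined\" or a vector of location indices",
                          call. = FALSE))
  }
  subset <- as.integer(subset)
  if (anyDuplicated(subset))
    stop("'subset' contains duplicate locations", call. = FALSE)
  if (!all(subset %in% cells$loc))
    stop("'subset' contains unknown location indices", call. = FALSE)
  if (any(cells$is_center[match(subset, cells$loc)]))
    stop("the central reference cell cannot be a target location",
         call. = FALSE)
  subset
}

#' Randomised target-location schedule
#'
#' Each scheduled location appears exactly once; the order is a seeded
#' random permutation, re-randomised each time the test is run. The full
#' protocol covers all 62 non-centre cells; the refined protocol covers the
#' 22-location subset.
#'
#' @param grid a \code{search_grid}.
#' @param subset \code{"all"}, \code{"refined"}, or an integer vector of
#'   non-centre location indices.
#' @param seed integer seed for the permutation.
#' @return integer vector of location indices in presentation order.
#' @export
schedule_locations <- function(grid = search_grid(), subset = "all",
                               seed = NULL) {
  subset <- resolve_subset(grid, subset)
  with_seed(seed, sample(subset))
}

#' Median response time
#'
#' The search test's summary measure: the standard median (mean of the
#' central pair for even counts) of the per-location response times.
#'
#' @param rts numeric vector of positive response times (seconds).
#' @return scalar median in seconds.
#' @export
median_rt <- function(rts) {
  if (length(rts) == 0) stop("'rts' must be non-empty", call. = FALSE)
  if (!is.numeric(rts) || any(!is.finite(rts)) || any(rts <= 0))
    stop("'rts' must be positive finite response times", call. = FALSE)
  stats::median(rts)
}

#' Simulate one run of the visual-search test
#'
#' Schedules the target locations, then draws one response time per
#' location from the observer's eccentricity-dependent RT model, and
#' summarises the run by its median RT. Reproducible given \code{seed}.
#'
#' @param observer an \code{observer_model}.
#' @param grid a \code{search_grid}.
#' @param subset location subset passed to \code{\link{schedule_locations}}.
#' @param seed integer seed (drives both the schedule and the RT noise).
#' @param speed_factor multiplicative factor on the observer's mean RT curve
#'   (participant speed and between-run jitter).
#' @return an object of class \code{search_session}: \code{trials}
#'   (data.frame: trial, loc, col, row, ecc_deg, rt_s), \code{median_rt},
#'   \code{subset} and \code{seed}.
#' @export
run_search_session <- function(observer, grid = search_grid(),
                               subset = "all", seed = NULL,
                               speed_factor = 1) {
  if (!inherits(observer, "observer_model"))
    stop("'observer' must be an observer_model", call. = FALSE)
  assert_scalar_number(speed_factor, "speed_factor", positive = TRUE)
  subset <- resolve_subset(grid, subset)
  with_seed(seed, {
    order_loc <- sample(subset)
    idx <- match(order_loc, grid$cells$loc)
    ecc <- grid$cells$ecc_deg[idx]
    rt <- sample_rt(ecc, observer, speed_factor = speed_factor)
    trials <- data.frame(trial = seq_along(order_loc),
                         loc = order_loc,
                         col = grid$cells$col[idx],
                         row = grid$cells$row[idx],
                         ecc_deg = ecc,
                         rt_s = rt)
    structure(list(trials = trials,
                   median_rt = median_rt(rt),
                   subset = sort(subset),
                   seed = seed),
              class = "search_session")
  })
}

#' @export
print.search_session <- function(x, ...) {
  cat(sprintf("<search_session: %d locations, median RT %.3f s>\n",
              nrow(x$trials), x$median_rt))
  invisible(x)
}
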