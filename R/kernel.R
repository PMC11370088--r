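# Kernel utilization distributions on a planar grid, the href reference
# bandwidth, probability contours and volume-of-intersection overlap, plus
# the per-k state-stability analysis that ties the HMM and the kernels
# together.

#' Reference bandwidth (href) for a bivariate kernel UD
#'
#' The bivariate-normal reference rule used in home-range work:
#' `h = 0.5 * (sd(x) + sd(y)) * n^(-1/6)`.
#'
#' @param x,y planar coordinates (metres).
#' @return bandwidth h (same unit as the coordinates).
#' @export
href_bandwidth <- function(x, y) {
  0.5 * (stats::sd(x) + stats::sd(y)) * length(x)^(-1 / 6)
}

#' Kernel utilization distribution of a point set
#'
#' Bivariate Gaussian kernel density on a regular grid, normalized to
#' integrate to 1 over the grid. The default bandwidth is the href
#' reference rule. Coordinates must be planar metres (project first, e.g.
#' with [project_aeqd()]).
#'
#' @param x,y planar coordinates (metres), at least 5 points.
#' @param grid optional common grid, a list with `xg`, `yg` (cell-centre
#'   vectors) as produced by [make_ud_grid()]; when NULL a grid is built
#'   from the point extent.
#' @param grid_cells cells per axis when building a grid, default 200.
#' @param extent_padding fractional padding of the extent, default 0.1.
#' @param h bandwidth (metres); default [href_bandwidth()].
#' @return object of class `kernel_ud`: list with `xg`, `yg`, `z` (density
#'   matrix, `length(xg)` x `length(yg)`), `h`, `cell_area`, `n`.
#' @export
kernel_ud <- function(x, y, grid = NULL, grid_cells = 200,
                      extent_padding = 0.1, h = NULL) {
  n <- length(x)
  if (n < 5) stop("kernel_ud: need at least 5 points")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("kernel_ud: all points coincident; bandwidth undefined")
  if (is.null(h)) h <- href_bandwidth(x, y)
  if (h <= 0) stop("kernel_ud: non-positive bandwidth")
  if (is.null(grid))
    grid <- make_ud_grid(x, y, grid_cells, extent_padding, pad_abs = 3 * h)
  A <- outer(grid$xg, x, function(g, p) stats::dnorm(g, p, h))
  B <- outer(grid$yg, y, function(g, p) stats::dnorm(g, p, h))
  z <- (A %*% t(B)) / n
  cell_area <- diff(grid$xg[1:2]) * diff(grid$yg[1:2])
  z <- z / (sum(z) * cell_area)  # renormalize grid truncation
  structure(list(xg = grid$xg, yg = grid$yg, z = z, h = h,
                 cell_area = cell_area, n = n),
            class = "kernel_ud")
}

#' Build a common UD grid from a point extent
#'
#' @param x,y coordinates whose extent the grid must cover.
#' @param grid_cells cells per axis.
#' @param extent_padding fractional padding per side.
#' @param pad_abs additional absolute padding (metres), e.g. 3 bandwidths.
#' @return list with cell-centre vectors `xg`, `yg`.
#' @export
make_ud_grid <- function(x, y, grid_cells = 200, extent_padding = 0.1,
                         pad_abs = 0) {
  pad_x <- extent_padding * diff(range(x)) + pad_abs
  pad_y <- extent_padding * diff(range(y)) + pad_abs
  list(xg = seq(min(x) - pad_x, max(x) + pad_x, length.out = grid_cells),
       yg = seq(min(y) - pad_y, max(y) + pad_y, length.out = grid_cells))
}

#' Construct a UD directly from gridded densities
#'
#' Used for analytic reference distributions in tests and for reading UD
#' rasters back; densities are renormalized to integrate to 1.
#'
#' @param xg,yg cell-centre vectors.
#' @param z density matrix (`length(xg)` x `length(yg)`).
#' @return a `kernel_ud`.
#' @export
make_ud <- function(xg, yg, z) {
  cell_area <- diff(xg[1:2]) * diff(yg[1:2])
  z <- z / (sum(z) * cell_area)
  structure(list(xg = xg, yg = yg, z = z, h = NA_real_,
                 cell_area = cell_area, n = NA_integer_),
            class = "kernel_ud")
}

#' @export
print.kernel_ud <- function(x, ...) {
  cat(sprintf(
    "<kernel_ud> %d x %d grid, h = %s m, mass = %.4f\n",
    length(x$xg), length(x$yg),
    if (is.na(x$h)) "(given)" else sprintf("%.1f", x$h),
    sum(x$z) * x$cell_area))
  invisible(x)
}

#' Probability contour of a UD
#'
#' The p-contour is the smallest-density-threshold set holding at least a
#' fraction p of the mass (the conventional "50% kernel" at p = 0.5).
#'
#' @param ud a `kernel_ud`.
#' @param p contour mass, default 0.5.
#' @return list with `threshold` (density), `mass` (attained mass, >= p),
#'   `inside` (logical matrix), `area` (m^2 of the contour set).
#' @export
ud_contour <- function(ud, p = 0.5) {
  ord <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(ud$z[ord]) * ud$cell_area
  i <- which(cum >= p)[1]
  threshold <- ud$z[ord][i]
  inside <- ud$z >= threshold
  list(threshold = threshold, mass = sum(ud$z[inside]) * ud$cell_area,
       inside = inside, area = sum(inside) * ud$cell_area)
}

#' Volume-of-intersection overlap of two UDs
#'
#' `VI = sum_cells min(ud_a, ud_b) * cell_area`, the shared volume of two
#' utilization distributions on one grid; 1 for identical normalized UDs, 0
#' for disjoint supports.
#'
#' @param ud_a,ud_b `kernel_ud` objects on the identical grid.
#' @return VI in \[0, 1\].
#' @export
overlap_vi <- function(ud_a, ud_b) {
  if (length(ud_a$xg) != length(ud_b$xg) ||
      length(ud_a$yg) != length(ud_b$yg) ||
      any(ud_a$xg != ud_b$xg) || any(ud_a$yg != ud_b$yg))
    stop("overlap_vi: UDs are not on the same grid")
  sum(pmin(ud_a$z, ud_b$z)) * ud_a$cell_area
}

#' Stability of inferred behavioural states across sampling intervals
#'
#' For every k in the grid the trip is sub-sampled, a fresh 3-state HMM is
#' fitted on (speed, |angle|) with a shared seed policy, states are labelled
#' by speed, and the chosen state's positions are turned into a kernel UD on
#' one common planar grid. The VI overlap between every pair of intervals
#' quantifies how much the state's spatial picture drifts with k.
#'
#' @param trip a uniform 1-Hz `gps_path` (e.g. from [gen_trip()]).
#' @param k_grid sampling intervals (s).
#' @param state which state's UD to compare: `"forage"` (default), `"rest"`
#'   or `"commute"`.
#' @param seed seed shared by every per-k fit.
#' @param grid_cells,extent_padding common-grid geometry (see
#'   [make_ud_grid()]).
#' @param n_restarts EM restarts per k.
#' @param min_points smallest usable observation count per k, default 30.
#' @return object of class `overlap_curve`: list with `k`, `vi` (overlap
#'   matrix), `mean_overlap` (mean VI of each k against the others),
#'   `state_pct` (k x state percentage matrix), `models`, `failed_k`.
#' @export
state_stability_curve <- function(trip, k_grid, state = "forage", seed = 1,
                                  grid_cells = 200, extent_padding = 0.1,
                                  n_restarts = 10, min_points = 30) {
  stopifnot(inherits(trip, "gps_path"))
  ctr <- c(mean(trip$lon), mean(trip$lat))
  pr_all <- project_aeqd(trip$lon, trip$lat, center = ctr)
  grid <- make_ud_grid(pr_all$x, pr_all$y, grid_cells, extent_padding)
  nk <- length(k_grid)
  uds <- vector("list", nk)
  models <- vector("list", nk)
  pct <- matrix(NA_real_, nk, 3,
                dimnames = list(as.character(k_grid),
                                c("rest", "forage", "commute")))
  failed <- logical(nk)
  for (i in seq_len(nk)) {
    res <- tryCatch({
      sub <- subsample(trip, k_grid[i])
      obs <- hmm_observations(sub)
      if (nrow(obs) < min_points)
        stop("fewer than ", min_points, " points at k = ", k_grid[i])
      model <- fit_hmm(obs, n_states = 3, seed = seed,
                       n_restarts = n_restarts)
      labels <- suppressWarnings(label_states(model))
      st <- decode_states(model, obs)
      st_lab <- labels[st]
      for (lb in colnames(pct))
        pct[i, lb] <- 100 * mean(st_lab == lb)
      pick <- st_lab == state
      if (sum(pick) < 5) stop("fewer than 5 ", state, " points at k = ",
                              k_grid[i])
      pr <- project_aeqd(obs$lon[pick], obs$lat[pick], center = ctr)
      uds[[i]] <- kernel_ud(pr$x, pr$y, grid = grid)
      models[[i]] <- model
      TRUE
    }, error = function(e) {
      warning("state_stability_curve: k = ", k_grid[i], " failed: ",
              conditionMessage(e))
      FALSE
    })
    failed[i] <- !isTRUE(res)
  }
  vi <- matrix(NA_real_, nk, nk,
               dimnames = list(as.character(k_grid), as.character(k_grid)))
  for (i in seq_len(nk)) for (j in i:nk) {
    if (!failed[i] && !failed[j]) {
      vi[i, j] <- overlap_vi(uds[[i]], uds[[j]])
      vi[j, i] <- vi[i, j]
    }
  }
  mean_overlap <- vapply(seq_len(nk), function(i) {
    others <- vi[i, -i]
    if (all(is.na(others))) NA_real_ else mean(others, na.rm = TRUE)
  }, numeric(1))
  structure(list(k = k_grid, vi = vi, mean_overlap = mean_overlap,
                 state = state, state_pct = pct, models = models,
                 uds = uds, failed_k = k_grid[failed]),
            class = "overlap_curve")
}

#' @export
print.overlap_curve <- function(x, ...) {
  cat(sprintf("<overlap_curve> %s-state VI over %d intervals (k = %s s)\n",
              x$state, length(x$k),
              paste(range(x$k), collapse = "-")))
  if (length(x$failed_k)) cat("  failed k:", x$failed_k, "\n")
  print(round(stats::setNames(x$mean_overlap, x$k), 3))
  invisible(x)
}

#' Write a UD raster as plain text
#'
#' Header lines (ncols, nrows, cellsize, origin) followed by the density
#' matrix, space-delimited.
#'
#' @param ud a `kernel_ud`.
#' @param file output path.
#' @export
write_ud_raster <- function(ud, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(ud$xg)),
               sprintf("nrows %d", length(ud$yg)),
               sprintf("cellsize_x %.6f", diff(ud$xg[1:2])),
               sprintf("cellsize_y %.6f", diff(ud$yg[1:2])),
               sprintf("origin %.6f %.6f", ud$xg[1], ud$yg[1])), con)
  utils::write.table(ud$z, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
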