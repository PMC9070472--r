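#' Aggregate points to a fishnet grid of incident counts
#'
#' Lays a square grid over the study area's bounding box, anchored at the
#' box's minimum corner, and counts the points falling in each cell. Cells
#' are half-open \code{[x0, x0+s) x [y0, y0+s)}, so a point on a shared edge
#' belongs to the cell with the larger index (a point exactly on the grid's
#' outer maximum edge is kept in the last cell). When the study area has a
#' polygon, cells whose CENTERS fall outside it are dropped; remaining cells
#' keep their counts, including zeros (zero cells inform cold spots). When
#' the study area is a bare area, the grid covers its implicit square extent
#' (see [study_area()]) and all cells are kept; points outside the extent
#' are not counted.
#'
#' @param points two-column matrix or data.frame of planar coordinates (m).
#' @param study_area a [study_area()].
#' @param cell_size grid cell side (m).
#' @return a data.frame of class \code{gi_cells} with columns
#'   \code{cell_id}, \code{center_x}, \code{center_y}, \code{count};
#'   grid geometry in attributes \code{cell_size}, \code{nx}, \code{ny},
#'   \code{origin}.
#' @export
aggregate_to_grid <- function(points, study_area, cell_size) {
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be > 0", call. = FALSE)
  }
  xy <- as_xy(points, min_n = 1L)
  has_poly <- !is.null(study_area$polygon)
  bb <- study_area$bbox
  s <- cell_size
  nx <- max(1L, as.integer(ceiling((bb["xmax"] - bb["xmin"]) / s - 1e-12)))
  ny <- max(1L, as.integer(ceiling((bb["ymax"] - bb["ymin"]) / s - 1e-12)))
  ix <- floor((xy[, 1] - bb["xmin"]) / s)
  iy <- floor((xy[, 2] - bb["ymin"]) / s)
  # points exactly on the outer max edge stay in the last row/column
  ix[ix == nx & xy[, 1] <= bb["xmin"] + nx * s + 1e-9] <- nx - 1L
  iy[iy == ny & xy[, 2] <= bb["ymin"] + ny * s + 1e-9] <- ny - 1L
  inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  cell_of_point <- iy[inside] * nx + ix[inside] + 1L
  counts <- tabulate(cell_of_point, nbins = nx * ny)
  gx <- bb["xmin"] + (rep(seq_len(nx), times = ny) - 0.5) * s
  gy <- bb["ymin"] + (rep(seq_len(ny), each = nx) - 0.5) * s
  cells <- data.frame(cell_id = seq_len(nx * ny),
                      center_x = gx, center_y = gy, count = counts)
  if (has_poly) {
    keep <- points_in_polygon(cells$center_x, cells$center_y, study_area$polygon)
    cells <- cells[keep, , drop = FALSE]
  }
  if (nrow(cells) == 0) stop("no grid cells fall inside the study area", call. = FALSE)
  rownames(cells) <- NULL
  structure(cells, class = c("gi_cells", "data.frame"),
            cell_size = s, nx = nx, ny = ny,
            origin = c(bb["xmin"], bb["ymin"]))
}

#' Getis-Ord Gi* statistic on grid cells
#'
#' Computes the Gi* z-score for each cell with binary fixed-distance weights
#' on the cell centers: \code{w_ij = 1} iff the center distance is at most
#' \code{band}, INCLUDING the focal cell itself (\code{w_ii = 1}, the "star"
#' form). With \code{Xbar = sum(x)/n}, \code{S = sqrt(sum(x^2)/n - Xbar^2)},
#' \code{W_i = sum_j w_ij} and \code{W2_i = sum_j w_ij^2}:
#' \deqn{Gi*_i = \frac{\sum_j w_{ij} x_j - \bar X W_i}
#'   {S \sqrt{(n W2_i - W_i^2)/(n-1)}}}
#' A large positive z marks a hot spot (the cell and its neighbours have
#' high counts), a large negative z a cold spot. \code{p_raw} is the
#' two-sided standard-normal tail probability.
#'
#' @param cells a \code{gi_cells} table from [aggregate_to_grid()].
#' @param band fixed-distance neighbourhood radius (m); must be at least the
#'   nearest-neighbour spacing for every cell to have a neighbour (see
#'   [default_band()]) and small enough that no cell neighbours ALL cells
#'   (otherwise the variance term vanishes and an error is raised).
#' @return the cells with columns \code{gi_z} and \code{p_raw} added.
#' @export
gi_star <- function(cells, band) {
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (!is.finite(band) || band <= 0) stop("band must be > 0", call. = FALSE)
  x <- cells$count
  xbar <- mean(x)
  s2 <- mean(x^2) - xbar^2
  if (s2 <= 0) {
    stop("degenerate input: all cell counts are equal, Gi* variance is zero",
         call. = FALSE)
  }
  S <- sqrt(s2)
  d2 <- outer(cells$center_x, cells$center_x, "-")^2 +
    outer(cells$center_y, cells$center_y, "-")^2
  W <- (d2 <= band^2 + 1e-9) * 1
  Wi <- rowSums(W)
  W2i <- rowSums(W^2)
  denom_core <- (n * W2i - Wi^2) / (n - 1)
  if (any(denom_core <= 0)) {
    stop(paste0("band so large that some cell neighbours every cell ",
                "(W_i = n): Gi* denominator is zero; reduce the band"),
         call. = FALSE)
  }
  gi <- (as.vector(W %*% x) - xbar * Wi) / (S * sqrt(denom_core))
  cells$gi_z <- gi
  cells$p_raw <- 2 * pnorm(-abs(gi))
  cells
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment: sort p ascending, take
#' \code{adj_(i) = min over j >= i of p_(j) * n / j}, cap at 1, and map back
#' to the input order. Adjusted values are monotone non-decreasing in the
#' sorted order and never smaller than the raw values.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Assign signed confidence bins to Gi* cells
#'
#' Bins follow the hotspot-mapping convention: magnitude 3/2/1 for
#' FDR-adjusted p below 0.01/0.05/0.10 (99/95/90\% confidence), 0 for not
#' significant; the sign is the sign of the Gi* z-score (positive = hot
#' spot, negative = cold spot).
#'
#' @param cells a \code{gi_cells} table with \code{gi_z} and \code{p_adj}.
#' @param alpha_bins the three thresholds, descending (default
#'   \code{c(0.10, 0.05, 0.01)}).
#' @return the cells with an integer \code{bin} column in -3..3 added.
#' @export
assign_bins <- function(cells, alpha_bins = c(0.10, 0.05, 0.01)) {
  stopifnot(all(c("gi_z", "p_adj") %in% names(cells)))
  mag <- ifelse(cells$p_adj < alpha_bins[3], 3L,
         ifelse(cells$p_adj < alpha_bins[2], 2L,
         ifelse(cells$p_adj < alpha_bins[1], 1L, 0L)))
  cells$bin <- as.integer(mag * sign(cells$gi_z))
  cells
}

#' Default fixed-distance band for Gi*
#'
#' The maximum over cells of the distance to the nearest other cell center:
#' the smallest radius at which every cell has at least one neighbour
#' besides itself, guaranteeing a connected analysis.
#'
#' @param cells a \code{gi_cells} table (>= 2 cells).
#' @return band in metres.
#' @export
default_band <- function(cells) {
  if (nrow(cells) < 2) stop("need at least 2 cells", call. = FALSE)
  max(nn_distances(cells$center_x, cells$center_y))
}

#' Full hotspot analysis
#'
#' Convenience wrapper: aggregate points to a grid, compute Gi*, adjust the
#' p-values by Benjamini-Hochberg FDR, and assign signed confidence bins.
#' Scale defaults are explicit and logged: when only \code{band} is given,
#' \code{cell_size = band / 2}; when neither is given, the cell size is a
#' 1/30 of the larger bounding-box side and the band comes from
#' [default_band()].
#'
#' @inheritParams aggregate_to_grid
#' @param cell_size grid cell side (m), or \code{NULL} for the default.
#' @param band neighbourhood radius (m), or \code{NULL} for [default_band()];
#'   must be >= cell_size.
#' @param alpha_bins see [assign_bins()].
#' @return a \code{gi_cells} data.frame with \code{count, gi_z, p_raw, p_adj,
#'   bin}; the cell size and band used are attached as attributes.
#' @export
hotspot_analysis <- function(points, study_area, cell_size = NULL,
                             band = NULL, alpha_bins = c(0.10, 0.05, 0.01)) {
  if (is.null(cell_size)) {
    cell_size <- if (!is.null(band)) band / 2 else {
      bb <- study_area$bbox
      max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"]) / 30
    }
  }
  cells <- aggregate_to_grid(points, study_area, cell_size)
  if (is.null(band)) band <- default_band(cells)
  if (band < cell_size) {
    stop("band must be at least the cell size", call. = FALSE)
  }
  message(sprintf("hotspot: cell_size = %.6g m, band = %.6g m, %d cells",
                  cell_size, band, nrow(cells)))
  cells <- gi_star(cells, band)
  cells$p_adj <- bh_fdr(cells$p_raw)
  cells <- assign_bins(cells, alpha_bins)
  attr(cells, "band") <- band
  cells
}
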