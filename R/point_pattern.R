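# Standard error constant of the mean nearest-neighbour distance under
# complete spatial randomness (Clark & Evans 1954): SE = 0.26136 / sqrt(n^2/A).
CE_SE_CONST <- 0.26136

#' Mean nearest-neighbour distance
#'
#' Mean over all points of the Euclidean distance to the nearest OTHER
#' point. Coincident points are allowed (their nearest-neighbour distance is
#' 0). The scan is the plain O(n^2) reference computation, vectorised in
#' blocks.
#'
#' @param points a two-column matrix or data.frame of planar coordinates
#'   (metres); at least 2 rows.
#' @return mean nearest-neighbour distance in the coordinate unit.
#' @examples
#' mean_nn_distance(cbind(c(0, 7), c(0, 0)))  # 7
#' @export
mean_nn_distance <- function(points) {
  xy <- as_xy(points)
  mean(nn_distances(xy[, 1], xy[, 2]))
}

as_xy <- function(points, min_n = 2L) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two coordinate columns", call. = FALSE)
  if (nrow(points) < min_n) {
    stop(sprintf("need at least %d point%s", min_n, if (min_n > 1) "s" else ""),
         call. = FALSE)
  }
  if (any(!is.finite(points))) stop("coordinates must be finite", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

#' Expected mean nearest-neighbour distance under CSR
#'
#' Closed form \code{0.5 * sqrt(area / n)} for n points placed completely at
#' random over a region of the given area.
#'
#' @param n number of points.
#' @param area region area (m^2).
#' @return expected mean nearest-neighbour distance (m).
#' @examples
#' expected_mean_distance(531, 3198130000)
#' @export
expected_mean_distance <- function(n, area) {
  if (n < 1 || area <= 0) stop("need n >= 1 and area > 0", call. = FALSE)
  0.5 * sqrt(area / n)
}

#' Clark-Evans average nearest-neighbour analysis
#'
#' Classifies a planar point set as clustered, random or dispersed by
#' comparing the observed mean nearest-neighbour distance Do against its
#' expectation under complete spatial randomness, De = 0.5*sqrt(A/n), over
#' a DECLARED study area A. The ratio Rn = Do/De is < 1 for clustering,
#' about 1 for CSR, and > 1 (up to 2.149) for dispersion. The test statistic
#' is z = (Do - De)/SE with SE = 0.26136/sqrt(n^2/A); z is negative for
#' clustering (Do < De). The p-value is the two-sided standard-normal tail.
#' No edge correction is applied.
#'
#' The area is a required input and is never inferred from the points: Rn is
#' meaningless without a declared A, and reproducing a published analysis
#' requires the published area.
#'
#' @param points two-column matrix or data.frame of planar coordinates (m).
#' @param area declared study area (m^2), or a [study_area()].
#' @param alpha significance level for the pattern label (default 0.05).
#' @return an object of class \code{nna_result}: a list with \code{n},
#'   \code{area}, \code{observed_mean_distance}, \code{expected_mean_distance},
#'   \code{standard_error}, \code{rn}, \code{z_score}, \code{p_value},
#'   \code{pattern} (\code{clustered}/\code{random}/\code{dispersed}) and
#'   \code{alpha}.
#' @examples
#' set.seed(1)
#' pts <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
#' clark_evans(pts, area = 1e6)
#' @export
clark_evans <- function(points, area, alpha = 0.05) {
  if (inherits(area, "study_area")) area <- area$area
  if (!is.finite(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  xy <- as_xy(points)
  n <- nrow(xy)
  do_ <- mean_nn_distance(xy)
  de <- expected_mean_distance(n, area)
  se <- CE_SE_CONST / sqrt(n^2 / area)
  z <- (do_ - de) / se
  p <- 2 * pnorm(-abs(z))
  rn <- do_ / de
  pattern <- if (p < alpha && rn < 1) "clustered"
             else if (p < alpha && rn > 1) "dispersed"
             else "random"
  structure(list(n = n, area = area,
                 observed_mean_distance = do_,
                 expected_mean_distance = de,
                 standard_error = se,
                 rn = rn, z_score = z, p_value = p,
                 pattern = pattern, alpha = alpha),
            class = "nna_result")
}

#' @export
print.nna_result <- function(x, ...) {
  cat("Clark-Evans nearest-neighbour analysis\n")
  cat(sprintf("  n = %d points over %.6g m^2\n", x$n, x$area))
  cat(sprintf("  observed mean NN distance Do = %.4f m\n", x$observed_mean_distance))
  cat(sprintf("  expected mean NN distance De = %.4f m\n", x$expected_mean_distance))
  cat(sprintf("  Rn = %.6f, z = %.6f, p = %.4g\n", x$rn, x$z_score, x$p_value))
  cat(sprintf("  Pattern: %s (alpha = %g)\n",
              paste0(toupper(substring(x$pattern, 1, 1)), substring(x$pattern, 2)),
              x$alpha))
  invisible(x)
}

#' CSR calibration of the Clark-Evans test
#'
#' Simulates complete-spatial-randomness point sets of the given size over a
#' square region of the given area, runs [clark_evans()] on each, and
#' returns the per-simulation ratio, z-score and rejection indicator. Used
#' to verify that the normal approximation holds at the study's n: the mean
#' simulated Rn should be about 1 and the rejection rate about the nominal
#' alpha.
#'
#' @param n points per simulation (>= 10).
#' @param area region area (m^2).
#' @param n_sims number of simulations (>= 100, unless \code{n_sims = 1} for
#'   a determinism check).
#' @param seed integer seed.
#' @param alpha significance level for the rejection indicator.
#' @return a data.frame with columns \code{rn}, \code{z}, \code{reject}.
#' @export
csr_calibration <- function(n, area, n_sims = 1000L, seed = 1L, alpha = 0.05) {
  if (n < 10) stop("need n >= 10", call. = FALSE)
  set.seed(seed)
  side <- sqrt(area)
  res <- vapply(seq_len(n_sims), function(i) {
    pts <- cbind(runif(n, 0, side), runif(n, 0, side))
    ce <- clark_evans(pts, area, alpha = alpha)
    c(ce$rn, ce$z_score, as.numeric(ce$p_value < alpha))
  }, numeric(3))
  data.frame(rn = res[1, ], z = res[2, ], reject = res[3, ] == 1)
}
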