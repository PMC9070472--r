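#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the simulated study: the study region, the facility
#' point process, and the enrollee residence/choice/geocoding model. The
#' defaults emulate the motivating field study: 531 facilities over a
#' 3.19813e9 m^2 metropolitan area, 431 enrollees, a 300-500 m
#' landmark-proxy positional error on recorded residences, and a
#' distance-decay facility choice that yields high bypass rates.
#'
#' @param seed integer seed; the generator is deterministic given the seed.
#'   Facility coordinates are drawn first, then facility attributes, then
#'   enrollees (from an offset stream), so changing \code{n_enrollees} never
#'   perturbs the facility pattern.
#' @param area a [study_area()] (default: bare area of 3.19813e9 m^2, i.e. an
#'   implicit ~56.6 km square).
#' @param n_facilities number of facility points.
#' @param pattern facility point process: \code{"csr"} (homogeneous Poisson /
#'   complete spatial randomness, conditioned on n), \code{"thomas"}
#'   (cluster process: uniform parents, isotropic Gaussian offspring) or
#'   \code{"grid"} (square lattice, spacing \code{sqrt(area/n)}).
#' @param thomas_parents number of cluster parents (thomas only).
#' @param thomas_sd Gaussian scatter of offspring about their parent, metres.
#' @param n_enrollees number of enrollees.
#' @param decay_lambda distance-decay scale (metres) of facility choice:
#'   an enrollee at true residence r picks facility j with probability
#'   proportional to \code{attractiveness[j] * exp(-d(r, j) / decay_lambda)}.
#'   Small lambda means near-rational nearest-facility choosers; large
#'   lambda means distance-insensitive choice and hence more bypassing.
#' @param attractiveness optional positive weights, one per facility
#'   (default all 1).
#' @param jitter_min,jitter_max landmark-proxy displacement radius bounds
#'   (metres): the recorded residence is the true residence displaced by a
#'   uniform angle and a radius uniform on \code{[jitter_min, jitter_max]}.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(seed = 1L,
                             area = study_area(area = 3.19813e9),
                             n_facilities = 531L,
                             pattern = c("csr", "thomas", "grid"),
                             thomas_parents = 10L,
                             thomas_sd = 2000,
                             n_enrollees = 431L,
                             decay_lambda = 3000,
                             attractiveness = NULL,
                             jitter_min = 300,
                             jitter_max = 500) {
  pattern <- match.arg(pattern)
  if (!inherits(area, "study_area")) area <- study_area(area = area)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (n_facilities <= 0 || n_enrollees <= 0 || thomas_parents <= 0) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (!is.finite(decay_lambda) || decay_lambda <= 0) {
    stop("decay_lambda must be a positive distance in metres", call. = FALSE)
  }
  if (jitter_min < 0 || jitter_min > jitter_max) {
    stop("need 0 <= jitter_min <= jitter_max", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), area = area,
                 n_facilities = as.integer(n_facilities), pattern = pattern,
                 thomas_parents = as.integer(thomas_parents),
                 thomas_sd = thomas_sd,
                 n_enrollees = as.integer(n_enrollees),
                 decay_lambda = decay_lambda,
                 attractiveness = attractiveness,
                 jitter_min = jitter_min, jitter_max = jitter_max),
            class = "synthetic_config")
}

# Uniform points in the study region: uniform in the bounding box, with
# rejection against the polygon when one is present (rejection, not
# reflection, keeps the conditional distribution exactly uniform).
runif_region <- function(n, area) {
  bb <- area$bbox
  draw <- function(m) {
    cbind(runif(m, bb["xmin"], bb["xmax"]), runif(m, bb["ymin"], bb["ymax"]))
  }
  if (is.null(area$polygon)) {
    xy <- draw(n)
  } else {
    xy <- matrix(numeric(0), ncol = 2)
    while (nrow(xy) < n) {
      cand <- draw(max(2L * (n - nrow(xy)), 16L))
      keep <- points_in_polygon(cand[, 1], cand[, 2], area$polygon)
      xy <- rbind(xy, cand[keep, , drop = FALSE])
    }
    xy <- xy[seq_len(n), , drop = FALSE]
  }
  colnames(xy) <- c("x", "y")
  xy
}

in_region <- function(x, y, area) {
  bb <- area$bbox
  ok <- x >= bb["xmin"] & x <= bb["xmax"] & y >= bb["ymin"] & y <= bb["ymax"]
  if (!is.null(area$polygon)) {
    ok[ok] <- points_in_polygon(x[ok], y[ok], area$polygon)
  }
  ok
}

#' Generate a synthetic facility table
#'
#' Draws \code{n_facilities} points from the configured point process
#' (\code{csr}, \code{thomas} or \code{grid}) inside the study region, then
#' assigns attributes: care level drawn with probabilities matching the
#' field study's level mix (42\% primary, 58\% secondary, a handful
#' tertiary), accreditation for secondary/tertiary facilities only (56\%
#' of them, the study's observed accreditation share), and an
#' administrative-area label from an 11-band partition of the region.
#'
#' For the thomas pattern, offspring are scattered isotropically
#' (\code{sd = thomas_sd}) around uniform parents and clipped to the region
#' by rejection; exactly \code{n_facilities} points are returned and the
#' parent coordinates are attached as \code{attr(, "parents")}.
#'
#' @param config a [synthetic_config()].
#' @return a validated facility data.frame (see [read_facilities()]).
#' @export
gen_facilities <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_facilities
  area <- config$area
  parents <- NULL
  xy <- switch(config$pattern,
    csr = runif_region(n, area),
    thomas = {
      parents <- runif_region(config$thomas_parents, area)
      pts <- matrix(numeric(0), ncol = 2)
      while (nrow(pts) < n) {
        m <- max(2L * (n - nrow(pts)), 16L)
        pid <- sample.int(nrow(parents), m, replace = TRUE)
        cand <- parents[pid, , drop = FALSE] +
          cbind(rnorm(m, 0, config$thomas_sd), rnorm(m, 0, config$thomas_sd))
        keep <- in_region(cand[, 1], cand[, 2], area)
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts[seq_len(n), , drop = FALSE]
    },
    grid = {
      bb <- area$bbox
      s <- sqrt(area$area / n)
      gx <- seq(bb["xmin"] + s / 2, bb["xmax"], by = s)
      gy <- seq(bb["ymin"] + s / 2, bb["ymax"], by = s)
      lattice <- as.matrix(expand.grid(x = gx, y = gy))
      keep <- in_region(lattice[, 1], lattice[, 2], area)
      lattice <- lattice[keep, , drop = FALSE]
      if (nrow(lattice) < n) {
        stop(sprintf(
          "grid pattern: only %d lattice points of spacing %.3g fit inside the area; cannot place %d",
          nrow(lattice), s, n), call. = FALSE)
      }
      lattice[seq_len(n), , drop = FALSE]
    })
  colnames(xy) <- c("x", "y")
  level <- sample(FACILITY_LEVELS, n, replace = TRUE,
                  prob = c(0.42, 0.578, 0.002))
  accreditable <- level %in% c("secondary", "tertiary")
  nhis <- rep(FALSE, n)
  nhis[accreditable] <- runif(sum(accreditable)) < 0.56
  bb <- area$bbox
  band <- pmin(11L, 1L + floor(11 * (xy[, 1] - bb["xmin"]) /
                                 (bb["xmax"] - bb["xmin"])))
  out <- data.frame(
    id = sprintf("F%04d", seq_len(n)),
    name = sprintf("Facility %04d", seq_len(n)),
    level = level,
    nhis_accredited = nhis,
    lga = sprintf("LGA%02d", band),
    x = xy[, 1], y = xy[, 2],
    stringsAsFactors = FALSE
  )
  if (!is.null(parents)) attr(out, "parents") <- parents
  out
}

#' Generate synthetic enrollees with facility choice and geocoding error
#'
#' True residences are uniform in the study region. Each enrollee chooses
#' the facility they use with probability proportional to
#' \code{attractiveness * exp(-distance / decay_lambda)}, evaluated at the
#' TRUE residence; when the facility table carries accreditation flags and
#' any facility is accredited, choice is restricted to accredited
#' facilities (scheme enrollees can only use accredited providers). The
#' recorded coordinates are then the true residence displaced by a uniform
#' angle and a radius uniform on \code{[jitter_min, jitter_max]},
#' emulating landmark-proxy geocoding. Bypassing measured downstream on
#' the recorded coordinates therefore mixes genuine non-nearest choice
#' with measurement-driven apparent bypassing.
#'
#' The true residences are attached as \code{attr(, "true_xy")} so tests
#' can measure the displacement directly.
#'
#' @param config a [synthetic_config()].
#' @param facilities a facility table (typically from [gen_facilities()]).
#' @return a validated enrollee data.frame (see [read_enrollees()]).
#' @export
gen_enrollees <- function(config, facilities) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(facilities) == 0) stop("facility table is empty", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- config$n_enrollees
  choice <- facilities
  a <- config$attractiveness %||% rep(1, nrow(facilities))
  if (length(a) != nrow(facilities) || any(a <= 0)) {
    stop("attractiveness must be one positive weight per facility", call. = FALSE)
  }
  if ("nhis_accredited" %in% names(facilities) && any(facilities$nhis_accredited)) {
    keep <- facilities$nhis_accredited
    choice <- facilities[keep, , drop = FALSE]
    a <- a[keep]
  }
  true_xy <- runif_region(n, config$area)
  d <- sqrt(outer(true_xy[, 1], choice$x, "-")^2 +
              outer(true_xy[, 2], choice$y, "-")^2)
  # log weights, shifted per enrollee before exponentiation so tiny decay
  # scales do not underflow every weight to zero
  logw <- sweep(-d / config$decay_lambda, 2, log(a), "+")
  used <- vapply(seq_len(n), function(i) {
    w <- exp(logw[i, ] - max(logw[i, ]))
    sample(choice$id, 1L, prob = w)
  }, character(1))
  theta <- runif(n, 0, 2 * pi)
  r <- runif(n, config$jitter_min, config$jitter_max)
  out <- data.frame(
    id = sprintf("E%04d", seq_len(n)),
    x = true_xy[, 1] + r * cos(theta),
    y = true_xy[, 2] + r * sin(theta),
    used_facility_id = used,
    stringsAsFactors = FALSE
  )
  attr(out, "true_xy") <- true_xy
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper drawing facilities then enrollees from one
#' configuration.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements \code{facilities}, \code{enrollees} and
#'   \code{config}.
#' @export
simulate_dataset <- function(config) {
  facilities <- gen_facilities(config)
  enrollees <- gen_enrollees(config, facilities)
  list(facilities = facilities, enrollees = enrollees, config = config)
}
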