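# Independent brute-force oracles and printed-table fixtures used across the
# test files. All oracles are written as plain double loops, independent of
# the package's vectorised implementations.

# Mean nearest-neighbour distance, plain double loop.
oracle_mean_nn <- function(x, y) {
  n <- length(x)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}

# Nearest facility per enrollee, plain O(n*m) double loop. Ties resolved to
# the lexicographically smallest id, as documented.
oracle_nearest <- function(ex, ey, fx, fy, fid, tol = 1e-6) {
  n <- length(ex)
  out_id <- character(n); out_d <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((ex[i] - fx)^2 + (ey[i] - fy)^2)
    m <- min(d)
    out_id[i] <- min(fid[d <= m + tol])
    out_d[i] <- m
  }
  list(id = out_id, dist = out_d)
}

# Point-in-cell counts by explicit per-point comparison against half-open
# cell bounds.
oracle_grid_counts <- function(px, py, origin, s, nx, ny) {
  counts <- matrix(0L, nrow = ny, ncol = nx)
  for (k in seq_along(px)) {
    placed <- FALSE
    for (iy in seq_len(ny)) {
      for (ix in seq_len(nx)) {
        x0 <- origin[1] + (ix - 1) * s; y0 <- origin[2] + (iy - 1) * s
        hi_x <- if (ix == nx) px[k] <= x0 + s + 1e-9 else px[k] < x0 + s
        hi_y <- if (iy == ny) py[k] <= y0 + s + 1e-9 else py[k] < y0 + s
        if (px[k] >= x0 && hi_x && py[k] >= y0 && hi_y) {
          counts[iy, ix] <- counts[iy, ix] + 1L
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
  }
  as.integer(t(counts))  # row-major (x fastest), matching cell_id order
}

# Gi* for one focal cell evaluated directly from the formula definition.
oracle_gi_one <- function(cx, cy, counts, band, i) {
  n <- length(counts)
  xbar <- sum(counts) / n
  S <- sqrt(sum(counts^2) / n - xbar^2)
  w <- as.numeric(sqrt((cx - cx[i])^2 + (cy - cy[i])^2) <= band + 1e-9)
  Wi <- sum(w); W2i <- sum(w^2)
  (sum(w * counts) - xbar * Wi) / (S * sqrt((n * W2i - Wi^2) / (n - 1)))
}

# ---- printed-table fixtures -------------------------------------------------

# Administrative-area summary: population, facility counts by level,
# accredited count, enrollees; urban core vs semiurban ring.
lga_fixture <- function() {
  data.frame(
    name = c("IBN", "IBNE", "IBNW", "IBSE", "IBSW",
             "Akinyele", "Egbeda", "Ido", "Lagelu", "Oluyole", "Ona-Ara"),
    stratum = c(rep("urban", 5), rep("semiurban", 6)),
    population = c(856988, 330399, 152834, 266457, 283098,
                   211359, 319388, 117129, 147957, 734377, 118465),
    facilities_primary = c(24, 13, 9, 15, 23, 36, 34, 18, 19, 26, 29),
    facilities_secondary = c(63, 36, 27, 14, 79, 10, 42, 27, 10, 12, 24),
    facilities_tertiary = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    nhis_facilities = c(38, 31, 22, 7, 65, 3, 9, 11, 6, 0, 0),
    enrollees = c(42429, 12792, 23593, 769, 23730, 204, 6857, 1188, 559, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Published bypassing counts by patronised facility: (bypassed, non-bypassed).
bypass_fixture <- function() {
  data.frame(
    facility = c("Teju", "St. Mary", "St. Marello", "St. Dominic",
                 "Cottage Police Clinic", "Lafia", "LAD", "Jericho",
                 "Immaculate", "Doctor's Polyclinic", "Chrisbo"),
    n_bypassed = c(59, 59, 29, 30, 39, 63, 39, 14, 50, 10, 13),
    n_non = c(1, 0, 0, 7, 2, 0, 9, 0, 0, 5, 2),
    stringsAsFactors = FALSE
  )
}

# Build an assignments table realising given per-facility bypass counts.
assignments_from_counts <- function(counts) {
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    np <- counts$n_bypassed[i] + counts$n_non[i]
    data.frame(
      enrollee_id = sprintf("%s-%03d", counts$facility[i], seq_len(np)),
      nearest_facility_id = "N",
      nearest_distance = 0,
      used_facility_id = counts$facility[i],
      used_distance = 0,
      bypassed = rep(c(TRUE, FALSE), c(counts$n_bypassed[i], counts$n_non[i])),
      stringsAsFactors = FALSE
    )
  }))
  class(rows) <- c("assignments", "data.frame")
  rows
}

# Published shortest/longest distance travelled (km) by patronised facility.
distance_fixture <- function() {
  data.frame(
    facility = c("Chrisbo", "Doctors Polyclinic", "Immaculate", "Jericho",
                 "Lad", "Lafia", "Police Cottage", "St. Marello Catholic",
                 "St. Mary Catholic", "St. Dominic", "Teju"),
    shortest_km = c(1.095, 1.021, 1.141, 0.763, 0.513, 1.157, 0.833,
                    1.932, 1.752, 0.978, 0.866),
    longest_km = c(2.732, 3.731, 7.617, 3.805, 6.062, 7.329, 5.709,
                   8.595, 7.234, 6.156, 6.089),
    stringsAsFactors = FALSE
  )
}

# Assignments with two patrons per facility sitting exactly at the published
# shortest and longest distances.
assignments_from_distances <- function(tab) {
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(
      enrollee_id = sprintf("%s-%d", tab$facility[i], 1:2),
      nearest_facility_id = "N",
      nearest_distance = 0,
      used_facility_id = tab$facility[i],
      used_distance = c(tab$shortest_km[i], tab$longest_km[i]) * 1000,
      bypassed = TRUE,
      stringsAsFactors = FALSE
    )
  }))
  class(rows) <- c("assignments", "data.frame")
  rows
}

# Small random facility/enrollee tables for round-trip and oracle tests.
random_facilities <- function(n, seed = 1, side = 1000) {
  set.seed(seed)
  data.frame(
    id = sprintf("F%03d", sample(seq_len(10 * n), n)),
    name = sprintf("Fac %d", seq_len(n)),
    level = sample(c("primary", "secondary", "tertiary"), n, replace = TRUE),
    nhis_accredited = sample(c(TRUE, FALSE), n, replace = TRUE),
    lga = sample(sprintf("LGA%02d", 1:5), n, replace = TRUE),
    x = runif(n, 0, side), y = runif(n, 0, side),
    stringsAsFactors = FALSE
  )
}

random_enrollees <- function(n, facility_ids, seed = 2, side = 1000) {
  set.seed(seed)
  data.frame(
    id = sprintf("E%03d", seq_len(n)),
    x = runif(n, 0, side), y = runif(n, 0, side),
    used_facility_id = sample(facility_ids, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
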