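make_fac <- function(ids, x, y, accredited = TRUE) {
  data.frame(id = ids, name = ids, level = "secondary",
             nhis_accredited = accredited, lga = "L", x = x, y = y,
             stringsAsFactors = FALSE)
}
make_enr <- function(ids, x, y, used) {
  data.frame(id = ids, x = x, y = y, used_facility_id = used,
             stringsAsFactors = FALSE)
}

test_that("assignment hand cases: patron of the only/far facility", {
  fac <- make_fac("F1", 3, 0)
  enr <- make_enr("E1", 0, 0, "F1")
  a <- assign_nearest(enr, fac)
  expect_identical(a$nearest_facility_id, "F1")
  expect_false(a$bypassed)
  expect_equal(a$nearest_distance, a$used_distance)

  fac2 <- make_fac(c("F1", "F2"), c(3, 4), c(0, 0))
  a2 <- assign_nearest(make_enr("E1", 0, 0, "F2"), fac2)
  expect_true(a2$bypassed)
  expect_equal(a2$nearest_distance, 3)
  expect_equal(a2$used_distance, 4)
  expect_identical(a2$nearest_facility_id, "F1")
})

test_that("co-nearest ties are not bypassing and report the smallest id", {
  fac <- make_fac(c("FB", "FA"), c(1, -1), c(0, 0))
  a <- assign_nearest(make_enr("E1", 0, 0, "FB"), fac)
  expect_identical(a$nearest_facility_id, "FA")  # lexicographic tie-break
  expect_false(a$bypassed)                        # FB is co-nearest
  expect_equal(a$nearest_distance, a$used_distance)
})

test_that("assignment errors are informative", {
  fac <- make_fac("F1", 0, 0, accredited = FALSE)
  enr <- make_enr("E9", 1, 1, "F1")
  expect_error(assign_nearest(enr, fac), "accreditation")
  expect_error(assign_nearest(make_enr("E9", 1, 1, "NOPE"),
                              make_fac("F1", 0, 0)), "E9")
})

test_that("assignments match a brute-force O(n*m) scan on random instances", {
  for (seed in 1:5) {
    fac <- random_facilities(30, seed = seed)
    fac$nhis_accredited <- TRUE
    enr <- random_enrollees(300, fac$id, seed = seed + 100)
    a <- assign_nearest(enr, fac)
    o <- oracle_nearest(enr$x, enr$y, fac$x, fac$y, fac$id)
    expect_identical(a$nearest_facility_id, o$id)
    expect_equal(a$nearest_distance, o$dist, tolerance = 1e-12)
    expect_true(all(a$nearest_distance <= a$used_distance + 1e-6))
    expect_true(all(a$used_distance[!a$bypassed] -
                      a$nearest_distance[!a$bypassed] <= 1e-6))
  }
})

test_that("hub lines carry consistent geometry and conserve counts", {
  dat <- simulate_dataset(synthetic_config(seed = 4, n_facilities = 60,
                                           n_enrollees = 80))
  a <- assign_nearest(dat$enrollees, dat$facilities)
  for (w in c("nearest", "used")) {
    hl <- hub_lines(a, dat$enrollees, dat$facilities, w)
    expect_equal(nrow(hl), nrow(dat$enrollees))
    len <- sqrt((hl$x1 - hl$x0)^2 + (hl$y1 - hl$y0)^2)
    expect_equal(hl$distance_m, len, tolerance = 1e-6)
  }
  # GeoJSON output: LineString features, one per enrollee; empty in = empty out
  p <- tempfile(fileext = ".geojson")
  hl <- hub_lines(a, dat$enrollees, dat$facilities, "used")
  write_geojson(hl, p)
  fc <- jsonlite::read_json(p)
  expect_length(fc$features, nrow(dat$enrollees))
  expect_identical(fc$features[[1]]$geometry$type, "LineString")
  write_geojson(hl[0, ], p)
  expect_length(jsonlite::read_json(p)$features, 0)
})

test_that("bypass_table reproduces printed percentages and conserves counts", {
  tab <- bypass_table(assignments_from_counts(bypass_fixture()))
  total <- tab[tab$facility_id == "Total", ]
  expect_equal(total$n_patrons, 431)
  expect_equal(total$pct_bypassed, 94.0)
  expect_equal(total$pct_non_bypassed, 6.0)
  expect_equal(tab$pct_bypassed[tab$facility_id == "Teju"], 98.3)
  expect_equal(tab$pct_bypassed[tab$facility_id == "St. Dominic"], 81.1)
  expect_equal(tab$pct_bypassed[tab$facility_id == "Doctor's Polyclinic"], 66.7)
  body <- tab[tab$facility_id != "Total", ]
  expect_equal(body$n_bypassed + body$n_non_bypassed, body$n_patrons)
  expect_equal(sum(body$n_patrons), total$n_patrons)
  expect_equal(sum(body$n_bypassed), total$n_bypassed)
})

test_that("no bypassing when everyone uses their nearest facility", {
  fac <- make_fac(c("F1", "F2"), c(0, 100), c(0, 0))
  enr <- make_enr(c("E1", "E2"), c(1, 99), c(0, 0), c("F1", "F2"))
  tab <- bypass_table(assign_nearest(enr, fac))
  expect_true(all(tab$pct_bypassed == 0))
  expect_true(all(tab$pct_non_bypassed == 100))
})

test_that("distance_summary reproduces printed column means and a group-scan oracle", {
  ds <- distance_summary(assignments_from_distances(distance_fixture()))
  avg <- ds[ds$facility_id == "Average", ]
  expect_equal(avg$shortest_km, 1.096)
  expect_equal(avg$longest_km, 5.914)
  expect_true(all(ds$shortest_km <= ds$longest_km))

  # single facility, single patron at 2 km
  one <- structure(data.frame(
    enrollee_id = "E1", nearest_facility_id = "F1", nearest_distance = 500,
    used_facility_id = "F1", used_distance = 2000, bypassed = TRUE,
    stringsAsFactors = FALSE), class = c("assignments", "data.frame"))
  ds1 <- distance_summary(one)
  expect_equal(ds1$shortest_km, c(2, 2))
  expect_equal(ds1$longest_km, c(2, 2))

  # random data vs an explicit per-group min/max scan
  dat <- simulate_dataset(synthetic_config(seed = 14, n_facilities = 80,
                                           n_enrollees = 200))
  a <- assign_nearest(dat$enrollees, dat$facilities)
  ds2 <- distance_summary(a)
  body <- ds2[ds2$facility_id != "Average", ]
  for (i in seq_len(nrow(body))) {
    dd <- a$used_distance[a$used_facility_id == body$facility_id[i]]
    expect_equal(body$shortest_km[i], round_half_up(min(dd) / 1000, 3))
    expect_equal(body$longest_km[i], round_half_up(max(dd) / 1000, 3))
  }
  expect_equal(ds2$shortest_km[nrow(ds2)],
               round_half_up(mean(body$shortest_km), 3))
})
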