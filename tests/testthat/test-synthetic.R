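test_that("the generator is deterministic in the seed and sensitive to it", {
  cfg <- synthetic_config(seed = 42, n_facilities = 120, n_enrollees = 60)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$facilities, d2$facilities)
  expect_identical(d1$enrollees, d2$enrollees)
  d3 <- simulate_dataset(synthetic_config(seed = 43, n_facilities = 120,
                                          n_enrollees = 60))
  expect_false(identical(d1$facilities$x, d3$facilities$x))
})

test_that("changing the enrollee count never perturbs facility coordinates", {
  f1 <- simulate_dataset(synthetic_config(seed = 5, n_facilities = 80,
                                          n_enrollees = 20))$facilities
  f2 <- simulate_dataset(synthetic_config(seed = 5, n_facilities = 80,
                                          n_enrollees = 200))$facilities
  expect_identical(f1, f2)
})

test_that("grid pattern places points on the exact lattice", {
  cfg <- synthetic_config(seed = 1, area = study_area(area = 1),
                          n_facilities = 4, pattern = "grid",
                          jitter_min = 0, jitter_max = 0)
  fac <- gen_facilities(cfg)
  expect_equal(nrow(fac), 4)
  # spacing s = sqrt(1/4) = 0.5; every nearest-neighbour distance equals s
  nn <- geoaccess:::nn_distances(fac$x, fac$y)
  expect_equal(nn, rep(0.5, 4), tolerance = 1e-12)
  expect_setequal(round(fac$x, 12), c(0.25, 0.75))
  # a non-square count that does not fit the lattice errors out
  cfg5 <- synthetic_config(seed = 1, area = study_area(area = 1),
                           n_facilities = 5, pattern = "grid")
  expect_error(gen_facilities(cfg5), "grid")
})

test_that("csr points are uniform across quadrats (chi-square, 100 seeds)", {
  rejected <- 0L
  for (seed in 1:100) {
    cfg <- synthetic_config(seed = seed, n_facilities = 2000)
    fac <- gen_facilities(cfg)
    side <- sqrt(cfg$area$area)
    qx <- pmin(4L, floor(5 * fac$x / side)); qy <- pmin(4L, floor(5 * fac$y / side))
    counts <- tabulate(qy * 5L + qx + 1L, nbins = 25L)
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 5L)  # uniformity not rejected in >= 95% of seeds
})

test_that("landmark-proxy jitter has the configured radius distribution", {
  cfg <- synthetic_config(seed = 3, n_facilities = 50, n_enrollees = 5000)
  dat <- simulate_dataset(cfg)
  true_xy <- attr(dat$enrollees, "true_xy")
  r <- sqrt((dat$enrollees$x - true_xy[, 1])^2 +
              (dat$enrollees$y - true_xy[, 2])^2)
  expect_true(all(r >= 300 - 1e-9 & r <= 500 + 1e-9))
  # uniform on [300, 500]: mean 400, se of the mean ~ 0.8 m at n = 5000
  expect_lt(abs(mean(r) - 400), 5)
})

test_that("facility choice obeys the distance-decay limits", {
  # lambda -> 0: (almost) everyone picks the facility nearest their TRUE home
  cfg <- synthetic_config(seed = 9, n_facilities = 100, n_enrollees = 400,
                          decay_lambda = 1)
  dat <- simulate_dataset(cfg)
  acc <- dat$facilities[dat$facilities$nhis_accredited, ]
  true_xy <- attr(dat$enrollees, "true_xy")
  near <- oracle_nearest(true_xy[, 1], true_xy[, 2], acc$x, acc$y, acc$id)
  expect_gte(mean(dat$enrollees$used_facility_id == near$id), 0.99)

  # one-hot attractiveness with a huge decay scale: everyone uses that facility
  target <- acc$id[1]
  a <- ifelse(dat$facilities$id == target, 1, 1e-12)
  cfg2 <- synthetic_config(seed = 9, n_facilities = 100, n_enrollees = 400,
                           decay_lambda = 1e9, attractiveness = a)
  enr2 <- gen_enrollees(cfg2, dat$facilities)
  expect_true(all(enr2$used_facility_id == target))
})

test_that("generator and Clark-Evans statistic jointly recover each regime", {
  for (seed in 1:3) {
    area <- study_area(area = 3.19813e9)
    csr <- gen_facilities(synthetic_config(seed = seed, n_facilities = 500,
                                           pattern = "csr"))
    th <- gen_facilities(synthetic_config(seed = seed, n_facilities = 500,
                                          pattern = "thomas"))
    gr <- gen_facilities(synthetic_config(seed = seed, n_facilities = 484,
                                          pattern = "grid"))
    expect_lt(abs(clark_evans(csr, area)$rn - 1), 0.1)
    expect_lt(clark_evans(th, area)$rn, 1)
    expect_gt(clark_evans(gr, area)$rn, 1.5)
  }
})

test_that("bypass rate rises with the decay scale and falls away without jitter", {
  lambdas <- c(300, 3000, 30000)
  rates <- sapply(lambdas, function(lam) {
    mean(sapply(1:20, function(seed) {
      dat <- simulate_dataset(synthetic_config(
        seed = seed, n_facilities = 150, n_enrollees = 150,
        decay_lambda = lam))
      a <- assign_nearest(dat$enrollees, dat$facilities)
      mean(a$bypassed)
    }))
  })
  expect_true(all(diff(rates) >= 0))

  # near-rational choosers: zero jitter kills bypassing, 300-500 m jitter
  # keeps apparent bypassing alive
  zero <- numeric(10); jit <- numeric(10)
  for (seed in 1:10) {
    d0 <- simulate_dataset(synthetic_config(
      seed = seed, n_facilities = 150, n_enrollees = 150,
      decay_lambda = 1, jitter_min = 0, jitter_max = 0))
    zero[seed] <- mean(assign_nearest(d0$enrollees, d0$facilities)$bypassed)
    d1 <- simulate_dataset(synthetic_config(
      seed = seed, n_facilities = 150, n_enrollees = 150, decay_lambda = 1))
    jit[seed] <- mean(assign_nearest(d1$enrollees, d1$facilities)$bypassed)
  }
  expect_lt(mean(zero), 0.02)
  expect_gt(mean(jit), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(decay_lambda = 0), "decay_lambda")
  expect_error(synthetic_config(jitter_min = 600, jitter_max = 500), "jitter")
  expect_error(synthetic_config(n_facilities = 0), "positive")
})
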