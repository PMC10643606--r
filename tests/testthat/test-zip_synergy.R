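test_that("plate normalization maps controls to the cytotoxicity anchors", {
  raw <- matrix(c(1000, 600, 200), 3, 1,
                dimnames = list(c("0", "1", "3"), "0"))
  dm <- normalize_plate(raw, vehicle_wells = c(990, 1010),
                        kill_wells = c(195, 205),
                        doses_row = c(0, 1, 3), doses_col = 0)
  expect_equal(unname(dm$response[, 1]), c(0, 0.5, 1))
  expect_error(normalize_plate(raw, vehicle_wells = 100, kill_wells = 500,
                               doses_row = c(0, 1, 3), doses_col = 0),
               "control inversion")
  # replicate stacks are averaged
  arr <- array(rep(c(1000, 600, 200), 2), dim = c(3, 1, 2),
               dimnames = list(c("0", "1", "3"), "0", NULL))
  dm2 <- normalize_plate(arr, 1000, 200, c(0, 1, 3), 0)
  expect_equal(unname(dm2$response[, 1]), c(0, 0.5, 1))
})

test_that("4PL fitting recovers noise-free parameters and flags flat curves", {
  d <- 0.1 * 3^(0:8)
  truth <- c(lo = 0.05, hi = 0.8, ec50 = 2, hill = 1.5)
  y <- truth["lo"] + (truth["hi"] - truth["lo"]) /
    (1 + exp(-truth["hill"] * (log(d) - log(truth["ec50"]))))
  f <- fit_4pl(d, y)
  expect_false(f$flat)
  expect_lt(abs(f$min - truth["lo"]), 1e-4)
  expect_lt(abs(f$max - truth["hi"]), 1e-4 * truth["hi"])
  expect_lt(abs(f$ec50 / truth["ec50"] - 1), 1e-4)
  expect_lt(abs(f$hill / truth["hill"] - 1), 1e-4)
  # flat response
  ff <- fit_4pl(d, rep(0.2, 9))
  expect_true(ff$flat)
  expect_equal(ff$min, 0.2)
  # monotone-decreasing cytotoxicity (wrong orientation): flat fallback
  fd <- fit_4pl(d, seq(0.9, 0.1, length.out = 9))
  expect_true(fd$flat)
})

test_that("ZIP delta is zero on an additive surface and matches hand Bliss arithmetic", {
  c1 <- c(0, 0.5, 1, 1.3); c2 <- c(0, 0.6, 2, 1.1)
  dm <- simulate_dose_matrix(c1, c2, delta0 = 0, noise_sd = 0)
  ss <- zip_delta(dm)
  expect_lt(max(abs(ss$delta), na.rm = TRUE), 1e-6)
  expect_lt(abs(ss$max_window_score), 1e-6)

  # constant monotherapy cytotoxicity 0.5 each: Bliss expectation 0.75;
  # observed 0.9 -> delta = 0.15 -> 15 on the percent scale
  resp <- matrix(0.9, 5, 5)
  resp[1, ] <- 0.5; resp[, 1] <- 0.5; resp[1, 1] <- 0
  dmh <- structure(list(drug_row = "A", drug_col = "B",
                        doses_row = c(0, 1, 3, 9, 27),
                        doses_col = c(0, 1, 3, 9, 27), response = resp),
                   class = "dose_matrix")
  ssh <- zip_delta(dmh)
  expect_equal(unique(as.numeric(stats::na.omit(as.numeric(ssh$delta)))), 15,
               tolerance = 1e-9)
  expect_equal(ssh$mean_delta, 15, tolerance = 1e-9)
})

test_that("a planted constant interaction is recovered on the percent scale", {
  c1 <- c(0, 0.5, 1, 1.3); c2 <- c(0, 0.6, 2, 1.1)
  dm <- simulate_dose_matrix(c1, c2, delta0 = 0.15, noise_sd = 0)
  ss <- zip_delta(dm)
  expect_lt(abs(ss$mean_delta - 15), 0.5)
  expect_lt(abs(ss$max_window_score - 15), 0.5)
})

test_that("transposing the matrix transposes the delta surface", {
  c1 <- c(0, 0.5, 1, 1.3); c2 <- c(0, 0.6, 2, 1.1)
  dm <- simulate_dose_matrix(c1, c2, delta0 = 0.1, noise_sd = 0.02, seed = 6)
  dmT <- structure(list(drug_row = dm$drug_col, drug_col = dm$drug_row,
                        doses_row = dm$doses_col, doses_col = dm$doses_row,
                        response = t(dm$response)), class = "dose_matrix")
  s1 <- zip_delta(dm)
  s2 <- zip_delta(dmT)
  expect_equal(s2$delta, t(s1$delta), tolerance = 1e-8)
  expect_equal(s2$mean_delta, s1$mean_delta, tolerance = 1e-8)
})

test_that("the max 3x3 window score dominates the global mean on even grids", {
  means <- vapply(1:5, function(s) {
    dm <- simulate_dose_matrix(c(0, 0.5, 1, 1.3), c(0, 0.6, 2, 1.1),
                               delta0 = 0, noise_sd = 0.02, seed = s)
    ss <- zip_delta(dm)    # 9x9 combination grid tiles into 3x3 windows
    expect_gte(ss$max_window_score, ss$mean_delta - 1e-9)
    ss$mean_delta
  }, numeric(1))
  # near-null surfaces stay near zero on the percent scale; individual
  # replicates carry curve-fit wiggle so the bound applies to the average
  expect_lt(abs(mean(means)), 1)
  expect_true(all(abs(means) < 2.5))
})

test_that("group comparison of max synergy scores reuses the exact rank-sum", {
  same <- c(5, 10, 15)
  expect_equal(compare_synergy_groups(same, same)$p, 1)
  res <- compare_synergy_groups(c(30, 25, 20), c(1, 2, 3))
  expect_equal(res$p, 0.1)
  expect_equal(res$median_a, 25)
  expect_equal(res$median_b, 2)
  # p decreases monotonically with group separation (72 vs 15, seeded)
  set.seed(12)
  base <- rnorm(72, 10, 5); small <- rnorm(15, 10, 5)
  ps <- vapply(c(0, 3, 6, 9), function(shift)
    compare_synergy_groups(base + shift, small)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("dose matrices round-trip through CSV", {
  dm <- simulate_dose_matrix(c(0, 0.5, 1, 1.3), c(0, 0.6, 2, 1.1),
                             delta0 = 0.05, noise_sd = 0.01, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_dose_matrix(dm, f)
  back <- read_dose_matrix(f)
  expect_equal(back$doses_row, dm$doses_row, tolerance = 1e-6)
  expect_equal(unname(back$response), unname(dm$response), tolerance = 1e-6)
})
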