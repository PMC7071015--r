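peak_row <- function(volume, atom_i = "HA", atom_j = "HN") {
  data.frame(res_i = 1, atom_i = atom_i, res_j = 2, atom_j = atom_j,
             volume = volume)
}

test_that("calibration follows the inverse-sixth-power law", {
  ref <- calibration_reference(2.5, 1000)
  # identical volume: identical distance
  expect_equal(calibrate_noe(peak_row(1000), ref)$distance_A, 2.5)
  # 64-fold weaker volume: doubled distance (64 = 2^6)
  expect_equal(calibrate_noe(peak_row(1000 / 64), ref)$distance_A, 5.0,
               tolerance = 1e-12)
  # alpha_ref/alpha = 8: factor 8^(1/6) = sqrt(2)
  ref18 <- calibration_reference(1.8, 1000)
  expect_equal(calibrate_noe(peak_row(125), ref18)$distance_A,
               1.8 * sqrt(2), tolerance = 1e-12)
  expect_error(calibrate_noe(peak_row(0), ref), "peak 1")
  expect_error(calibrate_noe(peak_row(-2), ref), "non-positive")
})

test_that("calibration round-trips, is monotone and scale-invariant", {
  set.seed(5)
  d <- runif(40, 1.9, 6)
  c0 <- 7.3e5
  peaks <- data.frame(res_i = seq_along(d), atom_i = "HA",
                      res_j = seq_along(d) + 1, atom_j = "HN",
                      volume = c0 * d^-6)
  ref <- calibration_reference(2.2, c0 * 2.2^-6)
  out <- calibrate_noe(peaks, ref)
  expect_equal(out$distance_A, d, tolerance = 1e-9)
  expect_identical(out$source_peak, seq_along(d))
  # bounds invariant: 0 < lower <= distance <= upper
  expect_true(all(out$lower_A > 0))
  expect_true(all(out$lower_A <= out$distance_A + 1e-12))
  expect_true(all(out$distance_A <= out$upper_A))
  # larger volume -> strictly smaller distance
  ord <- order(peaks$volume)
  expect_true(all(diff(out$distance_A[ord]) < 0))
  # multiplying every volume (incl. the reference) leaves distances unchanged
  peaks2 <- peaks
  peaks2$volume <- peaks$volume * 137.5
  ref2 <- calibration_reference(2.2, ref$a_ref * 137.5)
  expect_equal(calibrate_noe(peaks2, ref2)$distance_A, out$distance_A,
               tolerance = 1e-12)
})

test_that("bound construction clamps and corrects pseudo-atoms", {
  ref <- calibration_reference(2.0, 1000)
  # strong peak -> short distance; lower bound clamped at 1.8 when possible
  strong <- calibrate_noe(peak_row(4000), ref)     # r = 2 * (1/4)^(1/6) ~ 1.59
  expect_equal(strong$lower_A, pmin(1.8, strong$distance_A))
  weak <- calibrate_noe(peak_row(50), ref)
  expect_equal(weak$lower_A, weak$distance_A - 0.5)
  expect_equal(weak$upper_A, weak$distance_A + 0.5)
  # beta pseudo-proton gets the +1.0 A upper-bound allowance
  hb <- calibrate_noe(peak_row(50, atom_j = "HB"), ref)
  expect_equal(hb$upper_A, hb$distance_A + 1.5)
})

test_that("proline classification bands match the 13C shift convention", {
  # the trans assignment observed for the linker proline: delta-delta 4.27 ppm
  expect_identical(classify_proline(31.2, 26.93), "trans")
  expect_identical(classify_proline(34.5, 25.0), "cis")     # 9.5 ppm
  expect_identical(classify_proline(32.0, 25.0), "ambiguous")  # 7.0 ppm
  expect_identical(classify_proline(c(30, 25, 32), c(25.73, 34.5, 25)),
                   c("trans", "cis", "ambiguous"))
})

test_that("peak and restraint tables round-trip through TSV", {
  ref <- calibration_reference(2.5, 1000)
  peaks <- data.frame(res_i = c(1, 2), atom_i = c("HA", "HN"),
                      res_j = c(3, 4), atom_j = c("HB", "HA"),
                      volume = c(812.5, 77.1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_noe_peaks(peaks, f1)
  expect_equal(read_noe_peaks(f1), peaks)
  restr <- calibrate_noe(peaks, ref)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_restraints_tsv(restr, f2)
  back <- read_restraints_tsv(f2)
  expect_equal(back$distance_A, restr$distance_A, tolerance = 1e-12)
  expect_equal(back$lower_A, restr$lower_A, tolerance = 1e-12)
  expect_equal(back$upper_A, restr$upper_A, tolerance = 1e-12)
})
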