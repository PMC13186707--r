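test_that("max projection takes per-pixel maxima with lowest-z ties", {
  # single plane: identity
  m <- matrix(withr::with_seed(1L, rpois(25, 5)), 5)
  one <- max_project(image_stack(m))
  expect_equal(one$image, m)
  expect_true(all(one$z_argmax == 0L))

  # planes [[0]], [[5]], [[3]]: value 5 from plane index 1
  st <- array(c(0, 5, 3), c(3, 1, 1))
  pr <- max_project(st)
  expect_equal(pr$image[1, 1], 5)
  expect_equal(pr$z_argmax[1, 1], 1L)

  # projection dominates every plane elementwise
  counts <- array(withr::with_seed(2L, rpois(4 * 6 * 6, 3)), c(4, 6, 6))
  pr2 <- max_project(counts)
  for (z in 1:4) expect_true(all(pr2$image >= counts[z, , ]))
})

test_that("DoG detection finds isolated Gaussian spots", {
  expect_equal(nrow(detect_foci(matrix(0, 32, 32), 1, 3,
                                detect_threshold = 0.5)), 0L)
  expect_error(detect_foci(matrix(0, 8, 8), 3, 1), "sigma_min")

  # one bright spot: exactly one candidate within 1 px of truth
  fs <- gen_focus_stack(focus_sim_spec(
    image_shape = c(40L, 40L), molecularities = 64L,
    positions = cbind(20.3, 19.6), background_rate = 2, seed = 8L))
  pr <- max_project(fs$stack)
  cand <- detect_foci(pr$image, 1.2, 3.75)
  expect_equal(nrow(cand), 1L)
  expect_lt(sqrt((cand$row - 20.3)^2 + (cand$col - 19.6)^2), 1.5)

  # two spots 10 sigma apart: two candidates
  fs2 <- gen_focus_stack(focus_sim_spec(
    image_shape = c(40L, 40L), molecularities = c(64L, 64L),
    positions = cbind(c(12, 27), c(12, 27)), background_rate = 2, seed = 9L))
  cand2 <- detect_foci(max_project(fs2$stack)$image, 1.2, 3.75)
  expect_equal(nrow(cand2), 2L)
})

test_that("2D Gaussian fit recovers noiseless parameters and the integral", {
  img <- render_gaussian_image(15, amp = 100, x0 = 7, y0 = 7, sigma = 1.2,
                               offset = 5)
  rec <- fit_focus(img, c(7, 7))
  expect_true(rec$accepted)
  expect_equal(rec$amplitude, 100, tolerance = 1e-3)
  expect_equal(rec$sigma, 1.2, tolerance = 1e-3)
  expect_equal(rec$x0, 7, tolerance = 1e-3)
  expect_equal(rec$y0, 7, tolerance = 1e-3)
  expect_equal(rec$offset, 5, tolerance = 1e-2)
  # analytic integral vs photons above offset summed over the whole image
  expect_equal(rec$intensity, sum(img - 5), tolerance = 0.02)

  # flat ROI: degenerate, rejected with a reason
  flat <- fit_focus(matrix(3, 11, 11), c(5, 5))
  expect_false(flat$accepted)
  expect_equal(flat$reason, "degenerate")

  # ROI at the border: rejected
  edge <- fit_focus(img, c(0, 7))
  expect_false(edge$accepted)
  expect_equal(edge$reason, "border")
})

test_that("annulus background subtraction recovers net intensities", {
  # pure uniform background: net intensity 0 (exact, median == level)
  bg <- matrix(7, 21, 21)
  rec <- fit_focus(render_gaussian_image(21, x0 = 10, y0 = 10), c(10, 10))
  rec_bg <- subtract_background(bg, rec)
  expect_equal(rec_bg$intensity, 0)
  expect_equal(rec_bg$offset, 7)

  # spot of known integral on uniform background: within Poisson error
  fs <- gen_focus_stack(focus_sim_spec(
    image_shape = c(30L, 30L), n_z = 1L, psf_sigma = 1.0,
    molecularities = 32L, positions = cbind(15, 15),
    photons_per_monomer = 50, background_rate = 3, seed = 12L))
  pr <- max_project(fs$stack)
  r <- fit_focus(pr$image, c(15, 15), z_argmax = pr$z_argmax)
  r <- subtract_background(pr$image, r)
  # 5x5 ROI captures erf(2.5 / (sigma sqrt 2))^2 of a sigma = 1 Gaussian
  capture <- (2 * pnorm(2.5) - 1)^2
  expect_lt(abs(r$intensity - 1600 * capture), 4 * sqrt(1600 + 25 * 3))

  # negative net photon count is floored at zero
  dip <- matrix(10, 21, 21)
  dip[9:13, 9:13] <- 0
  rec2 <- fit_focus(render_gaussian_image(21, x0 = 10, y0 = 10), c(10, 10))
  rec2d <- subtract_background(dip, rec2)
  expect_equal(rec2d$intensity, 0)

  # annulus outside the image: rejected as border
  near <- subtract_background(bg, within(rec, {x0 <- 2; y0 <- 2}))
  expect_false(near$accepted)
  expect_equal(near$reason, "border")
})

test_that("focus filters reject by distance, dimness, width and z edge", {
  base <- function(x0, y0, sigma = 1.5, intensity = 500, z = 3L)
    data.frame(x0 = x0, y0 = y0, sigma = sigma, amplitude = 10, offset = 2,
               intensity = intensity, z_argmax = z, accepted = TRUE,
               reason = NA_character_)
  # close pair: both rejected
  pair <- rbind(base(10, 10), base(10, 11))
  fp <- filter_foci(pair, min_distance = 4, n_z = 8L)
  expect_true(all(!fp$accepted))
  expect_true(all(fp$reason == "distance"))
  # keep_brighter spares the brighter member
  pair2 <- rbind(base(10, 10, intensity = 900), base(10, 11, intensity = 100))
  fk <- filter_foci(pair2, min_distance = 4, n_z = 8L, keep_brighter = TRUE)
  expect_equal(fk$accepted, c(TRUE, FALSE))

  # z-edge: argmax in the outer planes is discarded on either end
  for (z_bad in c(0L, 7L)) {
    fz <- filter_foci(base(20, 20, z = z_bad), min_distance = 4, n_z = 8L)
    expect_false(fz$accepted)
    expect_equal(fz$reason, "z_edge")
  }

  # dim and wide rejections carry their reasons
  fd <- filter_foci(base(20, 20, intensity = 1), min_intensity = 50, n_z = 8L)
  expect_equal(fd$reason, "dim")
  fs <- filter_foci(base(20, 20, sigma = 9), sigma_bounds = c(0.75, 3),
                    n_z = 8L)
  expect_equal(fs$reason, "sigma")

  # isolated bright in-range record passes untouched
  ok <- filter_foci(base(20, 20), min_distance = 4, min_intensity = 50,
                    sigma_bounds = c(0.75, 3), n_z = 8L)
  expect_true(ok$accepted)

  # bookkeeping: accepted + rejected = detected, one reason per rejection
  mix <- rbind(base(10, 10), base(10, 11), base(30, 30, intensity = 1))
  fm <- filter_foci(mix, min_distance = 4, min_intensity = 50, n_z = 8L)
  expect_equal(nrow(fm), 3L)
  expect_true(all(!is.na(fm$reason[!fm$accepted])))
  expect_true(all(is.na(fm$reason[fm$accepted])))
})

test_that("calibration is the day-matched mean of accepted NUP96 intensities", {
  recs <- data.frame(x0 = c(1, 2), y0 = c(1, 2), sigma = 1.5, amplitude = 1,
                     offset = 0, intensity = c(100, 300), z_argmax = 3L,
                     accepted = TRUE, reason = NA_character_)
  cal <- calibrate(recs)
  expect_equal(cal$mean_intensity, 200)
  expect_equal(cal$standard_stoichiometry, 32)
  expect_equal(calibrate(recs[1, ])$mean_intensity, 100)
  expect_error(calibrate(within(recs, accepted <- FALSE)), "no accepted")

  # day matching is enforced
  recs$day <- c("d1", "d2")
  expect_error(calibrate(recs), "day-matched")
  expect_equal(calibrate(recs, allow_mixed_days = TRUE)$mean_intensity, 200)

  # simulated standards: mean intensity within sampling error of the expected
  # per-pore capture (ROI fraction of the projected 32-mer signal)
  nup <- gen_nup96_stack(12L, photons_per_monomer = 50, seed = 17L)
  cal_sim <- calibrate(quantify_foci(nup$stack))
  expect_gt(cal_sim$mean_intensity, 0.6 * 32 * 50 * 0.33)
  expect_lt(cal_sim$mean_intensity, 1.4 * 32 * 50 * 0.40)
})

test_that("stoichiometry is the 32-referenced intensity ratio", {
  cal <- calibrate(data.frame(intensity = c(120, 280), accepted = TRUE))
  expect_identical(stoichiometry(200, cal), 32)
  expect_identical(stoichiometry(0, cal), 0)
  expect_identical(stoichiometry(400, cal), 64)
})

test_that("PLA quantification normalizes to the Otsu background", {
  mito <- matrix(1, 20, 20)
  mito[5:10, 5:10] <- 100
  # uniform PLA: ratio 1
  expect_equal(pla_mito_intensity(matrix(3, 20, 20), mito), 1)
  # PLA at 2b inside the mask, b outside: ratio 2
  pla <- matrix(5, 20, 20)
  pla[5:10, 5:10] <- 10
  expect_equal(pla_mito_intensity(pla, mito), 2)
  # constant mitochondrial image: degenerate threshold
  expect_error(pla_mito_intensity(pla, matrix(1, 20, 20)), "degenerate")
})
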