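make_refs <- function(irt, rt = NULL, keys = sprintf("REF%02d/2", seq_along(irt))) {
  refs <- data.frame(key = keys,
                     modified_peptide = sub("/.*$", "", keys),
                     precursor_charge = 2L,
                     rt_min = if (is.null(rt)) irt else rt,
                     irt = irt)
  class(refs) <- c("reference_set", class(refs))
  refs
}

test_that("landmarks tile the gradient and include its extremes", {
  lib <- uniform_library(100, rts = seq(1, 100, length.out = 100))
  refs <- pick_landmarks(lib, n = 12)
  expect_equal(nrow(refs), 12)
  expect_equal(min(refs$rt_min), 1)
  expect_equal(max(refs$rt_min), 100)
  # adjacent gaps within twice the ideal grid spacing
  ideal <- (100 - 1) / 11
  expect_true(all(diff(sort(refs$rt_min)) <= 2 * ideal))
  # provisional anchors: 0 at the earliest, 100 at the latest
  expect_equal(refs$irt[which.min(refs$rt_min)], 0)
  expect_equal(refs$irt[which.max(refs$rt_min)], 100)
})

test_that("landmark selection saturates and reports shortfalls", {
  lib <- uniform_library(12)
  refs <- pick_landmarks(lib, n = 12, min_intensity_quantile = 0)
  expect_equal(nrow(refs), 12)
  expect_setequal(refs$key, lib$entries$key)
  expect_error(pick_landmarks(uniform_library(8), n = 12), "short by")
})

test_that("the intensity floor removes weak entries from eligibility", {
  entries <- lapply(1:20, function(i) {
    e <- make_entry(synthetic_sequences(20, 10)[i], rt = 5 * i,
                    protein = sprintf("P%02d", i), n_frag = 5L)
    if (i > 10)  # weak second half
      e$fragments$relative_intensity <- c(1, rep(0.01, 4))
    e
  })
  lib <- make_library(entries)
  refs <- pick_landmarks(lib, n = 5, min_intensity_quantile = 0.5)
  expect_true(all(refs$rt_min <= 50))  # only the strong half is eligible
})

test_that("iRT assignment is linear between anchors and flags extrapolation", {
  lib <- uniform_library(5, rts = c(10, 15, 20, 25, 5))
  refs <- pick_landmarks(lib, n = 2, min_intensity_quantile = 0)
  # two landmarks: earliest (5) and latest (25)
  expect_setequal(refs$rt_min, c(5, 25))
  lib <- assign_irt(lib, refs)
  e <- lib$entries
  expect_equal(e$irt[e$rt_min == 15], 50)   # midpoint of the anchor span
  expect_equal(e$irt[e$rt_min == 5], 0)     # anchor recovers its value
  expect_equal(e$irt[e$rt_min == 25], 100)
  expect_false(any(e$irt_extrapolated))

  lib2 <- uniform_library(3, rts = c(10, 20, 25))
  refs2 <- make_refs(c(0, 100), rt = c(10, 20),
                     keys = lib2$entries$key[1:2])
  lib2 <- assign_irt(lib2, refs2)
  expect_equal(lib2$entries$irt, c(0, 100, 150))  # linear extension past the span
  expect_identical(lib2$entries$irt_extrapolated, c(FALSE, FALSE, TRUE))
})

test_that("calibration recovers an exact line", {
  cal <- calibrate(make_refs(c(0, 50, 100)),
                   data.frame(key = sprintf("REF%02d/2", 1:3),
                              rt_min = c(10, 15, 20)))
  expect_equal(cal$slope, 0.1, tolerance = 1e-9)
  expect_equal(cal$intercept, 10, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  expect_equal(cal$n_used, 3)
})

test_that("calibration rejects degenerate inputs", {
  expect_error(calibrate(make_refs(c(0, 50, 100)),
                         data.frame(key = "REF01/2", rt_min = 10)),
               ">= 2")
  # inverted gradient order gives a negative slope
  expect_error(calibrate(make_refs(c(0, 50, 100)),
                         data.frame(key = sprintf("REF%02d/2", 1:3),
                                    rt_min = c(20, 15, 10))),
               "slope")
})

test_that("one outlying reference is rejected and the line recovered", {
  irt <- seq(0, 100, length.out = 13)
  rt <- 10 + 0.1 * irt
  rt[7] <- 19  # true value would be 15
  cal <- calibrate(make_refs(irt), data.frame(key = sprintf("REF%02d/2", 1:13),
                                              rt_min = rt))
  expect_identical(cal$rejected, "REF07/2")
  expect_equal(cal$n_used, 12)
  expect_equal(cal$slope, 0.1, tolerance = 1e-6)
  expect_equal(cal$intercept, 10, tolerance = 1e-6)
})

test_that("slope recovery is within its standard error under noise", {
  irt <- seq(0, 100, length.out = 12)
  true_slope <- 0.1
  within <- logical(200)
  set.seed(314)
  for (s in 1:200) {
    rt <- 10 + true_slope * irt + rnorm(12, 0, 0.05)
    cal <- calibrate(make_refs(irt), data.frame(key = sprintf("REF%02d/2", 1:12),
                                                rt_min = rt))
    se <- cal$residual_sd / sqrt(sum((irt - mean(irt))^2))
    within[s] <- abs(cal$slope - true_slope) <= 3 * se
  }
  expect_gte(mean(within), 0.95)
})

test_that("RT prediction is affine with clipping at zero", {
  cal <- structure(list(slope = 0.1, intercept = 10, r_squared = 1,
                        residual_sd = 0, n_used = 3, rejected = character(0)),
                   class = "rt_calibration")
  expect_equal(as.numeric(predict_rt(30, cal)), 13)
  expect_equal(as.numeric(predict_rt(0, cal)), 10)
  cal$intercept <- -5
  p <- predict_rt(c(0, 100), cal)
  expect_equal(as.numeric(p), c(0, 5))
  expect_identical(attr(p, "clipped"), c(TRUE, FALSE))
})

test_that("self-calibration on the source gradient is an exact round trip", {
  lib <- simulate_library(generate_proteome(10, 300, seed = 2),
                          gradient_profile(120), seed = 2)$library
  refs <- pick_landmarks(lib)
  lib <- assign_irt(lib, refs)
  measured <- data.frame(key = refs$key, rt_min = refs$rt_min)  # no noise
  cal <- calibrate(refs, measured)
  pred <- as.numeric(predict_rt(lib$entries$irt, cal))
  expect_lt(max(abs(pred - lib$entries$rt_min)), 1e-9)
})

test_that("affine RT transforms change the fit but not iRTs or rank order", {
  lib <- uniform_library(30, rts = seq(2, 110, length.out = 30))
  refs <- pick_landmarks(lib, n = 12, min_intensity_quantile = 0)
  lib <- assign_irt(lib, refs)
  base_irt <- lib$entries$irt
  measured <- data.frame(key = refs$key, rt_min = 3 + 0.2 * refs$rt_min)
  cal <- calibrate(refs, measured)
  pred <- as.numeric(predict_rt(lib$entries$irt, cal))
  # a second affine transform a + b * rt with b > 0
  measured2 <- data.frame(key = refs$key, rt_min = 1 + 4 * measured$rt_min)
  cal2 <- calibrate(refs, measured2)
  pred2 <- as.numeric(predict_rt(lib$entries$irt, cal2))
  expect_equal(cal2$slope, 4 * cal$slope, tolerance = 1e-9)
  expect_equal(cal2$intercept, 1 + 4 * cal$intercept, tolerance = 1e-6)
  expect_identical(lib$entries$irt, base_irt)       # iRTs untouched
  expect_identical(order(pred), order(pred2))       # rank order preserved
})

test_that("median prediction error stays within twice the reference noise", {
  sim <- simulate_library(generate_proteome(25, 400, seed = 6),
                          gradient_profile(120), seed = 6)
  lib <- sim$library
  expect_gte(nrow(lib$entries), 500)
  refs <- pick_landmarks(lib)
  lib <- assign_irt(lib, refs)
  sigma <- 0.05
  errs <- c()
  for (s in 1:20) {
    tr <- simulate_transfer(lib, transfer_model(20 / 120, 0.5, 0,
                                                noise_sd = sigma, seed = s),
                            refs)
    cal <- calibrate(refs, tr$measured)
    pred <- as.numeric(predict_rt(lib$entries$irt, cal))
    errs <- c(errs, stats::median(abs(pred - tr$truth$rt_dest_true_min)))
  }
  expect_lt(stats::median(errs), 2 * sigma)
})
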