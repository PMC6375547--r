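g20 <- gradient_profile(20, "g20")

test_that("windows are centred, clipped at boundaries, dropped when outside", {
  t <- assign_windows(make_targets(c(5.0, 0.1, 25)), width = 0.4, g20)
  expect_equal(nrow(t), 2)
  expect_equal(c(t$window_start[1], t$window_end[1]), c(4.8, 5.2))
  expect_false(t$clipped[1])
  expect_equal(c(t$window_start[2], t$window_end[2]), c(0, 0.3))
  expect_true(t$clipped[2])
  dropped <- attr(t, "dropped")
  expect_equal(dropped$predicted_rt, 25)
})

test_that("the sweep line counts overlapping windows under half-open rules", {
  t <- make_targets(c(5.0, 5.2, 8.0))
  t <- assign_windows(t, 0.4, g20)
  p <- concurrency_profile(t)
  expect_equal(p$max_concurrency, 2)
  expect_gte(p$time_of_max, 5.0)
  expect_lt(p$time_of_max, 5.2)
  # single window
  expect_equal(concurrency_profile(assign_windows(make_targets(5), 0.4, g20))$max_concurrency, 1)
  # windows sharing only an endpoint do not overlap
  touch <- assign_windows(make_targets(c(4.5, 5.5)), 1.0, g20)
  expect_equal(concurrency_profile(touch)$max_concurrency, 1)
  # empty schedule
  expect_equal(concurrency_profile(make_targets(numeric(0))
                                   |> assign_windows(0.4, g20))$max_concurrency, 0)
})

test_that("sweep-line concurrency equals brute-force grid evaluation", {
  set.seed(99)
  for (i in 1:100) {
    n <- 50
    starts <- runif(n, 0, 5)
    widths <- runif(n, 0.05, 1)
    t <- data.frame(window_start = starts, window_end = starts + widths)
    expect_equal(concurrency_profile(t)$max_concurrency,
                 oracle_max_concurrency(starts, starts + widths, step = 0.001))
  }
})

test_that("concurrency is monotone in window width and in target count", {
  set.seed(21)
  rts <- runif(30, 1, 19)
  widths <- c(0.1, 0.2, 0.5, 1, 2)
  maxes <- vapply(widths, function(w)
    concurrency_profile(assign_windows(make_targets(rts), w, g20))$max_concurrency, 0L)
  expect_true(all(diff(maxes) >= 0))
  w1 <- assign_windows(make_targets(rts), 0.5, g20)
  w2 <- assign_windows(make_targets(c(rts, 10)), 0.5, g20)
  expect_gte(concurrency_profile(w2)$max_concurrency,
             concurrency_profile(w1)$max_concurrency)
})

test_that("dwell time divides the cycle among concurrent transitions", {
  mk <- function(n, cycle) {
    t <- assign_windows(make_targets(rep(10, n)), 0.4, g20)
    mrm_schedule(t, g20, cycle_time_s = cycle)
  }
  dw <- dwell_report(mk(100, 1))
  expect_equal(attr(dw, "min_dwell_ms"), 9.5)
  expect_equal(attr(dwell_report(mk(1, 1)), "min_dwell_ms"), 999.5)
  dw200 <- dwell_report(mk(200, 0.8))
  expect_equal(attr(dw200, "min_dwell_ms"), 3.5)
  expect_true(any(dw200$below_floor))
})

test_that("validation is strict at the concurrency limit", {
  co_elute <- function(n) {
    t <- assign_windows(make_targets(rep(10, n)), 0.4, g20)
    mrm_schedule(t, g20, cycle_time_s = 1, max_concurrent_limit = 200L)
  }
  # well under the limit (and dwell-feasible)
  expect_identical(validate_schedule(co_elute(8))$status, "PASS")
  # exactly at the limit: "fewer than" means FAIL
  expect_identical(validate_schedule(co_elute(200))$status, "FAIL")
  # empty schedule passes vacuously
  empty <- mrm_schedule(assign_windows(make_targets(numeric(0)), 0.4, g20), g20)
  expect_identical(validate_schedule(empty)$status, "PASS")
  # dwell floor alone can fail a schedule below the concurrency limit
  expect_identical(validate_schedule(co_elute(190))$status, "FAIL")  # 1000/190 < 5.5
  v <- validate_schedule(co_elute(200))
  expect_equal(v$max_concurrency, 200)
  expect_equal(length(v$offending_keys), 200)
})

test_that("infeasible methods split round-robin into passing halves", {
  t <- assign_windows(make_targets(rep(10, 300)), 0.4, g20)
  methods <- split_methods(t, g20, cycle_time_s = 1, max_concurrent_limit = 200L)
  expect_length(methods, 2)
  expect_equal(vapply(methods, function(s) nrow(s$targets), 0L), c(150L, 150L))
  for (m in methods) expect_identical(validate_schedule(m)$status, "PASS")
  # partition: disjoint and exhaustive
  keys <- unlist(lapply(methods, function(s) s$targets$key))
  expect_setequal(keys, t$key)
  expect_equal(anyDuplicated(keys), 0)
  # a passing schedule is returned unchanged as one method
  ok <- assign_windows(make_targets(seq(1, 19, length.out = 40)), 0.4, g20)
  expect_length(split_methods(ok, g20), 1)
})

test_that("split methods partition random target sets into passing methods", {
  set.seed(4)
  t <- assign_windows(make_targets(runif(120, 2, 18)), 2, g20)
  methods <- split_methods(t, g20, cycle_time_s = 1, max_concurrent_limit = 20L)
  expect_gte(length(methods), 2)
  for (m in methods) {
    expect_identical(validate_schedule(m)$status, "PASS")
    expect_lt(m$concurrency$max_concurrency, 20)
  }
  keys <- unlist(lapply(methods, function(s) s$targets$key))
  expect_setequal(keys, t$key)
  expect_equal(anyDuplicated(keys), 0)
})

test_that("dynamic-MRM export uses the exact vendor header and windows", {
  t <- assign_windows(make_targets(c(5, 9)), 0.4, g20)
  sched <- mrm_schedule(t, g20)
  path <- withr::local_tempfile(fileext = ".csv")
  export_dmrm_csv(sched, path)
  lines <- readLines(path)
  expect_identical(lines[1],
    "Compound Name,ISTD?,Precursor Ion,MS1 Res,Product Ion,MS2 Res,Fragmentor,Collision Energy,Cell Accelerator Voltage,Ret Time (min),Delta Ret Time,Polarity")
  expect_length(lines, 3)
  row <- strsplit(lines[2], ",")[[1]]
  expect_identical(row[1], "PEP001.2y5")
  expect_identical(row[10], "5.00")   # window centre = predicted RT (unclipped)
  expect_identical(row[11], "0.40")   # delta = full window width
  expect_identical(row[12], "Positive")
})

test_that("unscheduled export replaces RT columns with a dwell column", {
  t <- make_targets(c(5, 9))
  path <- withr::local_tempfile(fileext = ".csv")
  export_unscheduled_csv(t, dwell_ms = 25, path = path)
  lines <- readLines(path)
  expect_match(lines[1], "Dwell \\(ms\\)")
  expect_false(grepl("Ret Time", lines[1]))
  expect_match(lines[2], ",25.0,")
})

test_that("Skyline-style transition lists round-trip", {
  lib <- uniform_library(6)
  lib <- assign_irt(lib, pick_landmarks(lib, 3, min_intensity_quantile = 0))
  targets <- select_targets(lib, selection_rules(min_length = 4,
                                                 min_fragment_index = 1,
                                                 fragments_per_peptide = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  export_skyline_csv(targets, path)
  back <- read_skyline_csv(path)
  expect_equal(nrow(back), nrow(targets))
  m <- match(paste(back$PeptideModifiedSequence, back$FragmentIon),
             paste(targets$modified_peptide, targets$fragment))
  expect_false(anyNA(m))
  expect_equal(back$PrecursorMz, targets$precursor_mz[m], tolerance = 1e-4)
  expect_equal(back$ProductMz, targets$fragment_mz[m], tolerance = 1e-4)
})

test_that("collision energy ramps are linear per charge with 2+ fallback", {
  expect_equal(collision_energy(500, 2), 0.031 * 500 + 1)
  expect_equal(collision_energy(500, 3), 0.036 * 500 - 4.8)
  expect_equal(collision_energy(500, 4), collision_energy(500, 2))
})
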