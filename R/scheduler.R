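# Dynamic-MRM scheduling: RT windows, sweep-line concurrency, dwell-time
# feasibility, method splitting and transition-list export.

#' Default collision-energy model
#'
#' Vendor-style linear CE ramps per precursor charge:
#' `CE = slope * (m/z) + intercept` volts. Charges without their own
#' coefficients fall back to the 2+ ramp.
#'
#' @param slopes,intercepts Named numeric vectors keyed by charge.
#' @return List with `slopes` and `intercepts`.
#' @export
ce_defaults <- function(slopes = c(`2` = 0.031, `3` = 0.036),
                        intercepts = c(`2` = 1, `3` = -4.8)) {
  list(slopes = slopes, intercepts = intercepts)
}

#' Collision energy for a precursor
#' @param mz Precursor m/z (Th).
#' @param charge Precursor charge.
#' @param params Model from [ce_defaults()].
#' @return CE in volts.
#' @export
collision_energy <- function(mz, charge, params = ce_defaults()) {
  z <- as.character(charge)
  z[!z %in% names(params$slopes)] <- "2"
  unname(params$slopes[z] * mz + params$intercepts[z])
}

#' Assign scheduling windows around predicted retention times
#'
#' Each target gets the window `[predicted_rt - width/2,
#' predicted_rt + width/2]`, intersected with `[0, gradient length]`.
#' Windows truncated by the gradient boundary are flagged `clipped`;
#' targets whose window lies entirely outside the gradient are dropped
#' and reported in the attribute `dropped`.
#'
#' @param targets Target data frame carrying a `predicted_rt` column
#'   (minutes); if absent, `rt_min` is used as the prediction.
#' @param width Full window width in minutes (the instrument's
#'   "Delta Ret Time"); default 0.4.
#' @param gradient A [gradient_profile()].
#' @return `targets` with columns `predicted_rt`, `window_width`,
#'   `window_start`, `window_end`, `clipped` added.
#' @export
assign_windows <- function(targets, width = 0.4, gradient) {
  stopifnot(width > 0, inherits(gradient, "gradient_profile"))
  targets <- as.data.frame(targets)
  if (!"predicted_rt" %in% names(targets)) targets$predicted_rt <- targets$rt_min
  lo <- targets$predicted_rt - width / 2
  hi <- targets$predicted_rt + width / 2
  outside <- hi <= 0 | lo >= gradient$length
  dropped <- targets[outside, , drop = FALSE]
  targets <- targets[!outside, , drop = FALSE]
  lo <- pmax(lo[!outside], 0)
  hi <- pmin(hi[!outside], gradient$length)
  targets$window_width <- rep(width, nrow(targets))
  targets$window_start <- lo
  targets$window_end <- hi
  targets$clipped <- (hi - lo) < width - 1e-12
  rownames(targets) <- NULL
  attr(targets, "dropped") <- dropped
  if (nrow(dropped))
    message(nrow(dropped), " target(s) dropped: window outside the gradient")
  targets
}

#' Concurrency profile of scheduled windows
#'
#' Sweep-line count of simultaneously active transitions under the
#' half-open window convention `[start, end)`: windows sharing only an
#' endpoint do not overlap.
#'
#' @param targets Windowed targets from [assign_windows()].
#' @return A `concurrency_profile`: list with `breakpoints` (sorted event
#'   times), `counts` (per inter-breakpoint interval), `max_concurrency`
#'   and `time_of_max` (start of the first interval achieving it).
#' @export
concurrency_profile <- function(targets) {
  targets <- as.data.frame(targets)
  if (!nrow(targets))
    return(structure(list(breakpoints = numeric(0), counts = integer(0),
                          max_concurrency = 0L, time_of_max = NA_real_),
                     class = "concurrency_profile"))
  if (!all(c("window_start", "window_end") %in% names(targets)))
    stop("targets have no windows; call assign_windows() first")
  ev <- data.frame(time = c(targets$window_start, targets$window_end),
                   delta = rep(c(1L, -1L), each = nrow(targets)))
  # ends sort before starts at the same instant: half-open intervals
  ev <- ev[order(ev$time, ev$delta), , drop = FALSE]
  bp <- unique(ev$time)
  counts <- cumsum(vapply(split(ev$delta, match(ev$time, bp)), sum, 0L))
  counts <- as.integer(counts[match(seq_along(bp), as.integer(names(counts)))])
  # drop the final breakpoint interval (count is 0 after the last end)
  max_c <- if (length(counts)) max(counts) else 0L
  structure(list(breakpoints = bp,
                 counts = counts,
                 max_concurrency = max_c,
                 time_of_max = bp[which.max(counts)]),
            class = "concurrency_profile")
}

#' @export
print.concurrency_profile <- function(x, ...) {
  cat(sprintf("<concurrency_profile> max %d concurrent at %.3f min (%d breakpoints)\n",
              x$max_concurrency, x$time_of_max, length(x$breakpoints)))
  invisible(x)
}

#' Build a dynamic-MRM schedule
#'
#' Bundles windowed targets with the gradient, acquisition cycle time and
#' the concurrency limit, and computes the concurrency profile.
#'
#' @param targets Windowed targets from [assign_windows()].
#' @param gradient A [gradient_profile()].
#' @param cycle_time_s Target cycle time in seconds (default 1).
#' @param max_concurrent_limit Strict upper bound on concurrent
#'   transitions (default 200).
#' @return An object of class `mrm_schedule`.
#' @export
mrm_schedule <- function(targets, gradient, cycle_time_s = 1,
                         max_concurrent_limit = 200L) {
  stopifnot(inherits(gradient, "gradient_profile"), cycle_time_s > 0)
  structure(list(targets = as.data.frame(targets), gradient = gradient,
                 cycle_time_s = cycle_time_s,
                 max_concurrent_limit = as.integer(max_concurrent_limit),
                 concurrency = concurrency_profile(targets)),
            class = "mrm_schedule")
}

#' @export
print.mrm_schedule <- function(x, ...) {
  cat(sprintf("<mrm_schedule> %d transitions on %s (%g min), cycle %.2f s, max concurrency %d (limit < %d)\n",
              nrow(x$targets), x$gradient$label, x$gradient$length,
              x$cycle_time_s, x$concurrency$max_concurrency,
              x$max_concurrent_limit))
  invisible(x)
}

#' Per-interval dwell-time report
#'
#' With `k` concurrent transitions, each receives
#' `cycle_time_ms / k - interscan_overhead_ms` of dwell. Intervals whose
#' dwell falls below `min_dwell_ms` are flagged.
#'
#' @param schedule An [mrm_schedule()].
#' @param interscan_overhead_ms Per-transition interscan overhead
#'   (default 0.5 ms, a typical QqQ figure).
#' @param min_dwell_ms Feasibility floor (default 5 ms).
#' @return Data frame with `start`, `end`, `count`, `dwell_ms`,
#'   `below_floor` for every interval with at least one transition;
#'   the global minimum dwell is attached as attribute `min_dwell_ms`.
#' @export
dwell_report <- function(schedule, interscan_overhead_ms = 0.5, min_dwell_ms = 5) {
  stopifnot(inherits(schedule, "mrm_schedule"))
  p <- schedule$concurrency
  if (!length(p$counts)) {
    out <- data.frame(start = numeric(0), end = numeric(0), count = integer(0),
                      dwell_ms = numeric(0), below_floor = logical(0))
    attr(out, "min_dwell_ms") <- Inf
    return(out)
  }
  out <- data.frame(start = p$breakpoints,
                    end = c(p$breakpoints[-1L], schedule$gradient$length),
                    count = p$counts)
  out <- out[out$count > 0L, , drop = FALSE]
  out$dwell_ms <- schedule$cycle_time_s * 1000 / out$count - interscan_overhead_ms
  out$below_floor <- out$dwell_ms < min_dwell_ms
  rownames(out) <- NULL
  attr(out, "min_dwell_ms") <- if (nrow(out)) min(out$dwell_ms) else Inf
  out
}

#' Validate a schedule against concurrency and dwell constraints
#'
#' PASS requires a maximum concurrency strictly below the limit
#' ("fewer than" the limit, not "at most") and a minimum dwell time at or
#' above the floor. An empty schedule passes vacuously.
#'
#' @inheritParams dwell_report
#' @return List with `status` ("PASS"/"FAIL"), `max_concurrency`,
#'   `time_of_max`, `min_dwell_ms`, `worst_interval` (row of the dwell
#'   report) and `offending_keys` (targets active in the worst interval).
#' @export
validate_schedule <- function(schedule, interscan_overhead_ms = 0.5,
                              min_dwell_ms = 5) {
  stopifnot(inherits(schedule, "mrm_schedule"))
  p <- schedule$concurrency
  dw <- dwell_report(schedule, interscan_overhead_ms, min_dwell_ms)
  if (!nrow(schedule$targets))
    return(list(status = "PASS", max_concurrency = 0L, time_of_max = NA_real_,
                min_dwell_ms = Inf, worst_interval = NULL,
                offending_keys = character(0)))
  ok <- p$max_concurrency < schedule$max_concurrent_limit &&
    attr(dw, "min_dwell_ms") >= min_dwell_ms
  t0 <- p$time_of_max
  active <- schedule$targets$window_start <= t0 & t0 < schedule$targets$window_end
  worst <- dw[dw$start <= t0 & t0 < dw$end, , drop = FALSE]
  list(status = if (ok) "PASS" else "FAIL",
       max_concurrency = p$max_concurrency,
       time_of_max = t0,
       min_dwell_ms = attr(dw, "min_dwell_ms"),
       worst_interval = if (nrow(worst)) worst[1L, ] else NULL,
       offending_keys = unique(schedule$targets$key[active]))
}

#' Split an infeasible target list into several passing methods
#'
#' Greedy round-robin by retention-time order into `k` methods, with `k`
#' the smallest count for which every method passes
#' [validate_schedule()]. Each target lands in exactly one method.
#'
#' @param targets Windowed targets from [assign_windows()].
#' @param gradient,cycle_time_s,max_concurrent_limit See [mrm_schedule()].
#' @param interscan_overhead_ms,min_dwell_ms See [dwell_report()].
#' @return List of passing `mrm_schedule` objects (length 1 when the
#'   input already passes).
#' @export
split_methods <- function(targets, gradient, cycle_time_s = 1,
                          max_concurrent_limit = 200L,
                          interscan_overhead_ms = 0.5, min_dwell_ms = 5) {
  stopifnot(max_concurrent_limit >= 1L)
  targets <- as.data.frame(targets)
  ord <- order(targets$predicted_rt, targets$precursor_mz, targets$fragment_mz)
  targets <- targets[ord, , drop = FALSE]
  n <- nrow(targets)
  for (k in seq_len(max(n, 1L))) {
    idx <- rep(seq_len(k), length.out = n)
    schedules <- lapply(seq_len(k), function(i)
      mrm_schedule(targets[idx == i, , drop = FALSE], gradient,
                   cycle_time_s, max_concurrent_limit))
    if (all(vapply(schedules, function(s)
      validate_schedule(s, interscan_overhead_ms, min_dwell_ms)$status == "PASS",
      TRUE)))
      return(schedules)
  }
  stop("unable to split targets into passing methods")  # unreachable for limit >= 1
}

fmt_num <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)

compound_name <- function(targets) {
  paste0(targets$modified_peptide, ".", targets$precursor_charge, targets$fragment)
}

#' Export a dynamic-MRM (scheduled) transition list
#'
#' Agilent-style dMRM CSV. `Ret Time (min)` is the centre of the final
#' (possibly boundary-clipped) window and `Delta Ret Time` its full
#' width. Rows are sorted by RT then precursor m/z; m/z at 4 decimals,
#' times at 2.
#'
#' @param schedule A validated [mrm_schedule()].
#' @param path Output path.
#' @param fragmentor,cell_accelerator_voltage,polarity Instrument columns
#'   (vendor-style defaults).
#' @return `path`, invisibly.
#' @export
export_dmrm_csv <- function(schedule, path, fragmentor = 180,
                            cell_accelerator_voltage = 4,
                            polarity = "Positive") {
  stopifnot(inherits(schedule, "mrm_schedule"))
  t <- schedule$targets
  t <- t[order(t$predicted_rt, t$precursor_mz, t$fragment_mz), , drop = FALSE]
  out <- data.frame(
    `Compound Name` = compound_name(t),
    `ISTD?` = "FALSE",
    `Precursor Ion` = fmt_num(t$precursor_mz, 4),
    `MS1 Res` = "Unit",
    `Product Ion` = fmt_num(t$fragment_mz, 4),
    `MS2 Res` = "Unit",
    `Fragmentor` = fragmentor,
    `Collision Energy` = fmt_num(t$collision_energy, 1),
    `Cell Accelerator Voltage` = cell_accelerator_voltage,
    `Ret Time (min)` = fmt_num((t$window_start + t$window_end) / 2, 2),
    `Delta Ret Time` = fmt_num(t$window_end - t$window_start, 2),
    `Polarity` = polarity,
    check.names = FALSE
  )
  if (!nrow(t)) out <- out[0, ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an unscheduled transition list
#'
#' As [export_dmrm_csv()] but with a constant `Dwell (ms)` column in
#' place of the RT window columns — the standard method used to measure
#' reference-peptide RTs on a new gradient.
#'
#' @param targets Target data frame (windows not required).
#' @param dwell_ms Per-transition dwell time in ms (default 25).
#' @param path Output path.
#' @inheritParams export_dmrm_csv
#' @return `path`, invisibly.
#' @export
export_unscheduled_csv <- function(targets, dwell_ms = 25, path,
                                   fragmentor = 180,
                                   cell_accelerator_voltage = 4,
                                   polarity = "Positive") {
  t <- as.data.frame(targets)
  t <- t[order(t$precursor_mz, t$fragment_mz), , drop = FALSE]
  out <- data.frame(
    `Compound Name` = compound_name(t),
    `ISTD?` = "FALSE",
    `Precursor Ion` = fmt_num(t$precursor_mz, 4),
    `MS1 Res` = "Unit",
    `Product Ion` = fmt_num(t$fragment_mz, 4),
    `MS2 Res` = "Unit",
    `Fragmentor` = fragmentor,
    `Collision Energy` = fmt_num(t$collision_energy, 1),
    `Cell Accelerator Voltage` = cell_accelerator_voltage,
    `Dwell (ms)` = fmt_num(rep(dwell_ms, nrow(t)), 1),
    `Polarity` = polarity,
    check.names = FALSE
  )
  if (!nrow(t)) out <- out[0, ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a Skyline-style transition list
#'
#' Columns: `ProteinName`, `PeptideModifiedSequence`, `PrecursorCharge`,
#' `PrecursorMz`, `ProductMz`, `FragmentIon`, `ProductCharge`,
#' `NormalizedRetentionTime` (the iRT value when present, else the
#' library RT).
#'
#' @param targets Target data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_skyline_csv <- function(targets, path) {
  t <- as.data.frame(targets)
  rt <- if ("irt" %in% names(t) && !all(is.na(t$irt))) t$irt else t$rt_min
  ord <- order(rt, t$precursor_mz, t$fragment_mz)
  t <- t[ord, , drop = FALSE]
  out <- data.frame(
    ProteinName = t$protein_ids,
    PeptideModifiedSequence = t$modified_peptide,
    PrecursorCharge = t$precursor_charge,
    PrecursorMz = fmt_num(t$precursor_mz, 4),
    ProductMz = fmt_num(t$fragment_mz, 4),
    FragmentIon = t$fragment,
    ProductCharge = t$fragment_charge,
    NormalizedRetentionTime = fmt_num(rt[ord], 4)
  )
  if (!nrow(t)) out <- out[0, ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Skyline-style transition list
#' @param path CSV written by [export_skyline_csv()].
#' @return Data frame with numeric m/z columns.
#' @export
read_skyline_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("ProteinName", "PeptideModifiedSequence", "PrecursorCharge",
                "PrecursorMz", "ProductMz", "FragmentIon", "ProductCharge",
                "NormalizedRetentionTime")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("transition list is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("PrecursorMz", "ProductMz", "NormalizedRetentionTime"))
    d[[col]] <- as.numeric(d[[col]])
  d
}
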