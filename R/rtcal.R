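# Landmark selection, iRT scale construction, gradient calibration and
# retention-time prediction.

#' Pick landmark reference peptides spanning the gradient
#'
#' Landmarks anchor the empirical retention-time index (iRT). Eligible
#' entries are those whose summed fragment intensity clears an intensity
#' floor (landmarks must be reliably detectable); among them, entries
#' closest to an `n`-point grid over the eligible RT range are chosen, so
#' the earliest and latest eligible RTs are always included and the picks
#' approximately tile the whole elution range. Grid collisions fall back
#' to the next-nearest unused entry with a distinct RT.
#'
#' @param lib A [spectral_library()].
#' @param n Number of landmarks (default 12, the customary minimum for a
#'   stable calibration across a whole gradient).
#' @param min_intensity_quantile Intensity floor as a quantile of the
#'   per-entry summed fragment intensity (default 0.5).
#' @return A `reference_set`: data frame with columns `key`,
#'   `modified_peptide`, `precursor_charge`, `rt_min`, `irt`, sorted by RT.
#'   The iRT values are provisional anchors: 0 for the earliest landmark,
#'   100 for the latest, linear in RT between.
#' @export
pick_landmarks <- function(lib, n = 12L, min_intensity_quantile = 0.5) {
  stopifnot(inherits(lib, "spectral_library"))
  n <- as.integer(n)
  sums <- entry_intensity_sums(lib)
  floor_val <- stats::quantile(sums, min_intensity_quantile, names = FALSE)
  eligible <- lib$entries[sums >= floor_val, , drop = FALSE]
  if (nrow(eligible) < n)
    stop("only ", nrow(eligible), " entries pass the intensity floor; ",
         n, " landmarks requested (short by ", n - nrow(eligible), ")")
  eligible <- eligible[order(eligible$rt_min, eligible$key), , drop = FALSE]
  grid <- seq(min(eligible$rt_min), max(eligible$rt_min), length.out = n)
  chosen <- integer(0)
  for (g in grid) {
    ord <- order(abs(eligible$rt_min - g))
    for (j in ord) {
      if (j %in% chosen) next
      if (any(abs(eligible$rt_min[chosen] - eligible$rt_min[j]) < 1e-12)) next
      chosen <- c(chosen, j)
      break
    }
  }
  refs <- eligible[sort(chosen), c("key", "modified_peptide",
                                   "precursor_charge", "rt_min")]
  rt0 <- min(refs$rt_min); rt1 <- max(refs$rt_min)
  if (rt1 <= rt0) stop("landmarks span zero retention-time range")
  refs$irt <- 100 * (refs$rt_min - rt0) / (rt1 - rt0)
  rownames(refs) <- NULL
  class(refs) <- c("reference_set", class(refs))
  refs
}

#' Assign iRT values to every library entry
#'
#' Fits the reference line RT -> iRT (anchored at 0/100 for the earliest/
#' latest landmark of the calibration run) by least squares and evaluates
#' it at every entry's RT. Entries outside the landmark RT span receive
#' extrapolated values, permitted but flagged in the logical column
#' `irt_extrapolated`.
#'
#' @param lib A [spectral_library()].
#' @param refs A `reference_set` from [pick_landmarks()] drawn from this
#'   library's gradient.
#' @return `lib` with `entries$irt` filled and `entries$irt_extrapolated`
#'   added.
#' @export
assign_irt <- function(lib, refs) {
  stopifnot(inherits(lib, "spectral_library"), inherits(refs, "reference_set"))
  if (diff(range(refs$rt_min)) <= 0)
    stop("reference peptides span zero retention-time range")
  fit <- stats::lm(irt ~ rt_min, data = refs)
  co <- stats::coef(fit)
  lib$entries$irt <- unname(co[1L] + co[2L] * lib$entries$rt_min)
  lib$entries$irt_extrapolated <-
    lib$entries$rt_min < min(refs$rt_min) - 1e-12 |
    lib$entries$rt_min > max(refs$rt_min) + 1e-12
  lib
}

#' Calibrate the iRT scale to a new gradient
#'
#' Ordinary least squares of measured RT on reference iRT, with one
#' robust pass: points with absolute residual above `max_sigma` residual
#' standard deviations are dropped and the line refit once (never below 3
#' points). A usable calibration must have positive slope — a
#' non-positive slope means the gradient order is inverted and is
#' rejected.
#'
#' @param refs A `reference_set` with iRT values (see [pick_landmarks()]).
#' @param measured Data frame of measured RTs in the new gradient with
#'   columns `modified_peptide`, `precursor_charge`, `rt_min` (see
#'   [read_measured_rt_tsv()]), or columns `key`, `rt_min`.
#' @param max_sigma Outlier cut in residual standard deviations (default 3).
#' @return An `rt_calibration`: list with `slope` (min per iRT unit),
#'   `intercept` (min), `r_squared`, `residual_sd` (min), `n_used`,
#'   `rejected` (entry keys dropped by the robust pass).
#' @export
calibrate <- function(refs, measured, max_sigma = 3) {
  stopifnot(inherits(refs, "reference_set"))
  measured <- as.data.frame(measured)
  if (!"key" %in% names(measured))
    measured$key <- entry_key(measured$modified_peptide, measured$precursor_charge)
  m <- merge(refs[, c("key", "irt")], measured[, c("key", "rt_min")], by = "key")
  if (nrow(m) < 2L)
    stop("need >= 2 reference peptides with measured RTs; got ", nrow(m))

  ols <- function(d) {
    fit <- stats::lm(rt_min ~ irt, data = d)
    res <- stats::residuals(fit)
    list(fit = fit,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         residual_sd = if (nrow(d) > 2L) sqrt(sum(res^2) / (nrow(d) - 2L)) else 0,
         res = res)
  }
  pass1 <- ols(m)
  rejected <- character(0)
  final <- pass1
  keep <- rep(TRUE, nrow(m))
  # the robust pass only makes sense when there is real scatter; a floor of
  # 1e-9 min avoids rejecting points off a numerically exact line
  if (pass1$residual_sd > 1e-9) {
    keep <- abs(pass1$res) <= max_sigma * pass1$residual_sd
    if (any(!keep) && sum(keep) >= 3L) {
      rejected <- m$key[!keep]
      final <- ols(m[keep, , drop = FALSE])
    } else keep <- rep(TRUE, nrow(m))
  }
  if (final$slope <= 0)
    stop("calibration slope is not positive; gradient order appears inverted")
  used <- m[keep, , drop = FALSE]
  ss_tot <- sum((used$rt_min - mean(used$rt_min))^2)
  r2 <- if (ss_tot > 0) 1 - sum(final$res^2) / ss_tot else 1
  structure(list(slope = final$slope, intercept = final$intercept,
                 r_squared = max(0, min(1, r2)),
                 residual_sd = final$residual_sd,
                 n_used = nrow(used), rejected = rejected),
            class = "rt_calibration")
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf(
    "<rt_calibration> rt = %.4f + %.6f * irt | r^2 %.5f, residual sd %.4f min, n %d, rejected %d\n",
    x$intercept, x$slope, x$r_squared, x$residual_sd, x$n_used, length(x$rejected)))
  invisible(x)
}

#' Predict retention time on the calibrated gradient
#'
#' `intercept + slope * irt`; negative predictions are clipped to zero
#' and flagged via the logical attribute `clipped`.
#'
#' @param irt Numeric iRT value(s).
#' @param cal An `rt_calibration`.
#' @return Predicted RT(s) in minutes, with attribute `clipped`.
#' @export
predict_rt <- function(irt, cal) {
  stopifnot(inherits(cal, "rt_calibration"))
  rt <- cal$intercept + cal$slope * irt
  clipped <- rt < 0
  rt[clipped] <- 0
  attr(rt, "clipped") <- clipped
  rt
}

#' Read measured reference RTs for a new gradient
#'
#' TSV with columns `modified_peptide`, `precursor_charge`, `rt_min`.
#'
#' @param path Path to the TSV.
#' @return Data frame including a computed `key` column.
#' @export
read_measured_rt_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("modified_peptide", "precursor_charge", "rt_min")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("measured-RT TSV is missing column(s): ", paste(missing, collapse = ", "))
  d$precursor_charge <- as.integer(d$precursor_charge)
  d$rt_min <- as.numeric(d$rt_min)
  d$key <- entry_key(d$modified_peptide, d$precursor_charge)
  d
}

#' Write a calibration report
#'
#' Writes both a human-readable text report and a machine-readable
#' key-value file (`<path>.kv`).
#'
#' @param cal An `rt_calibration`.
#' @param path Output path for the text report.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(cal, path) {
  stopifnot(inherits(cal, "rt_calibration"))
  txt <- c(
    "Retention-time calibration (measured RT = intercept + slope * iRT)",
    sprintf("  slope        : %.6f min per iRT unit", cal$slope),
    sprintf("  intercept    : %.4f min", cal$intercept),
    sprintf("  r_squared    : %.6f", cal$r_squared),
    sprintf("  residual sd  : %.4f min", cal$residual_sd),
    sprintf("  points used  : %d", cal$n_used),
    sprintf("  rejected     : %s",
            if (length(cal$rejected)) paste(cal$rejected, collapse = ", ") else "none"))
  writeLines(txt, path)
  kv <- c(sprintf("slope\t%.10g", cal$slope),
          sprintf("intercept\t%.10g", cal$intercept),
          sprintf("r_squared\t%.10g", cal$r_squared),
          sprintf("residual_sd\t%.10g", cal$residual_sd),
          sprintf("n_used\t%d", cal$n_used),
          sprintf("rejected\t%s", paste(cal$rejected, collapse = ";")))
  writeLines(kv, paste0(path, ".kv"))
  invisible(path)
}
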