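# Matching observed MS/MS peaks to theoretical y/b ions.

# Theoretical y/b ion table for a peptide. Fragment charges follow the
# library convention: 1+ always, 2+ additionally when the precursor is 3+
# or higher.
theoretical_fragments <- function(pep) {
  len <- nchar(pep$sequence)
  charges <- if (pep$charge >= 3L) 1:2 else 1L
  grid <- expand.grid(series = c("y", "b"), index = seq_len(len - 1L),
                      charge = charges, stringsAsFactors = FALSE)
  grid$mz <- mapply(function(s, i, z) fragment_mz(pep, s, i, z),
                    grid$series, grid$index, grid$charge)
  grid
}

#' Annotate an MS/MS spectrum with y/b fragment ions
#'
#' Every theoretical y/b ion of the peptide (fragment charge 1+, and 2+ for
#' precursors of charge 3+ or higher) is matched to the most intense
#' observed peak within `tol_da`. When two theoretical ions claim the same
#' peak, the ion nearer in m/z wins (ties go to the y series); the loser is
#' dropped. Matched intensities are renormalised so the strongest annotated
#' fragment has relative intensity 1.
#'
#' @param peaks Two-column matrix or data frame of `mz`, `intensity`
#'   (any order along m/z).
#' @param pep A [peptide()].
#' @param tol_da Absolute matching tolerance in Da (default 0.1, the usual
#'   MS/MS search tolerance on quadrupole-TOF data).
#' @return Data frame with columns `series`, `index`, `charge`, `mz`
#'   (theoretical), `intensity` (raw matched peak intensity) and
#'   `relative_intensity`, sorted by descending relative intensity.
#'   Empty (zero-row) when no peak matches.
#' @export
annotate_spectrum <- function(peaks, pep, tol_da = 0.1) {
  stopifnot(inherits(pep, "peptide"), tol_da > 0)
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) < 2L) stop("peaks must have mz and intensity columns")
  names(peaks)[1:2] <- c("mz", "intensity")
  theo <- theoretical_fragments(pep)
  empty <- theo[0, c("series", "index", "charge", "mz")]
  empty$intensity <- numeric(0)
  empty$relative_intensity <- numeric(0)
  if (!nrow(peaks)) return(empty)

  # deferred acceptance: each unassigned ion proposes its most intense
  # still-available peak within tolerance; a peak claimed by several ions
  # goes to the nearer one in m/z (numerically exact ties to the y series);
  # losers retry with the remaining peaks. This keeps annotation stable
  # when the tolerance is widened: an ion never loses its match without
  # the winner being closer.
  assigned_peak <- rep(NA_integer_, nrow(theo))
  peak_taken <- rep(FALSE, nrow(peaks))
  unresolved <- seq_len(nrow(theo))
  repeat {
    claims <- do.call(rbind, lapply(unresolved, function(i) {
      d <- abs(peaks$mz - theo$mz[i])
      hit <- which(d <= tol_da & !peak_taken)
      if (!length(hit)) return(NULL)
      best <- hit[which.max(peaks$intensity[hit])]
      data.frame(theo_row = i, peak = best, dmz = d[best])
    }))
    if (is.null(claims)) break
    is_y <- theo$series[claims$theo_row] == "y"
    winners <- unlist(lapply(split(seq_len(nrow(claims)), claims$peak),
                             function(rows) {
      rows[order(round(claims$dmz[rows] * 1e9), !is_y[rows])][1L]
    }))
    assigned_peak[claims$theo_row[winners]] <- claims$peak[winners]
    peak_taken[claims$peak[winners]] <- TRUE
    unresolved <- setdiff(unresolved, claims$theo_row[winners])
    if (!length(unresolved)) break
  }
  hit_rows <- which(!is.na(assigned_peak))
  if (!length(hit_rows)) return(empty)
  out <- theo[hit_rows, c("series", "index", "charge", "mz")]
  out$intensity <- peaks$intensity[assigned_peak[hit_rows]]
  out$relative_intensity <- out$intensity / max(out$intensity)
  out <- out[order(-out$relative_intensity, out$index, out$series != "y", out$charge), ]
  rownames(out) <- NULL
  out
}
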