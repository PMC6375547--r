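# Spectral-library container, construction from PSMs + spectra, TSV I/O.

#' Describe a chromatographic gradient
#'
#' @param length Total analytical gradient duration in minutes.
#' @param label Free-text label (e.g. `"120min_standard_flow"`).
#' @return An object of class `gradient_profile`.
#' @export
gradient_profile <- function(length, label = sprintf("%gmin", length)) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("gradient length must be a single positive number of minutes")
  structure(list(length = as.numeric(length), label = as.character(label)),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient> %s (%g min)\n", x$label, x$length))
  invisible(x)
}

entry_key <- function(modified_peptide, charge) {
  paste(modified_peptide, charge, sep = "/")
}

#' Construct a spectral library
#'
#' A spectral library holds one entry per (modified sequence, precursor
#' charge) with its consensus retention time, precursor m/z and annotated
#' fragment ions, tied to the gradient the retention times were observed
#' on. Invariants are enforced: unique entry keys, non-empty fragment sets
#' with a unique base peak (relative intensity 1), non-negative RTs not
#' exceeding the gradient length, and precursor m/z consistent with the
#' peptide mass to within 0.01 Th.
#'
#' @param entries Data frame with columns `key`, `protein_ids`
#'   (semicolon-joined accessions), `peptide`, `modified_peptide`,
#'   `precursor_charge`, `precursor_mz`, `rt_min`, `irt` (NA when not yet
#'   assigned), `n_spectra`.
#' @param fragments Data frame with columns `key`, `series`, `index`,
#'   `fragment_charge`, `fragment_mz`, `relative_intensity`.
#' @param gradient A [gradient_profile()].
#' @param provenance Free-text metadata string.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(entries, fragments, gradient, provenance = "") {
  stopifnot(inherits(gradient, "gradient_profile"))
  entries <- as.data.frame(entries)
  fragments <- as.data.frame(fragments)
  if (anyDuplicated(entries$key))
    stop("duplicate library entry keys: ",
         paste(unique(entries$key[duplicated(entries$key)]), collapse = ", "))
  if (nrow(entries)) {
    if (any(entries$rt_min < 0)) stop("negative entry retention time")
    if (any(entries$rt_min > gradient$length + 1e-9))
      stop("entry retention time exceeds gradient length (",
           gradient$length, " min)")
    missing_frag <- setdiff(entries$key, fragments$key)
    if (length(missing_frag))
      stop("entries without fragments: ", paste(missing_frag, collapse = ", "))
    base_ok <- vapply(split(fragments$relative_intensity, fragments$key),
                      function(ri) sum(abs(ri - 1) < 1e-6) == 1L, TRUE)
    if (!all(base_ok))
      stop("each entry must have exactly one fragment with relative intensity 1")
    mz_theo <- vapply(seq_len(nrow(entries)), function(i)
      precursor_mz(parse_modified_peptide(entries$modified_peptide[i],
                                          entries$precursor_charge[i])),
      0)
    off <- abs(mz_theo - entries$precursor_mz) > 0.01
    if (any(off))
      stop("precursor m/z inconsistent with peptide mass for: ",
           paste(entries$key[off], collapse = ", "))
  }
  structure(list(entries = entries, fragments = fragments,
                 gradient = gradient, provenance = provenance),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d entries, %d fragment rows, gradient %s (%g min)\n",
              nrow(x$entries), nrow(x$fragments), x$gradient$label, x$gradient$length))
  invisible(x)
}

# Summed annotated fragment intensity per entry key (the "library pick
# intensity" used for peptide ranking and landmark eligibility).
entry_intensity_sums <- function(lib) {
  sums <- vapply(split(lib$fragments$relative_intensity, lib$fragments$key), sum, 0)
  sums[lib$entries$key]
}

#' Summed fragment intensity per library entry
#'
#' The "library pick intensity" used to rank peptides for selection and
#' to gate landmark eligibility: the sum of relative fragment intensities
#' of each entry.
#'
#' @param lib A [spectral_library()].
#' @return Named numeric vector keyed by entry key, in entry order.
#' @export
library_intensity_sums <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  entry_intensity_sums(lib)
}

#' Subset a spectral library by entry keys
#'
#' @param lib A [spectral_library()].
#' @param keys Entry keys to retain.
#' @return A [spectral_library()] restricted to `keys`.
#' @export
subset_library <- function(lib, keys) {
  stopifnot(inherits(lib, "spectral_library"))
  missing <- setdiff(keys, lib$entries$key)
  if (length(missing))
    stop("keys not in library: ", paste(utils::head(missing, 5), collapse = ", "))
  spectral_library(lib$entries[lib$entries$key %in% keys, , drop = FALSE],
                   lib$fragments[lib$fragments$key %in% keys, , drop = FALSE],
                   lib$gradient, lib$provenance)
}

#' Build a spectral library from PSMs and MGF spectra
#'
#' PSMs are grouped by (modified sequence, precursor charge). Each group
#' becomes one library entry: the retention time is the median PSM RT
#' (robust to a stray mis-assigned PSM), the protein set is the union over
#' PSMs, and the fragment pattern is taken from the single PSM whose
#' annotated fragment intensity sum is largest. PSMs whose spectrum
#' reference resolves to no spectrum are skipped and counted.
#'
#' @param psms PSM data frame (see [read_psm_tsv()]) or path to a PSM TSV.
#' @param spectra Spectrum list from [read_mgf()] or path to an MGF file.
#'   `spectrum_ref` is matched against MGF TITLEs first, then interpreted
#'   as a 1-based ordinal when entirely numeric.
#' @param gradient A [gradient_profile()] for the acquisition run(s).
#' @param tol_da Fragment-annotation tolerance in Da (default 0.1).
#' @return A [spectral_library()]. The number of skipped PSMs is attached
#'   as attribute `n_skipped`.
#' @export
build_library <- function(psms, spectra, gradient, tol_da = 0.1) {
  if (is.character(psms)) psms <- read_psm_tsv(psms)
  if (is.character(spectra)) spectra <- read_mgf(spectra)
  titles <- vapply(spectra, function(s) s$title %||% NA_character_, "")

  resolve <- function(ref) {
    hit <- which(!is.na(titles) & titles == ref)
    if (length(hit)) return(hit[1L])
    if (grepl("^[0-9]+$", ref)) {
      i <- as.integer(ref)
      if (i >= 1L && i <= length(spectra)) return(i)
    }
    NA_integer_
  }
  psms$spec_idx <- vapply(as.character(psms$spectrum_ref), resolve, 1L)
  n_skipped <- sum(is.na(psms$spec_idx))
  if (n_skipped)
    message(n_skipped, " PSM(s) skipped: spectrum reference not resolvable")
  psms <- psms[!is.na(psms$spec_idx), , drop = FALSE]
  if (!nrow(psms)) stop("no usable PSMs: every spectrum reference failed to resolve")

  psms$key <- entry_key(psms$modified_peptide, psms$charge)
  # canonical processing order: key, then RT, for order-invariant output
  psms <- psms[order(psms$key, psms$rt_min, psms$spec_idx), , drop = FALSE]

  entries <- list()
  fragments <- list()
  for (key in unique(psms$key)) {
    grp <- psms[psms$key == key, , drop = FALSE]
    pep <- parse_modified_peptide(grp$modified_peptide[1L], grp$charge[1L])
    anns <- lapply(grp$spec_idx, function(i)
      annotate_spectrum(spectra[[i]]$peaks, pep, tol_da))
    sums <- vapply(anns, function(a) if (nrow(a)) sum(a$intensity) else 0, 0)
    if (max(sums) == 0) next  # nothing annotated for this peptide
    best <- anns[[which.max(sums)]]
    prots <- sort(unique(unlist(strsplit(grp$protein_ids, ";", fixed = TRUE))))
    entries[[key]] <- data.frame(
      key = key,
      protein_ids = paste(prots, collapse = ";"),
      peptide = pep$sequence,
      modified_peptide = grp$modified_peptide[1L],
      precursor_charge = grp$charge[1L],
      precursor_mz = precursor_mz(pep),
      rt_min = stats::median(grp$rt_min),
      irt = NA_real_,
      n_spectra = nrow(grp)
    )
    fragments[[key]] <- data.frame(
      key = key, series = best$series, index = best$index,
      fragment_charge = best$charge, fragment_mz = best$mz,
      relative_intensity = best$relative_intensity
    )
  }
  if (!length(entries)) stop("no usable PSMs: no spectrum produced any fragment annotation")
  lib <- spectral_library(do.call(rbind, entries), do.call(rbind, fragments),
                          gradient, provenance = "built from PSMs + MGF")
  attr(lib, "n_skipped") <- n_skipped
  lib
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

LIBRARY_TSV_COLUMNS <- c("protein_ids", "peptide", "modified_peptide",
                         "precursor_charge", "precursor_mz", "rt_min", "irt",
                         "fragment", "fragment_charge", "fragment_mz",
                         "relative_intensity", "n_spectra")

#' Write a spectral library to TSV
#'
#' One row per fragment; m/z and RT values are written at 4 decimal
#' places. Column layout is fixed (see [read_library_tsv()]).
#'
#' @param lib A [spectral_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  rows <- merge(lib$fragments, lib$entries, by = "key", sort = FALSE)
  rows <- rows[order(rows$key, -rows$relative_intensity, rows$index, rows$series != "y"), ]
  out <- data.frame(
    protein_ids = rows$protein_ids,
    peptide = rows$peptide,
    modified_peptide = rows$modified_peptide,
    precursor_charge = rows$precursor_charge,
    precursor_mz = sprintf("%.4f", rows$precursor_mz),
    rt_min = sprintf("%.4f", rows$rt_min),
    irt = ifelse(is.na(rows$irt), "", sprintf("%.4f", rows$irt)),
    fragment = paste0(rows$series, rows$index),
    fragment_charge = rows$fragment_charge,
    fragment_mz = sprintf("%.4f", rows$fragment_mz),
    relative_intensity = sprintf("%.6f", rows$relative_intensity),
    n_spectra = rows$n_spectra
  )
  if (!nrow(rows)) out <- out[0, ]
  # header even for an empty library
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectral library from TSV
#'
#' Expects exactly the columns written by [write_library_tsv()]:
#' `protein_ids`, `peptide`, `modified_peptide`, `precursor_charge`,
#' `precursor_mz`, `rt_min`, `irt`, `fragment`, `fragment_charge`,
#' `fragment_mz`, `relative_intensity`, `n_spectra`. Fragment m/z values
#' are cross-checked against theoretical values recomputed from the
#' modified sequence; rows off by more than 0.01 Th trigger a warning.
#'
#' @param path Path to a library TSV.
#' @param gradient A [gradient_profile()] for the library's RT axis. When
#'   `NULL`, a gradient just covering the observed RTs is assumed.
#' @return A [spectral_library()].
#' @export
read_library_tsv <- function(path, gradient = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing <- setdiff(LIBRARY_TSV_COLUMNS, names(raw))
  if (length(missing))
    stop("library TSV is missing column(s): ", paste(missing, collapse = ", "))
  num <- function(col, allow_na = FALSE) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !(allow_na & (is.na(raw[[col]]) | raw[[col]] == ""))
    if (any(bad))
      stop("malformed value in column '", col, "' at line ",
           paste(which(bad) + 1L, collapse = ", "))  # +1 for the header line
    x
  }
  if (!nrow(raw)) {
    g <- gradient %||% gradient_profile(1, "empty")
    return(spectral_library(
      data.frame(key = character(0), protein_ids = character(0),
                 peptide = character(0), modified_peptide = character(0),
                 precursor_charge = integer(0), precursor_mz = numeric(0),
                 rt_min = numeric(0), irt = numeric(0), n_spectra = integer(0)),
      data.frame(key = character(0), series = character(0), index = integer(0),
                 fragment_charge = integer(0), fragment_mz = numeric(0),
                 relative_intensity = numeric(0)),
      g, provenance = path))
  }
  frag_ok <- grepl("^[yb][0-9]+$", raw$fragment)
  if (!all(frag_ok))
    stop("malformed fragment label at line ",
         paste(which(!frag_ok) + 1L, collapse = ", "))
  rows <- data.frame(
    key = entry_key(raw$modified_peptide, as.integer(num("precursor_charge"))),
    protein_ids = raw$protein_ids,
    peptide = raw$peptide,
    modified_peptide = raw$modified_peptide,
    precursor_charge = as.integer(num("precursor_charge")),
    precursor_mz = num("precursor_mz"),
    rt_min = num("rt_min"),
    irt = num("irt", allow_na = TRUE),
    series = substr(raw$fragment, 1, 1),
    index = as.integer(sub("^[yb]", "", raw$fragment)),
    fragment_charge = as.integer(num("fragment_charge")),
    fragment_mz = num("fragment_mz"),
    relative_intensity = num("relative_intensity"),
    n_spectra = as.integer(num("n_spectra"))
  )
  mz_theo <- vapply(seq_len(nrow(rows)), function(i)
    fragment_mz(parse_modified_peptide(rows$modified_peptide[i],
                                       rows$precursor_charge[i]),
                rows$series[i], rows$index[i], rows$fragment_charge[i]), 0)
  off <- which(abs(mz_theo - rows$fragment_mz) > 0.01)
  if (length(off))
    warning("fragment m/z disagrees with theoretical value by > 0.01 Th at line ",
            paste(off + 1L, collapse = ", "))
  first <- !duplicated(rows$key)
  entries <- rows[first, c("key", "protein_ids", "peptide", "modified_peptide",
                           "precursor_charge", "precursor_mz", "rt_min", "irt",
                           "n_spectra")]
  fragments <- rows[, c("key", "series", "index", "fragment_charge",
                        "fragment_mz", "relative_intensity")]
  rownames(entries) <- rownames(fragments) <- NULL
  g <- gradient %||% gradient_profile(max(entries$rt_min) + 1e-9 + 1,
                                      "inferred_from_rts")
  spectral_library(entries, fragments, g, provenance = path)
}
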