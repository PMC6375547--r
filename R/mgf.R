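# Reading Mascot generic format (MGF) peak lists and PSM tables.
# MGF is parsed directly: it is a line-oriented text format (BEGIN IONS /
# key=value headers / mz-intensity pairs) with no established R reader.

#' Read an MGF peak-list file
#'
#' Standard `BEGIN IONS`/`END IONS` blocks. `TITLE`, `PEPMASS`, `CHARGE`
#' and `RTINSECONDS` headers are honoured; retention times are converted
#' to minutes. Unknown headers are ignored.
#'
#' @param path Path to an MGF file.
#' @return List of spectra; each element is a list with `title`, `rt_min`
#'   (NA when absent), `pepmass`, `charge` and `peaks` (data frame `mz`,
#'   `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  lapply(seq_along(begins), function(k) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "#")]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    kv <- regmatches(headers, regexpr("=", headers), invert = TRUE)
    vals <- vapply(kv, `[`, "", 2L)
    names(vals) <- vapply(kv, `[`, "", 1L)
    peak_lines <- block[!is_header]
    peaks <- if (length(peak_lines)) {
      m <- do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"), function(x)
        as.numeric(x[1:2])))
      data.frame(mz = m[, 1L], intensity = m[, 2L])
    } else data.frame(mz = numeric(0), intensity = numeric(0))
    list(
      title = unname(vals["TITLE"]),
      rt_min = if (!is.na(vals["RTINSECONDS"])) as.numeric(vals["RTINSECONDS"]) / 60 else NA_real_,
      pepmass = if (!is.na(vals["PEPMASS"])) as.numeric(strsplit(vals[["PEPMASS"]], "[ \t]+")[[1L]][1L]) else NA_real_,
      charge = if (!is.na(vals["CHARGE"])) as.integer(sub("[+-]$", "", vals[["CHARGE"]])) else NA_integer_,
      peaks = peaks
    )
  })
}

#' Read a PSM (peptide-spectrum match) table
#'
#' Tab-separated, UTF-8, '.' decimal. Required columns: `spectrum_ref`,
#' `peptide`, `modified_peptide`, `charge`, `protein_ids`, `rt_min`;
#' `score` is optional.
#'
#' @param path Path to the PSM TSV.
#' @return Data frame with one row per PSM.
#' @export
read_psm_tsv <- function(path) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("spectrum_ref", "peptide", "modified_peptide", "charge",
                "protein_ids", "rt_min")
  missing <- setdiff(required, names(psms))
  if (length(missing))
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "))
  psms$charge <- as.integer(psms$charge)
  psms$rt_min <- as.numeric(psms$rt_min)
  psms
}
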