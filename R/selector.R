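# Assay-suitability filtering and top-N peptide/transition selection.

#' Selection rules for assay-suitable peptides and transitions
#'
#' Defaults encode common targeted-proteomics practice: fully tryptic
#' peptides of 6-25 residues with no missed cleavage and no variable
#' modification, precursor charges 2+/3+, y-series fragments of index >= 3
#' (y1/y2 are low-specificity), the top 5 peptides per protein and the top
#' 6 fragment ions per peptide by library intensity. Carbamidomethyl C is
#' a fixed modification and never counts as variable.
#'
#' @param min_length,max_length Peptide length bounds in residues.
#' @param max_missed_cleavages Maximum internal K/R (not before P) left uncut.
#' @param allow_variable_mods Keep entries carrying variable modifications?
#' @param allowed_precursor_charges Retained precursor charge states.
#' @param require_proteotypic Keep only peptides mapping to exactly one
#'   protein within the library?
#' @param peptides_per_protein,fragments_per_peptide Top-N caps.
#' @param min_fragment_index Smallest fragment ordinal retained.
#' @param series_allowed Fragment series retained, subset of `c("y", "b")`.
#' @return An object of class `selection_rules`.
#' @export
selection_rules <- function(min_length = 6L, max_length = 25L,
                            max_missed_cleavages = 0L,
                            allow_variable_mods = FALSE,
                            allowed_precursor_charges = c(2L, 3L),
                            require_proteotypic = TRUE,
                            peptides_per_protein = 5L,
                            fragments_per_peptide = 6L,
                            min_fragment_index = 3L,
                            series_allowed = "y") {
  if (min_length < 4L) stop("min_length must be >= 4")
  if (peptides_per_protein < 1L || fragments_per_peptide < 1L)
    stop("top-N caps must be >= 1")
  if (!all(series_allowed %in% c("y", "b"))) stop("series_allowed must be y and/or b")
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 allow_variable_mods = isTRUE(allow_variable_mods),
                 allowed_precursor_charges = as.integer(allowed_precursor_charges),
                 require_proteotypic = isTRUE(require_proteotypic),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 fragments_per_peptide = as.integer(fragments_per_peptide),
                 min_fragment_index = as.integer(min_fragment_index),
                 series_allowed = series_allowed),
            class = "selection_rules")
}

#' Count missed tryptic cleavages in a sequence
#'
#' A missed cleavage is an internal K or R not followed by P (trypsin does
#' not cleave K/R-P bonds, and a C-terminal K/R is a completed cleavage).
#'
#' @param sequence Canonical amino-acid string.
#' @return Integer count.
#' @examples
#' count_missed_cleavages("AKRPK") # 1: K2 counts, R3 is before P, K5 terminal
#' @export
count_missed_cleavages <- function(sequence) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  if (n < 2L) return(0L)
  internal <- seq_len(n - 1L)
  sum(residues[internal] %in% c("K", "R") & residues[internal + 1L] != "P")
}

has_variable_mods <- function(modified_peptide) {
  grepl("[", modified_peptide, fixed = TRUE)
}

#' Filter library entries to assay-suitable candidates
#'
#' Retains entries passing all rules: length bounds, missed-cleavage cap,
#' absence of variable modifications (when disallowed), allowed precursor
#' charge, and — when required — proteotypicity, i.e. the entry maps to a
#' single protein and its sequence occurs under no other protein anywhere
#' in the library.
#'
#' @param lib A [spectral_library()].
#' @param rules A [selection_rules()].
#' @return The candidate subset of `lib$entries` (possibly zero rows).
#' @export
filter_candidates <- function(lib, rules = selection_rules()) {
  stopifnot(inherits(lib, "spectral_library"), inherits(rules, "selection_rules"))
  e <- lib$entries
  if (!nrow(e)) stop("library is empty")
  len <- nchar(e$peptide)
  keep <- len >= rules$min_length & len <= rules$max_length
  keep <- keep & vapply(e$peptide, count_missed_cleavages, 0L) <= rules$max_missed_cleavages
  if (!rules$allow_variable_mods)
    keep <- keep & !has_variable_mods(e$modified_peptide)
  keep <- keep & e$precursor_charge %in% rules$allowed_precursor_charges
  if (rules$require_proteotypic) {
    # union of proteins per sequence across the whole library
    prot_by_seq <- lapply(split(e$protein_ids, e$peptide), function(p)
      unique(unlist(strsplit(p, ";", fixed = TRUE))))
    n_prot <- vapply(prot_by_seq[e$peptide], length, 0L)
    keep <- keep & n_prot == 1L
  }
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select top peptides and transitions per protein
#'
#' Implements the standard library-driven pick: per protein, peptides are
#' ranked by summed annotated fragment intensity (descending) and the top
#' `peptides_per_protein` distinct peptides kept; per peptide, fragments
#' are restricted to the allowed series with index >=
#' `min_fragment_index`, ranked by relative intensity, and the top
#' `fragments_per_peptide` kept. All ties break deterministically:
#' peptides by (intensity, shorter sequence, modified sequence,
#' lower charge), fragments by (intensity, lower index, y before b).
#' Fragments whose m/z falls within `precursor_exclusion_th` of the
#' precursor m/z are excluded (they would be swamped by precursor
#' interference on a QqQ).
#'
#' @param lib A [spectral_library()].
#' @param rules A [selection_rules()].
#' @param candidates Optional pre-filtered candidate entries (defaults to
#'   [filter_candidates()] on `lib`).
#' @param ce_params Collision-energy model from [ce_defaults()].
#' @param precursor_exclusion_th Minimum |fragment m/z - precursor m/z| in
#'   Th (default 0.2).
#' @return A `target_set`: data frame with one row per transition
#'   (`protein_ids`, `peptide`, `modified_peptide`, `precursor_charge`,
#'   `precursor_mz`, `rt_min`, `irt`, `fragment`, `fragment_charge`,
#'   `fragment_mz`, `relative_intensity`, `library_intensity_rank`,
#'   `collision_energy`, `key`). Proteins contributing zero surviving
#'   peptides are listed in attribute `uncovered_proteins`.
#' @export
select_targets <- function(lib, rules = selection_rules(),
                           candidates = NULL, ce_params = ce_defaults(),
                           precursor_exclusion_th = 0.2) {
  stopifnot(inherits(lib, "spectral_library"))
  if (is.null(candidates)) candidates <- filter_candidates(lib, rules)
  all_proteins <- sort(unique(unlist(strsplit(lib$entries$protein_ids, ";",
                                              fixed = TRUE))))
  out <- list()
  if (nrow(candidates)) {
    cand <- candidates
    cand$intensity_sum <- entry_intensity_sums(lib)[cand$key]
    # deterministic global order: protein group, then peptide rank
    cand <- cand[order(cand$protein_ids, -cand$intensity_sum,
                       nchar(cand$peptide), cand$modified_peptide,
                       cand$precursor_charge), , drop = FALSE]
    for (prot in unique(cand$protein_ids)) {
      grp <- cand[cand$protein_ids == prot, , drop = FALSE]
      grp <- grp[!duplicated(grp$modified_peptide), , drop = FALSE]  # best charge state per peptide
      grp <- utils::head(grp, rules$peptides_per_protein)
      for (i in seq_len(nrow(grp))) {
        fr <- lib$fragments[lib$fragments$key == grp$key[i], , drop = FALSE]
        fr <- fr[fr$series %in% rules$series_allowed &
                 fr$index >= rules$min_fragment_index &
                 abs(fr$fragment_mz - grp$precursor_mz[i]) >= precursor_exclusion_th, ,
                 drop = FALSE]
        if (!nrow(fr)) next
        fr <- fr[order(-fr$relative_intensity, fr$index, fr$series != "y"), , drop = FALSE]
        fr <- utils::head(fr, rules$fragments_per_peptide)
        out[[length(out) + 1L]] <- data.frame(
          protein_ids = prot,
          peptide = grp$peptide[i],
          modified_peptide = grp$modified_peptide[i],
          precursor_charge = grp$precursor_charge[i],
          precursor_mz = grp$precursor_mz[i],
          rt_min = grp$rt_min[i],
          irt = grp$irt[i],
          fragment = paste0(fr$series, fr$index),
          fragment_charge = fr$fragment_charge,
          fragment_mz = fr$fragment_mz,
          relative_intensity = fr$relative_intensity,
          library_intensity_rank = seq_len(nrow(fr)),
          collision_energy = collision_energy(grp$precursor_mz[i],
                                              grp$precursor_charge[i], ce_params),
          key = grp$key[i]
        )
      }
    }
  }
  targets <- if (length(out)) do.call(rbind, out) else data.frame(
    protein_ids = character(0), peptide = character(0),
    modified_peptide = character(0), precursor_charge = integer(0),
    precursor_mz = numeric(0), rt_min = numeric(0), irt = numeric(0),
    fragment = character(0), fragment_charge = integer(0),
    fragment_mz = numeric(0), relative_intensity = numeric(0),
    library_intensity_rank = integer(0), collision_energy = numeric(0),
    key = character(0))
  rownames(targets) <- NULL
  covered <- unique(unlist(strsplit(targets$protein_ids, ";", fixed = TRUE)))
  attr(targets, "uncovered_proteins") <- setdiff(all_proteins, covered)
  class(targets) <- c("target_set", class(targets))
  targets
}

#' Write a target set to TSV
#' @param targets A `target_set` from [select_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_tsv <- function(targets, path) {
  cols <- c("protein_ids", "modified_peptide", "precursor_charge",
            "precursor_mz", "fragment", "fragment_charge", "fragment_mz",
            "library_intensity_rank")
  out <- as.data.frame(targets)[, cols]
  out$precursor_mz <- sprintf("%.4f", out$precursor_mz)
  out$fragment_mz <- sprintf("%.4f", out$fragment_mz)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
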