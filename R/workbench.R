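# Evaluation utilities: cross-instrument fragment-rank agreement,
# protein-level peak-area roll-up, two-group comparison with BH control.

#' Fraction of top-k fragment labels shared between two library entries
#'
#' Used to compare fragmentation patterns of the same peptide across
#' instruments or libraries: fragments are identified by (series, index,
#' charge), each entry's top-`k` by relative intensity is taken, and the
#' overlap fraction returned. When an entry carries fewer than `k`
#' fragments, `k` is lowered to the available minimum with a message.
#'
#' @param frags_a,frags_b Fragment data frames of the two entries
#'   (columns `series`, `index`, `fragment_charge`, `relative_intensity`),
#'   e.g. subsets of `lib$fragments`.
#' @param k Depth of the comparison (default 3).
#' @return Overlap fraction in `[0, 1]`, with attribute `k_used`.
#' @export
fragment_rank_overlap <- function(frags_a, frags_b, k = 3L) {
  top <- function(f, k) {
    f <- as.data.frame(f)
    f <- f[order(-f$relative_intensity, f$index, f$series != "y"), , drop = FALSE]
    paste0(f$series, f$index, "^", f$fragment_charge)[seq_len(k)]
  }
  k_used <- min(k, nrow(as.data.frame(frags_a)), nrow(as.data.frame(frags_b)))
  if (k_used < 1L) stop("both entries must carry at least one fragment")
  if (k_used < k) message("fewer than ", k, " fragments available; using k = ", k_used)
  out <- length(intersect(top(frags_a, k_used), top(frags_b, k_used))) / k_used
  attr(out, "k_used") <- k_used
  out
}

#' Roll peptide peak areas up to protein level
#'
#' Sums peptide areas per protein and replicate — the summed-peptide-area
#' protein quantity used for downstream comparison. Missing
#' peptide-replicate pairs are treated as absent, never zero-imputed;
#' proteins with unequal peptide counts across replicates are flagged in
#' the attribute `incomplete_proteins`.
#'
#' @param areas Data frame with columns `protein_ids`, `modified_peptide`,
#'   `replicate`, `area` (and optionally `group`, carried through).
#' @return Data frame `protein_ids`, `replicate` (+ `group`), `area`.
#' @export
rollup_protein_area <- function(areas) {
  areas <- as.data.frame(areas)
  required <- c("protein_ids", "modified_peptide", "replicate", "area")
  missing <- setdiff(required, names(areas))
  if (length(missing))
    stop("area table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(areas$area < 0)
  if (length(bad))
    stop("negative peak area at row ", paste(bad, collapse = ", "))
  keys <- c("protein_ids", "replicate", intersect("group", names(areas)))
  out <- stats::aggregate(areas["area"], by = areas[keys], FUN = sum)
  out <- out[do.call(order, out[keys]), c(keys, "area"), drop = FALSE]
  rownames(out) <- NULL
  npep <- stats::aggregate(list(n = areas$modified_peptide),
                           by = areas[c("protein_ids", "replicate")],
                           FUN = function(x) length(unique(x)))
  rng <- vapply(split(npep$n, npep$protein_ids), function(x)
    diff(range(x)), 0)
  attr(out, "incomplete_proteins") <- names(rng)[rng > 0]
  out
}

#' Two-group protein comparison with BH-adjusted Welch tests
#'
#' Welch two-sample t-tests on log2 protein areas, with
#' Benjamini-Hochberg step-up adjustment over all tested proteins and
#' significance stars at adjusted 0.05 / 0.01 / 0.001. This is a plain
#' Welch test, not an empirical-Bayes moderated statistic; the output
#' header says so, so results are not misread. Proteins with zero or
#' absent areas, or with fewer than 2 replicates in either group, are
#' excluded and listed in the attribute `excluded_proteins`.
#'
#' @param areas Protein-level area table from [rollup_protein_area()]
#'   with a `group` column.
#' @param group_a,group_b The two group labels; fold change is
#'   `log2(mean B) - log2(mean A)` on the log2 scale (B over A).
#' @return Data frame `protein_ids`, `log2fc`, `p`, `p_adj`, `stars`,
#'   sorted by `p_adj`; attribute `test` records the statistic used.
#' @export
two_group_compare <- function(areas, group_a, group_b) {
  areas <- as.data.frame(areas)
  if (!"group" %in% names(areas)) stop("area table needs a 'group' column")
  areas <- areas[areas$group %in% c(group_a, group_b), , drop = FALSE]
  excluded <- character(0)
  rows <- list()
  for (prot in unique(areas$protein_ids)) {
    d <- areas[areas$protein_ids == prot, ]
    a <- d$area[d$group == group_a]
    b <- d$area[d$group == group_b]
    if (length(a) < 2L || length(b) < 2L || any(c(a, b) <= 0) || anyNA(c(a, b))) {
      excluded <- c(excluded, prot)
      next
    }
    la <- log2(a); lb <- log2(b)
    p <- if (stats::var(la) == 0 && stats::var(lb) == 0) {
      if (mean(lb) == mean(la)) 1 else 0
    } else stats::t.test(lb, la, var.equal = FALSE)$p.value
    rows[[prot]] <- data.frame(protein_ids = prot,
                               log2fc = mean(lb) - mean(la), p = p)
  }
  if (!length(rows)) stop("no protein is testable in both groups")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$stars <- cut(out$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  out <- out[order(out$p_adj, out$protein_ids), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_proteins") <- excluded
  attr(out, "test") <- "Welch two-sample t-test on log2 areas (not moderated)"
  out
}

#' Write a comparison report TSV
#' @param comparison Output of [two_group_compare()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# test: ", attr(comparison, "test")), con)
  utils::write.table(comparison, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
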