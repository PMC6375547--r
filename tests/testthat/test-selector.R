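test_that("missed-cleavage counting follows the trypsin rule", {
  expect_equal(count_missed_cleavages("AK"), 0L)       # terminal K completes cleavage
  expect_equal(count_missed_cleavages("AKRPK"), 1L)    # K2 counts; R3 is before P
  expect_equal(count_missed_cleavages("PEPTIDE"), 0L)
  expect_equal(count_missed_cleavages("KRK"), 2L)
})

test_that("candidate filtering enforces every rule independently", {
  entries <- list(
    make_entry("AGSPVTLNDE", rt = 10, protein = "P1"),                 # clean
    make_entry("AGSPM[+15.99491]TLNDE", rt = 12, protein = "P1",
               modified = "AGSPM[+15.99491]TLNDE"),                    # oxidised
    make_entry("AGSPV", rt = 14, protein = "P1"),                      # too short
    make_entry("AGSPKVTLNDE", rt = 16, protein = "P1"),                # missed cleavage
    make_entry("AGSPVTLNDEQ", rt = 18, protein = "P1", charge = 4L),   # 4+ excluded
    make_entry("SHAEDPEPTVV", rt = 20, protein = "P1;P2")              # not proteotypic
  )
  lib <- make_library(entries)
  kept <- filter_candidates(lib, selection_rules())
  expect_identical(kept$peptide, "AGSPVTLNDE")
  # each relaxation readmits exactly the matching entry
  expect_true("AGSPM[+15.99491]TLNDE" %in%
    filter_candidates(lib, selection_rules(allow_variable_mods = TRUE))$modified_peptide)
  expect_true("AGSPV" %in%
    filter_candidates(lib, selection_rules(min_length = 4))$peptide)
  expect_true("AGSPKVTLNDE" %in%
    filter_candidates(lib, selection_rules(max_missed_cleavages = 1))$peptide)
  expect_true("AGSPVTLNDEQ" %in%
    filter_candidates(lib, selection_rules(allowed_precursor_charges = 2:4))$peptide)
  expect_true("SHAEDPEPTVV" %in%
    filter_candidates(lib, selection_rules(require_proteotypic = FALSE))$peptide)
})

test_that("a shared sequence under two entries defeats proteotypicity for both", {
  entries <- list(make_entry("AGSPVTLNDE", rt = 10, protein = "P1"),
                  make_entry("AGSPVTLNDE", rt = 11, protein = "P2", charge = 3L))
  lib <- make_library(entries)
  expect_equal(nrow(filter_candidates(lib, selection_rules())), 0)
})

test_that("relaxing any single rule never shrinks the candidate set", {
  lib <- simulate_library(generate_proteome(6, 300, seed = 3),
                          gradient_profile(120), seed = 3)$library
  base <- selection_rules()
  n0 <- nrow(filter_candidates(lib, base))
  relaxed <- list(
    selection_rules(min_length = 4),
    selection_rules(max_length = 40),
    selection_rules(max_missed_cleavages = 1),
    selection_rules(allow_variable_mods = TRUE),
    selection_rules(allowed_precursor_charges = 1:4),
    selection_rules(require_proteotypic = FALSE))
  for (r in relaxed)
    expect_gte(nrow(filter_candidates(lib, r)), n0)
})

# one protein, 8 eligible peptides with 10 y-ions each; summed intensity
# strictly decreases with the peptide index, so peptides 1..5 are the
# expected top five
eight_peptide_library <- function() {
  seqs <- synthetic_sequences(8, len = 12L)
  entries <- lapply(seq_along(seqs), function(i)
    make_entry(seqs[i], rt = 10 * i, protein = "PROT1", n_frag = 10L,
               intensities = c(1, seq(0.9, 0.1, length.out = 9) * (1 - 0.05 * i))))
  make_library(entries)
}

test_that("default selection keeps the top 5 peptides and top 6 fragments", {
  lib <- eight_peptide_library()
  targets <- select_targets(lib)
  expect_equal(length(unique(targets$key)), 5L)
  expect_true(all(table(targets$key) == 6L))
  # the five highest summed-intensity peptides are the ones kept
  sums <- sort(library_intensity_sums(lib), decreasing = TRUE)
  expect_setequal(unique(targets$key), names(sums)[1:5])
  # fragments restricted to y-series with index >= 3
  expect_true(all(grepl("^y", targets$fragment)))
  expect_true(all(as.integer(sub("^y", "", targets$fragment)) >= 3L))
  # per-peptide ranks are 1..6 by descending library intensity
  for (k in unique(targets$key)) {
    tk <- targets[targets$key == k, ]
    expect_identical(tk$library_intensity_rank, 1:6)
    expect_true(all(diff(tk$relative_intensity) <= 0))
  }
})

test_that("a protein with fewer candidates than the cap is not padded", {
  entries <- list(make_entry("AGSPVTLNDE", rt = 10, protein = "P1"),
                  make_entry("TTSPVTLNDE", rt = 30, protein = "P1"))
  targets <- select_targets(make_library(entries))
  expect_equal(length(unique(targets$key)), 2L)
})

test_that("fragment ties break to the lower index, then y before b", {
  e <- make_entry("AGSPVTLNDEFW", rt = 10, n_frag = 11L,
                  intensities = c(1, rep(0.5, 10)))
  # add b-series duplicates of two y-ion intensities
  pep <- peptide("AGSPVTLNDEFW", charge = 2)
  b <- data.frame(key = e$entry$key, series = "b", index = 4:5,
                  fragment_charge = 1L,
                  fragment_mz = c(fragment_mz(pep, "b", 4), fragment_mz(pep, "b", 5)),
                  relative_intensity = 0.5)
  e$fragments <- rbind(e$fragments, b)
  lib <- make_library(list(e))
  t_yb <- select_targets(lib, selection_rules(series_allowed = c("y", "b"),
                                              fragments_per_peptide = 4L))
  # rank 1 is the base peak y1? no: index floor is 3, so candidates are
  # y3..y11 at 0.5 and b4/b5 at 0.5 -> lower index first, y before b
  expect_identical(t_yb$fragment, c("y3", "y4", "b4", "y5"))
})

test_that("selection output is identical under input row permutation", {
  lib <- eight_peptide_library()
  perm <- sample(nrow(lib$entries))
  lib2 <- spectral_library(lib$entries[perm, ],
                           lib$fragments[sample(nrow(lib$fragments)), ],
                           lib$gradient)
  t1 <- select_targets(lib)
  t2 <- select_targets(lib2)
  rownames(t1) <- rownames(t2) <- NULL
  expect_identical(t1, t2)
})

test_that("transition count per protein respects the caps", {
  lib <- simulate_library(generate_proteome(4, 350, seed = 9),
                          gradient_profile(120), seed = 9)$library
  targets <- select_targets(lib)
  per_prot <- table(targets$protein_ids)
  rules <- selection_rules()
  expect_true(all(per_prot <= rules$peptides_per_protein * rules$fragments_per_peptide))
  # uncovered proteins are reported, not errors
  expect_type(attr(targets, "uncovered_proteins"), "character")
})
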