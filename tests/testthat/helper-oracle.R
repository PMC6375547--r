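# Independent oracles, coded from first principles rather than through the
# package's own mass table.

# Monoisotopic element masses (Da)
.EL <- c(H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
         S = 31.97207069)

# Residue elemental compositions (residue = amino acid minus water)
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1), N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3), Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1), R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2), W = c(C = 11, H = 10, N = 2, O = 1)
)

.formula_mass <- function(f) sum(.EL[names(f)] * f)

# Neutral monoisotopic mass from elemental composition; carbamidomethyl on
# every C (adds C2H3NO) plus explicit modification deltas.
oracle_peptide_mass <- function(sequence, mod_deltas = numeric(0)) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- sum(vapply(residues, function(r) .formula_mass(.RESIDUE_FORMULA[[r]]), 0))
  m <- m + sum(residues == "C") * .formula_mass(c(C = 2, H = 3, N = 1, O = 1))
  m + sum(mod_deltas) + .formula_mass(c(H = 2, O = 1))
}

# Benjamini-Hochberg step-up adjustment, written out explicitly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force maximum window concurrency: direct counting on a fine grid,
# augmented with the window starts themselves (the count only changes at a
# start, so this is exhaustive for half-open windows).
oracle_max_concurrency <- function(starts, ends, step = 0.001) {
  grid <- c(seq(min(starts) - step, max(ends) + step, by = step), starts)
  counts <- colSums(outer(starts, grid, "<=") & outer(ends, grid, ">"))
  max(counts)
}

random_peptide_sequence <- function(min_len = 6, max_len = 25) {
  len <- sample(min_len:max_len, 1L)
  paste(sample(names(srmkit::RESIDUE_MASSES), len, replace = TRUE),
        collapse = "")
}
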