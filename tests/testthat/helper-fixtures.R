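# Programmatic fixtures: hand-built libraries, targets and MGF/PSM files.

# One library entry with y-ion fragments. `intensities` are relative
# (max must be 1); defaults give distinct, strictly decreasing values.
make_entry <- function(sequence, charge = 2L, rt = 10, protein = "P1",
                       n_frag = NULL, intensities = NULL,
                       modified = sequence) {
  pep <- srmkit::parse_modified_peptide(modified, charge)
  len <- nchar(pep$sequence)
  if (is.null(n_frag)) n_frag <- len - 1L
  stopifnot(n_frag <= len - 1L)
  if (is.null(intensities)) intensities <- 1 - (seq_len(n_frag) - 1L) * 0.05
  key <- paste(modified, charge, sep = "/")
  entry <- data.frame(
    key = key, protein_ids = protein, peptide = pep$sequence,
    modified_peptide = modified, precursor_charge = charge,
    precursor_mz = srmkit::precursor_mz(pep), rt_min = rt, irt = NA_real_,
    n_spectra = 1L)
  frags <- data.frame(
    key = key, series = "y", index = seq_len(n_frag), fragment_charge = 1L,
    fragment_mz = vapply(seq_len(n_frag), function(k)
      srmkit::fragment_mz(pep, "y", k, 1L), 0),
    relative_intensity = intensities)
  list(entry = entry, fragments = frags)
}

make_library <- function(entries, gradient_min = 120, label = "test") {
  srmkit::spectral_library(
    do.call(rbind, lapply(entries, `[[`, "entry")),
    do.call(rbind, lapply(entries, `[[`, "fragments")),
    srmkit::gradient_profile(gradient_min, label))
}

# Deterministic distinct canonical sequences without K/R (no missed
# cleavages) of a given length: the index is written in base 16 over a
# 16-letter alphabet, so sequences are unique by construction.
synthetic_sequences <- function(n, len = 10L) {
  letters16 <- c("A", "G", "S", "P", "V", "T", "L", "N", "D", "Q",
                 "E", "M", "H", "F", "Y", "W")
  width <- max(3L, ceiling(log(n + 1, 16)))
  stopifnot(len > width)
  vapply(seq_len(n), function(i) {
    digits <- (i %/% 16^(seq_len(width) - 1L)) %% 16
    paste(c(letters16[digits + 1L], rep("E", len - width)), collapse = "")
  }, "")
}

# A library of n entries with prescribed RTs and equal intensity sums.
uniform_library <- function(n = 100, rts = seq(1, 100, length.out = n),
                            gradient_min = 120) {
  seqs <- synthetic_sequences(n, len = 10L)
  make_library(lapply(seq_len(n), function(i)
    make_entry(seqs[i], rt = rts[i], protein = sprintf("P%03d", i),
               n_frag = 5L)), gradient_min)
}

# Minimal windowed target table for scheduler tests.
make_targets <- function(rt, key = sprintf("PEP%03d/2", seq_along(rt))) {
  n <- length(rt)
  data.frame(
    key = key,
    protein_ids = rep("P1", n),
    modified_peptide = sub("/.*$", "", key),
    precursor_charge = rep(2L, n),
    precursor_mz = 400 + seq_len(n) * 0.01,
    fragment = rep("y5", n),
    fragment_charge = rep(1L, n),
    fragment_mz = 550 + seq_len(n) * 0.01,
    collision_energy = rep(13.4, n),
    predicted_rt = rt)
}

write_mgf_fixture <- function(path, spectra) {
  lines <- unlist(lapply(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", s$title),
      if (!is.null(s$rt_s)) paste0("RTINSECONDS=", s$rt_s),
      paste0("PEPMASS=", s$pepmass %||% 500),
      sprintf("%.5f %.1f", s$peaks$mz, s$peaks$intensity),
      "END IONS")
  }))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Peaks at the theoretical y-ion positions of a peptide, with given
# raw intensities (named by index).
y_ion_peaks <- function(sequence, charge = 2L, intensities) {
  pep <- srmkit::peptide(sequence, charge = charge)
  idx <- as.integer(names(intensities))
  data.frame(
    mz = vapply(idx, function(k) srmkit::fragment_mz(pep, "y", k, 1L), 0),
    intensity = as.numeric(intensities))
}

write_psm_fixture <- function(path, psms) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
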