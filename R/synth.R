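# Seeded simulator: random proteomes, in-silico tryptic spectral libraries
# with hydrophobicity-driven retention times, and gradient-transfer
# experiments.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Average amino-acid frequencies in well-annotated protein databases
# (percent); K + R together ~11.4%, matching typical tryptic peptide
# densities.
RESIDUE_FREQUENCIES <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

# Kyte-Doolittle hydropathy index, the driver of the simulated
# reversed-phase retention model.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Generate a random proteome
#'
#' Reproducible random protein sequences over the 20 canonical residues at
#' typical database frequencies, with stable IDs `SYN_0001`, `SYN_0002`, ...
#' Protein lengths are Poisson-distributed around `mean_length`.
#'
#' @param n_proteins Number of proteins.
#' @param mean_length Mean protein length in residues (default 400).
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
generate_proteome <- function(n_proteins, mean_length = 400, seed = 1L) {
  stopifnot(n_proteins >= 1)
  with_seed(seed, {
    lens <- pmax(30L, stats::rpois(n_proteins, mean_length))
    seqs <- vapply(lens, function(L)
      paste(sample(names(RESIDUE_FREQUENCIES), L, replace = TRUE,
                   prob = RESIDUE_FREQUENCIES), collapse = ""), "")
    names(seqs) <- sprintf("SYN_%04d", seq_len(n_proteins))
    seqs
  })
}

#' Write/read a proteome as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O.
#'
#' @param proteome Named character vector of sequences.
#' @param path FASTA path.
#' @return `path` (write) or a named character vector (read).
#' @export
write_proteome_fasta <- function(proteome, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O")
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' In-silico tryptic digest
#'
#' Cleaves after K/R not followed by P and returns all products carrying
#' `0..max_missed` missed cleavages, with their positions in the parent
#' sequence.
#'
#' @param sequence Canonical amino-acid string.
#' @param max_missed Maximum missed cleavages retained (default 1).
#' @return Data frame with columns `peptide`, `start`, `end`, `missed`.
#' @export
digest <- function(sequence, max_missed = 1L) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & residues[pmin(cut_after + 1L, n)] != "P" |
                         cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  k <- length(starts)
  out <- list()
  for (m in 0:max_missed) {
    if (k - m < 1L) break
    i <- seq_len(k - m)
    out[[m + 1L]] <- data.frame(
      peptide = vapply(i, function(j)
        paste(residues[starts[j]:ends[j + m]], collapse = ""), ""),
      start = starts[i], end = ends[i + m], missed = m
    )
  }
  do.call(rbind, out)
}

#' Parameters of the simulated spectral library
#'
#' @param min_length,max_length Peptide length bounds retained (6-25,
#'   the usual assay-suitable range).
#' @param max_missed Missed cleavages generated (default 1, mirroring
#'   common search settings).
#' @param rt_jitter_sd Gaussian RT jitter in minutes (default 0.1).
#' @param rt_lo_frac,rt_hi_frac Fraction of the gradient covered by the
#'   elution range (default 0.05-0.95; peptides neither elute in the
#'   injection front nor in the wash).
#' @param intensity_meanlog,intensity_sdlog Lognormal fragment-intensity
#'   parameters.
#' @param charge_len_threshold Peptides longer than this are simulated as
#'   3+, others as 2+ (default 14).
#' @return List of parameters.
#' @export
synth_params <- function(min_length = 6L, max_length = 25L, max_missed = 1L,
                         rt_jitter_sd = 0.1, rt_lo_frac = 0.05,
                         rt_hi_frac = 0.95, intensity_meanlog = 0,
                         intensity_sdlog = 1, charge_len_threshold = 14L) {
  as.list(environment())
}

#' Simulate a spectral library from a proteome
#'
#' Digests every protein, keeps peptides within the length bounds,
#' assigns each peptide a retention time by mapping its Kyte-Doolittle
#' hydropathy sum affinely onto the central part of the gradient plus
#' Gaussian jitter, draws i.i.d. lognormal y-ion intensities
#' (renormalised so the base peak is 1), and computes all precursor and
#' fragment m/z values. Precursor charge is 2+ for short peptides and 3+
#' above the length threshold. Peptides shared between proteins carry the
#' union of their protein IDs.
#'
#' @param proteome Named character vector from [generate_proteome()].
#' @param gradient A [gradient_profile()].
#' @param seed RNG seed.
#' @param params [synth_params()].
#' @return List with `library` (a [spectral_library()]) and
#'   `ground_truth` (data frame `key`, `modified_peptide`,
#'   `precursor_charge`, `hydrophobicity`, `rt_true_min`).
#' @export
simulate_library <- function(proteome, gradient, seed = 1L,
                             params = synth_params()) {
  stopifnot(inherits(gradient, "gradient_profile"))
  peps <- do.call(rbind, lapply(names(proteome), function(id) {
    d <- digest(proteome[[id]], params$max_missed)
    d$protein <- id
    d
  }))
  peps <- peps[nchar(peps$peptide) >= params$min_length &
               nchar(peps$peptide) <= params$max_length, , drop = FALSE]
  if (!nrow(peps)) stop("no eligible peptides after digestion and length filtering")
  # collapse shared sequences to one entry with the union of proteins
  prot_by_seq <- vapply(split(peps$protein, peps$peptide), function(p)
    paste(sort(unique(p)), collapse = ";"), "")
  seqs <- names(prot_by_seq)
  lens <- nchar(seqs)
  hyd <- vapply(strsplit(seqs, "", fixed = TRUE), function(r)
    sum(KYTE_DOOLITTLE[r]), 0)
  span <- range(hyd)
  lo <- params$rt_lo_frac * gradient$length
  hi <- params$rt_hi_frac * gradient$length
  rt_true <- if (diff(span) > 0)
    lo + (hyd - span[1L]) / diff(span) * (hi - lo) else rep((lo + hi) / 2, length(hyd))
  charges <- ifelse(lens <= params$charge_len_threshold, 2L, 3L)
  keys <- entry_key(seqs, charges)

  with_seed(seed, {
    rts <- rt_true + stats::rnorm(length(rt_true), 0, params$rt_jitter_sd)
    rts <- pmin(pmax(rts, 0), gradient$length)
    frags <- lapply(seq_along(seqs), function(i) {
      pep <- peptide(seqs[i], charge = charges[i])
      idx <- seq_len(lens[i] - 1L)
      raw <- stats::rlnorm(length(idx), params$intensity_meanlog,
                           params$intensity_sdlog)
      data.frame(key = keys[i], series = "y", index = idx,
                 fragment_charge = 1L,
                 fragment_mz = vapply(idx, function(k)
                   fragment_mz(pep, "y", k, 1L), 0),
                 relative_intensity = raw / max(raw))
    })
    entries <- data.frame(
      key = keys,
      protein_ids = unname(prot_by_seq),
      peptide = seqs,
      modified_peptide = seqs,  # no variable modifications simulated
      precursor_charge = charges,
      precursor_mz = vapply(seq_along(seqs), function(i)
        precursor_mz(peptide(seqs[i], charge = charges[i])), 0),
      rt_min = rts,
      irt = NA_real_,
      n_spectra = 1L
    )
    truth <- data.frame(key = keys, modified_peptide = seqs,
                        precursor_charge = charges, hydrophobicity = hyd,
                        rt_true_min = rt_true)
    rownames(entries) <- rownames(truth) <- NULL
    list(library = spectral_library(entries, do.call(rbind, frags), gradient,
                                    provenance = sprintf("simulated (seed %d)", seed)),
         ground_truth = truth)
  })
}

#' Gradient-transfer model
#'
#' Destination RT = `intercept + slope * rt + quad_coeff * rt^2`, with
#' Gaussian measurement noise of sd `noise_sd` applied to reference-
#' peptide RT measurements.
#'
#' @param slope Dimensionless gradient scale factor (> 0).
#' @param intercept Minutes.
#' @param quad_coeff Curvature per minute (default 0; nonzero values
#'   stress-test the linear calibration).
#' @param noise_sd Reference-RT measurement noise sd in minutes.
#' @param seed RNG seed for the noise realisation.
#' @return An object of class `transfer_model`.
#' @export
transfer_model <- function(slope, intercept = 0, quad_coeff = 0,
                           noise_sd = 0, seed = 1L) {
  if (slope <= 0) stop("transfer slope must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 quad_coeff = quad_coeff, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "transfer_model")
}

#' Simulate transferring a library to a new gradient
#'
#' Applies the transfer model to every entry's library RT to obtain the
#' true destination RT (negative values clipped to 0 and flagged), and —
#' when a reference set is supplied — produces noisy "measured" RTs for
#' the reference peptides only, emulating a quick calibration run on the
#' destination gradient.
#'
#' @param lib A [spectral_library()].
#' @param model A [transfer_model()].
#' @param refs Optional `reference_set` from [pick_landmarks()].
#' @param peptide_noise_sd Optional extra Gaussian jitter (minutes) on
#'   every peptide's true destination RT, emulating run-to-run
#'   chromatographic variability (default 0: deterministic truth).
#' @return List with `truth` (data frame `key`, `modified_peptide`,
#'   `precursor_charge`, `rt_source_min`, `rt_dest_true_min`, `clipped`)
#'   and `measured` (reference-peptide data frame `key`,
#'   `modified_peptide`, `precursor_charge`, `rt_min`; `NULL` without
#'   `refs`).
#' @export
simulate_transfer <- function(lib, model, refs = NULL, peptide_noise_sd = 0) {
  stopifnot(inherits(lib, "spectral_library"), inherits(model, "transfer_model"))
  f <- function(rt) model$intercept + model$slope * rt + model$quad_coeff * rt^2
  with_seed(model$seed, {
    dest <- f(lib$entries$rt_min)
    if (peptide_noise_sd > 0)
      dest <- dest + stats::rnorm(length(dest), 0, peptide_noise_sd)
    clipped <- dest < 0
    dest[clipped] <- 0
    truth <- data.frame(key = lib$entries$key,
                        modified_peptide = lib$entries$modified_peptide,
                        precursor_charge = lib$entries$precursor_charge,
                        rt_source_min = lib$entries$rt_min,
                        rt_dest_true_min = dest,
                        clipped = clipped)
    measured <- NULL
    if (!is.null(refs)) {
      idx <- match(refs$key, truth$key)
      if (anyNA(idx))
        stop("reference keys missing from library: ",
             paste(refs$key[is.na(idx)], collapse = ", "))
      measured <- data.frame(
        key = refs$key,
        modified_peptide = refs$modified_peptide,
        precursor_charge = refs$precursor_charge,
        rt_min = truth$rt_dest_true_min[idx] +
          stats::rnorm(nrow(refs), 0, model$noise_sd))
    }
    list(truth = truth, measured = measured)
  })
}

#' Write ground-truth destination RTs to TSV
#' @param truth Truth table from [simulate_transfer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(truth, path) {
  out <- data.frame(modified_peptide = truth$modified_peptide,
                    charge = truth$precursor_charge,
                    rt_source_min = sprintf("%.4f", truth$rt_source_min),
                    rt_dest_true_min = sprintf("%.4f", truth$rt_dest_true_min))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Fraction of targets whose true destination RT falls inside the window
#'
#' The detection-rate readout of a gradient-transfer experiment: a target
#' is a hit when its true destination RT lies in its half-open scheduling
#' window `[start, end)`.
#'
#' @param schedule An [mrm_schedule()] or windowed target data frame.
#' @param truth Truth table from [simulate_transfer()].
#' @return List with `rate` (fraction in `[0, 1]`) and `hits`
#'   (per-transition table with logical `hit`).
#' @export
detection_rate <- function(schedule, truth) {
  targets <- if (inherits(schedule, "mrm_schedule")) schedule$targets
             else as.data.frame(schedule)
  if (!nrow(targets)) stop("no targets in schedule")
  idx <- match(targets$key, truth$key)
  if (anyNA(idx))
    stop("target keys missing from truth table: ",
         paste(unique(targets$key[is.na(idx)]), collapse = ", "))
  rt <- truth$rt_dest_true_min[idx]
  hit <- targets$window_start <= rt & rt < targets$window_end
  hits <- data.frame(key = targets$key, fragment = targets$fragment,
                     window_start = targets$window_start,
                     window_end = targets$window_end,
                     rt_dest_true_min = rt, hit = hit)
  list(rate = mean(hit), hits = hits)
}
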