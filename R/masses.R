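# Monoisotopic residue masses and peptide/fragment m/z arithmetic.

#' Monoisotopic masses of the 20 canonical amino-acid residues (Da)
#'
#' Residue (i.e. water-subtracted) monoisotopic masses. Cysteine is listed
#' unmodified; carbamidomethylation is applied implicitly by the mass
#' functions (see [peptide()]).
#'
#' @format Named numeric vector, one element per one-letter residue code.
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Physical constants used in m/z computation (Da)
#' @name mass-constants
#' @keywords internal
NULL

PROTON_MASS <- 1.0072765
WATER_MASS <- 18.010565

# Mass delta of carbamidomethylation, applied to every cysteine as a fixed
# modification (mirrors common alkylation during sample preparation).
CARBAMIDOMETHYL_DELTA <- 57.02146

# Mass delta of methionine oxidation, the only variable modification the
# modified-sequence dialect is expected to carry in practice.
OXIDATION_DELTA <- 15.99491

#' Construct a peptide
#'
#' A peptide is an uppercase sequence over the 20 canonical residues, a list
#' of explicit (variable) modifications and a precursor charge.
#' Carbamidomethylation of cysteine is treated as an always-on fixed
#' modification: it is never listed in `mods` and is added implicitly to
#' every `C` by all mass functions. Variable modifications (e.g. oxidised
#' methionine, +15.99491 Da) must be explicit.
#'
#' @param sequence Uppercase amino-acid string (canonical residues only).
#' @param mods `NULL`, or a data frame with columns `pos` (1-based residue
#'   index) and `delta` (mass shift in Da).
#' @param charge Positive integer precursor charge.
#' @return An object of class `peptide`.
#' @examples
#' peptide("PEPTIDE", charge = 2)
#' peptide("PEPMIDE", mods = data.frame(pos = 4, delta = 15.99491), charge = 2)
#' @export
peptide <- function(sequence, mods = NULL, charge = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("peptide sequence must be a single non-empty string")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(residues, names(RESIDUE_MASSES))
  if (length(unknown))
    stop("unknown residue character(s): ", paste(sort(unique(unknown)), collapse = ", "))
  if (is.null(mods)) {
    mods <- data.frame(pos = integer(0), delta = numeric(0))
  } else {
    mods <- as.data.frame(mods)[, c("pos", "delta")]
    if (any(mods$pos < 1 | mods$pos > length(residues)))
      stop("modification position outside 1..", length(residues))
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  structure(list(sequence = sequence, mods = mods, charge = charge),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d+)\n", modified_sequence(x), x$charge))
  invisible(x)
}

#' Parse a modified-sequence string into a peptide
#'
#' The dialect is Skyline-compatible: a bracketed signed mass delta follows
#' the modified residue, e.g. `"PEPM[+15.99491]IDE"`. Carbamidomethyl C is
#' implicit and must not be written.
#'
#' @param x Modified-sequence string.
#' @param charge Precursor charge.
#' @return A `peptide`.
#' @export
parse_modified_peptide <- function(x, charge = 1L) {
  if (!is.character(x) || length(x) != 1L) stop("expected a single string")
  seq_chars <- character(0)
  pos <- integer(0)
  delta <- numeric(0)
  i <- 1L
  n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(x, i, n), fixed = TRUE)
      if (close < 0L) stop("unterminated modification bracket in: ", x)
      body <- substr(x, i + 1L, i + close - 2L)
      d <- suppressWarnings(as.numeric(body))
      if (is.na(d)) stop("malformed modification delta: [", body, "]")
      if (!length(seq_chars)) stop("modification precedes first residue in: ", x)
      pos <- c(pos, length(seq_chars))
      delta <- c(delta, d)
      i <- i + close
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  peptide(paste(seq_chars, collapse = ""),
          mods = data.frame(pos = pos, delta = delta),
          charge = charge)
}

#' Render the modified-sequence string of a peptide
#'
#' Inverse of [parse_modified_peptide()]: explicit modifications are written
#' as bracketed signed deltas after their residue; implicit carbamidomethyl
#' C is not written.
#'
#' @param pep A `peptide`.
#' @return Single string.
#' @export
modified_sequence <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  residues <- strsplit(pep$sequence, "", fixed = TRUE)[[1L]]
  if (nrow(pep$mods)) {
    tags <- vapply(split(pep$mods$delta, pep$mods$pos), function(d)
      paste(sprintf("[%+.5f]", d), collapse = ""), "")
    idx <- as.integer(names(tags))
    residues[idx] <- paste0(residues[idx], tags)
  }
  paste(residues, collapse = "")
}

# Per-residue masses including implicit carbamidomethyl C and explicit mods.
residue_mass_vector <- function(pep) {
  residues <- strsplit(pep$sequence, "", fixed = TRUE)[[1L]]
  m <- unname(RESIDUE_MASSES[residues])
  m[residues == "C"] <- m[residues == "C"] + CARBAMIDOMETHYL_DELTA
  if (nrow(pep$mods)) {
    for (i in seq_len(nrow(pep$mods)))
      m[pep$mods$pos[i]] <- m[pep$mods$pos[i]] + pep$mods$delta[i]
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses, modification deltas (implicit
#' carbamidomethyl C included) and one water.
#'
#' @param pep A `peptide`.
#' @return Mass in Da.
#' @examples
#' peptide_mass(peptide("PEPTIDE")) # 799.3599
#' @export
peptide_mass <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  sum(residue_mass_vector(pep)) + WATER_MASS
}

#' Precursor m/z of a peptide
#'
#' `(neutral mass + z * proton) / z` with the peptide's own charge.
#'
#' @param pep A `peptide` with charge >= 1.
#' @return m/z in Th.
#' @export
precursor_mz <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  if (pep$charge < 1L) stop("charge must be >= 1")
  (peptide_mass(pep) + pep$charge * PROTON_MASS) / pep$charge
}

#' Theoretical fragment-ion m/z
#'
#' b-ions carry the first `index` residues; y-ions carry the last `index`
#' residues plus water. Both are reported protonated at `frag_charge`.
#' The full-length "fragment" (`index == length`) is not a fragment and is
#' rejected.
#'
#' @param pep A `peptide`.
#' @param series `"y"` or `"b"`.
#' @param index 1-based fragment ordinal, `1 <= index <= length - 1`.
#' @param frag_charge Positive fragment charge.
#' @return m/z in Th.
#' @examples
#' fragment_mz(peptide("PEPTIDE"), "y", 3) # 376.1714
#' @export
fragment_mz <- function(pep, series = c("y", "b"), index, frag_charge = 1L) {
  stopifnot(inherits(pep, "peptide"))
  series <- match.arg(series)
  len <- nchar(pep$sequence)
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index >= len)
    stop("fragment index must satisfy 1 <= index <= ", len - 1L,
         " (got ", index, ")")
  frag_charge <- as.integer(frag_charge)
  if (is.na(frag_charge) || frag_charge < 1L) stop("fragment charge must be >= 1")
  m <- residue_mass_vector(pep)
  neutral <- if (series == "b") sum(m[seq_len(index)])
             else sum(m[(len - index + 1L):len]) + WATER_MASS
  (neutral + frag_charge * PROTON_MASS) / frag_charge
}
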