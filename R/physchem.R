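# Physicochemical property panel.
#
# The per-residue scales are pinned here, in one versioned constants table,
# so every property is reproducible:
#  * hydropathy: Kyte & Doolittle (1982) GRAVY scale
#  * hydrophilicity: Hopp & Woods (1981)
#  * hydrophobicity: Eisenberg consensus scale (Eisenberg et al. 1984)
#  * residue volume: Zamyatnin (1972), cubic Angstrom
#  * flexibility: Bhaskaran & Ponnuswamy (1988) average flexibility index
#  * residue masses: average isotopic residue masses (Da); peptide mass adds
#    one water (18.01524 Da)
#  * pKa set: EMBOSS (iep) values for termini and ionizable side chains
# Class memberships (charged, tiny, aromatic, ...) follow the standard
# Taylor-style definitions and are listed in AA_CLASSES.

#' Per-residue physicochemical scales
#'
#' Named list of numeric vectors over the 20 standard residues (alphabetical
#' order): `hydropathy` (Kyte-Doolittle), `hydrophilicity` (Hopp-Woods),
#' `hydrophobicity` (Eisenberg consensus), `volume` (Zamyatnin, cubic
#' Angstrom), `flexibility` (Bhaskaran-Ponnuswamy) and `residue_mass`
#' (average Da, residue in chain).
#'
#' @format Named list of named numeric vectors of length 20.
#' @export
AA_SCALES <- local({
  nm <- function(...) stats::setNames(c(...), c("A", "C", "D", "E", "F", "G",
    "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  list(
    hydropathy = nm(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                    1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3),
    hydrophilicity = nm(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0,
                        -1.8, -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5,
                        -3.4, -2.3),
    hydrophobicity = nm(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38,
                        -1.50, 1.06, 0.64, -0.78, 0.12, -0.85, -2.53, -0.18,
                        -0.05, 1.08, 0.81, 0.26),
    volume = nm(88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7, 168.6,
                166.7, 162.9, 114.1, 112.7, 143.8, 173.4, 89.0, 116.1, 140.0,
                227.8, 193.6),
    flexibility = nm(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462,
                     0.466, 0.365, 0.295, 0.463, 0.509, 0.493, 0.529, 0.507,
                     0.444, 0.386, 0.305, 0.420),
    residue_mass = nm(71.0788, 103.1388, 115.0886, 129.1155, 147.1766,
                      57.0519, 137.1411, 113.1594, 128.1741, 113.1594,
                      131.1926, 114.1038, 97.1167, 128.1307, 156.1875,
                      87.0782, 101.1051, 99.1326, 186.2132, 163.1760)
  )
})

#' Residue class memberships
#'
#' Standard residue classes used for composition fractions and the
#' stable-versus-unstable group analysis: positively charged \{K, R, H\},
#' negatively charged \{D, E\}, neutral (all others), polar, non-polar,
#' aromatic \{F, W, Y, H\}, aliphatic \{I, L, V\}, tiny \{A, C, G, S, T\}
#' and small.
#'
#' @format Named list of character vectors.
#' @export
AA_CLASSES <- list(
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  neutral   = setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                        "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                      c("K", "R", "H", "D", "E")),
  polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Y"),
  nonpolar  = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W"),
  aromatic  = c("F", "W", "Y", "H"),
  aliphatic = c("I", "L", "V"),
  tiny      = c("A", "C", "G", "S", "T"),
  small     = c("A", "C", "D", "G", "N", "P", "S", "T", "V")
)

# EMBOSS pKa values; termini plus ionizable side chains.
PKA <- list(nterm = 8.6, cterm = 3.6,
            side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5,
                     K = 10.8, R = 12.5, Y = 10.1))

WATER_MASS <- 18.01524

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the free N-terminus, free C-terminus and
#' the ionizable side chains (D, E, C, Y, H, K, R) using the EMBOSS pKa
#' set. Monotonically non-increasing in pH.
#'
#' @param sequence A validated peptide sequence.
#' @param pH pH, strictly between 0 and 14.
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(sequence, pH = 7) {
  if (pH <= 0 || pH >= 14) stop("pH must be in (0, 14)", call. = FALSE)
  sequence <- validate_peptides(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pos_pka <- c(PKA$nterm, PKA$side[chars[chars %in% c("H", "K", "R")]])
  neg_pka <- c(PKA$cterm, PKA$side[chars[chars %in% c("C", "D", "E", "Y")]])
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point of a peptide
#'
#' The pH at which [net_charge()] crosses zero, located by bisection to
#' `|charge| < 1e-4`. The termini guarantee a sign change inside (0, 14).
#'
#' @param sequence A validated peptide sequence.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence) {
  lo <- 1e-3
  hi <- 14 - 1e-3
  f_lo <- net_charge(sequence, lo)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    f <- net_charge(sequence, mid)
    if (abs(f) < 1e-4) return(mid)
    if (sign(f) == sign(f_lo)) { lo <- mid; f_lo <- f } else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical property panel of peptides
#'
#' Computes a 17-property panel per peptide: mean hydrophobicity
#' (Eisenberg), mean hydrophilicity (Hopp-Woods), mean hydropathy
#' (Kyte-Doolittle GRAVY), amphipathicity (alpha-helical hydrophobic
#' moment per residue, Eisenberg scale, 100 degrees per step), mean residue
#' volume (cubic Angstrom), molecular weight (Da), isoelectric point,
#' net charge at pH 7, mean flexibility, and the polar, non-polar,
#' aromatic, aliphatic, tiny, small, positively charged and negatively
#' charged residue-class fractions.
#'
#' Mean-scale properties are simple averages over the sequence, so they are
#' invariant under residue permutation; amphipathicity is position
#' dependent by construction.
#'
#' @param sequences Character vector of peptides (or an [hl_dataset()]).
#' @return Data frame with one row per peptide and one column per property,
#'   plus a leading `sequence` column.
#' @examples
#' peptide_properties("GGGG")$frac_tiny  # 1
#' @export
peptide_properties <- function(sequences) {
  if (inherits(sequences, "hl_dataset") || is.data.frame(sequences))
    sequences <- sequences$sequence
  sequences <- validate_peptides(sequences)
  rows <- lapply(sequences, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    frac <- function(class) sum(chars %in% AA_CLASSES[[class]]) / n
    h <- AA_SCALES$hydrophobicity[chars]
    ang <- (seq_len(n) - 1L) * 100 * pi / 180
    mu_h <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / n
    data.frame(
      sequence = s,
      length = n,
      hydrophobicity = mean(h),
      hydrophilicity = mean(AA_SCALES$hydrophilicity[chars]),
      hydropathy = mean(AA_SCALES$hydropathy[chars]),
      amphipathicity = mu_h,
      volume = mean(AA_SCALES$volume[chars]),
      mol_weight = sum(AA_SCALES$residue_mass[chars]) + WATER_MASS,
      isoelectric_point = isoelectric_point(s),
      net_charge_ph7 = net_charge(s, 7),
      flexibility = mean(AA_SCALES$flexibility[chars]),
      frac_polar = frac("polar"),
      frac_nonpolar = frac("nonpolar"),
      frac_aromatic = frac("aromatic"),
      frac_aliphatic = frac("aliphatic"),
      frac_tiny = frac("tiny"),
      frac_small = frac("small"),
      frac_positive = frac("positive"),
      frac_negative = frac("negative"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
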