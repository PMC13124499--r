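# Monoisotopic residue masses (Da), canonical 20 residues.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AA_LETTERS <- names(.AA_MONO)

#' Physical constants used throughout the package
#'
#' Monoisotopic masses in Da: the proton mass used for m/z conversion, the
#' mass of water added to a neutral peptide, the carbamidomethyl (fixed, Cys)
#' and methionine-oxidation (variable) modification deltas, and the
#' 13C-12C / 15N-14N isotope mass differences used for heavy-label shifts.
#'
#' @name mass-constants
#' @keywords internal
NULL

PROTON_MASS <- 1.007276
WATER_MONO <- 18.0105646
MOD_CARBAMIDOMETHYL <- 57.02146
MOD_OXIDATION <- 15.99491
C13_SHIFT <- 1.0033548
N15_SHIFT <- 0.9970349

# Exponential-decay constant of the theoretical fragment intensity ladder,
# shared by the spectrum simulator and the PSM scorer so that a noiseless
# self-spectrum scores the closed-form maximum.
FRAGMENT_LADDER_DECAY <- 0.05

# Heavy-atom count limits per labeled residue (carbons, nitrogens).
.LABEL_ATOM_LIMITS <- list(K = c(C = 6, N = 2), R = c(C = 6, N = 4))

`%||%` <- function(a, b) if (is.null(a)) b else a
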