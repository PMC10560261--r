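#' Probe adduct mass constants
#'
#' Monoisotopic mass shifts (Da) used to label probe-modified peptides:
#' the clickable electrophilic purine (CEP) adduct on cysteine, the
#' iodoacetamide-alkyne (IA) adduct, and the four desthiobiotin probe
#' fragment peaks (d1-d4) carried as custom peaks in the search.
#'
#' @format Named numeric vector of mass shifts in Da.
#' @export
adduct_masses <- c(
  cep_cys   = 604.2637,
  ia_alkyne = 509.2962,
  d1        = 197.129,
  d2        = 240.1712,
  d3        = 425.2638,
  d4        = 453.2825
)

#' Nucleophilic residues considered for probe modification
#'
#' The thirteen nucleophilic amino acids searched as variable
#' probe-modification targets: C, D, E, H, K, M, N, Q, R, S, T, W, Y.
#'
#' @format Character vector of one-letter codes.
#' @export
nucleophilic_residues <- c("C", "D", "E", "H", "K", "M", "N", "Q",
                           "R", "S", "T", "W", "Y")

#' Default RNA-binding domain names
#'
#' Domain families treated as canonical RNA-binding domains (RBDs) when
#' classifying annotations and summarizing distances: KH, RRM, Helicase
#' C-terminal, Helicase ATP-binding, and double-stranded RNA-binding.
#'
#' @format Character vector of domain names.
#' @export
rbd_domain_names <- c("KH", "RRM", "Helicase C-terminal",
                      "Helicase ATP-binding", "Double-stranded RNA-binding")

# one-letter <-> three-letter residue tables used by the structure module
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.rna_resnames <- c("A", "U", "G", "C")
.dna_resnames <- c("DA", "DT", "DG", "DC")
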