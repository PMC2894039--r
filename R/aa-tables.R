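#' Van der Waals radii for heavy elements
#'
#' Standard per-element van der Waals radii (Bondi set) used for
#' solvent-accessible surface area computation. Hydrogens are excluded from
#' analysis and carry no entry.
#'
#' @return Named numeric vector of radii in Angstrom, names are element
#'   symbols in upper case.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.00, MN = 2.00, "NA" = 2.27,
    K = 2.75)
}

# atomic masses (u) for the same elements
element_masses <- function() {
  c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
    FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078, MN = 54.938,
    "NA" = 22.990, K = 39.098)
}

#' Reference maximal accessibilities per residue type
#'
#' Theoretical maximum solvent-accessible surface areas of residue X in an
#' extended Gly-X-Gly tripeptide (Tien et al. 2013 theoretical set), used to
#' convert absolute residue SASA into relative accessibility. Users may
#' supply their own table to [surface_residues()].
#'
#' @return Named numeric vector (Angstrom^2), names are 3-letter residue codes.
#' @export
max_accessibility <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' The 7-class amino-acid grouping used for conservation scoring
#'
#' Amino acids are partitioned into seven classes of structurally similar
#' residues; substitutions within a class are treated as conservative and
#' carry no entropy penalty:
#' (1) A,V,L,I,M,C; (2) G,S,T; (3) D,E; (4) N,Q; (5) R,K; (6) P,F,Y,W;
#' (7) H.
#'
#' @return Named integer vector mapping 1-letter amino-acid codes to class
#'   indices 1..7.
#' @export
class_scheme <- function() {
  cls <- list(c("A", "V", "L", "I", "M", "C"),
              c("G", "S", "T"),
              c("D", "E"),
              c("N", "Q"),
              c("R", "K"),
              c("P", "F", "Y", "W"),
              "H")
  out <- integer(0)
  for (k in seq_along(cls)) {
    v <- rep.int(k, length(cls[[k]]))
    names(v) <- cls[[k]]
    out <- c(out, v)
  }
  out
}

# number of classes in the default scheme
n_classes <- function(scheme = class_scheme()) max(scheme)
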