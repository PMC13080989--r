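# Element data: Bondi van der Waals radii (A), with a generic fallback for
# elements outside the table (2.0 A, typical for transition metals).

.bondi <- c(
  H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98,
  Xe = 2.16, B = 1.92, Li = 1.82, Na = 2.27, K = 2.75, Mg = 1.73,
  Zn = 1.39, Cu = 1.40, Ni = 1.63, Pd = 1.63, Pt = 1.75, Au = 1.66,
  `*` = 0.0, X = 0.0
)

#' Van der Waals radii for element symbols
#'
#' Bondi radii where tabulated; 2.0 A otherwise (dummy atoms: 0).
#' @param elements character vector of element symbols
#' @param override optional named numeric vector of replacement radii
#' @return numeric vector of radii in Angstrom
#' @export
vdw_radii <- function(elements, override = NULL) {
  tab <- .bondi
  if (!is.null(override)) tab[names(override)] <- override
  r <- unname(tab[elements])
  r[is.na(r)] <- 2.0
  r
}

# Default fraction of the vdW-sum below which a nonbonded contact counts as
# a steric clash; shared by CBU assembly, MOP assembly and Widom sampling.
mf_clash_factor <- function() 0.7

# Single-bond covalent radii (Pyykko-Atsumi values, A) for placing bonding
# sites at realistic separations.
covalent_radius <- function(element) {
  tab <- c(H = 0.32, B = 0.85, C = 0.75, N = 0.71, O = 0.63, F = 0.64,
           Si = 1.16, P = 1.11, S = 1.03, Cl = 0.99, Br = 1.14, I = 1.33,
           Se = 1.16)
  r <- unname(tab[element])
  r[is.na(r)] <- 1.2
  r
}

# Typical X-H bond lengths used when a cleaved side-chain site is reverted
# to hydrogen.
xh_bond_length <- function(element) {
  tab <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34, B = 1.19, Si = 1.48, P = 1.42)
  len <- unname(tab[element])
  len[is.na(len)] <- 1.05
  len
}
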