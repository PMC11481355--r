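#' Van der Waals radii (Bondi set)
#'
#' Heavy-atom van der Waals radii in angstroms, Bondi's consensus values with
#' common metals added. Unknown elements fall back to 1.8 A.
#'
#' @param extra named numeric vector of overrides/additions (element symbol ->
#'   radius in A).
#' @return named numeric vector of radii.
#' @export
vdw_radii <- function(extra = NULL) {
  r <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, B = 1.92, SE = 1.90,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 2.05, CU = 1.40,
    "NA" = 2.27, K = 2.75, NI = 1.63, CO = 2.00, MO = 2.10, W = 2.10
  )
  if (!is.null(extra)) r[toupper(names(extra))] <- extra
  r
}

.assign_vdw <- function(elements, table = vdw_radii(), default = 1.8) {
  r <- unname(table[toupper(elements)])
  r[is.na(r)] <- default
  r
}

# Apolar elements for alpha-sphere polarity: carbon and sulfur.
.APOLAR_ELEMENTS <- c("C", "S")
.POLAR_ELEMENTS <- c("N", "O", "P")

# Kyte-Doolittle hydropathy per residue type.
.HYDROPATHY <- c(
  ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
  LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2
)

# Residue volumes (A^3), Zamyatnin.
.RES_VOLUME <- c(
  ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
  GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
  LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
  SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0
)

.POLAR_RESIDUES <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS",
                     "SER", "THR", "TYR", "CYS", "TRP")
.RES_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0)

#' Default cofactor keep-list
#'
#' Three-letter het codes treated as part of the receptor (not stripped as
#' ligands) during receptor preparation, read from the editable text file
#' shipped in \code{inst/extdata/cofactors.txt} (one code per line, `#`
#' comments allowed).
#'
#' @param path optional path to an alternative keep-list file.
#' @return uppercase character vector of het codes.
#' @export
default_cofactors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cofactors.txt", package = "enzport")
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  toupper(x[nzchar(x)])
}
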