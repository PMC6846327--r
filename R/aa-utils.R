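#' @importFrom methods new validObject is slot setClass setGeneric setMethod setValidity show
#' @importFrom stats sd quantile t.test rnorm rbeta runif rlnorm plogis pnorm median aggregate
#' @importFrom utils read.delim write.table
NULL

# canonical one-letter codes (20 standard residues; Sec/Pyl deliberately absent)
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3TO1 <- structure(names(AA3), names = unname(AA3))

# mixed-case three-letter forms as printed in HGVS protein notation
AA3_TITLE <- structure(names(AA3),
                       names = paste0(substr(AA3, 1, 1),
                                      tolower(substr(AA3, 2, 3))))

#' Test for canonical amino-acid one-letter codes
#'
#' @param aa character vector of one-letter codes.
#' @return logical vector, `TRUE` where the code is one of the 20 canonical
#'   residues (selenocysteine and pyrrolysine are not accepted).
#' @export
#' @examples
#' isCanonicalAa(c("A", "U", "X"))
isCanonicalAa <- function(aa) {
  aa %in% AA1
}

#' Default van der Waals radii (Angstrom)
#'
#' Chothia-like element radii used for solvent-accessibility calculations:
#' C 1.70, N 1.55, O 1.52, S 1.80, H 1.20. Unknown elements fall back to
#' 1.70 with a warning at lookup time.
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
}

#' Theoretical maximum accessible surface areas (Tien scale)
#'
#' Residue-type maximum ASA values (Angstrom^2) from the theoretical scale
#' of Tien and colleagues, used to normalise absolute per-residue ASA to
#' relative solvent accessibility (RSA).
#'
#' @return named numeric vector (20 entries, one-letter codes).
#' @export
#' @examples
#' maxAsaTien()[["A"]]
maxAsaTien <- function() {
  c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)
}

# element inferred from a PDB atom name: strip digits/primes, first letter,
# except two-letter cases irrelevant for protein ATOM records
inferElement <- function(name) {
  stripped <- gsub("[0-9' ]", "", name)
  toupper(substr(stripped, 1, 1))
}
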