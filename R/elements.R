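# Covalent radii (Angstrom), Cordero et al. consensus values, for the elements
# that occur in Pd2L4 cage systems plus common counterion/solvent atoms.
.COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Fe = 1.32, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Br = 1.20, Pd = 1.39, Ag = 1.45, Pt = 1.36, Au = 1.36, I = 1.39
)

.PERIODIC_TABLE <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn"
)

# Normalize an element symbol ("C", "c", "PD" -> "Pd"); error on non-elements.
normalize_element <- function(x) {
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  bad <- !(x %in% .PERIODIC_TABLE)
  if (any(bad))
    parse_error(sprintf("unknown element symbol(s): %s",
                        paste(unique(x[bad]), collapse = ", ")))
  x
}

covalent_radius <- function(element) {
  r <- .COVALENT_RADII[element]
  if (anyNA(r))
    data_error(sprintf("no covalent radius tabulated for element(s): %s",
                       paste(unique(element[is.na(r)]), collapse = ", ")))
  unname(r)
}
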