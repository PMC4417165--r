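# Idealized planar base geometries expressed in the standard reference frame
# (origin near the pair centre, x toward the major-groove edge, y toward the
# sugar of the owning strand, z along the stack normal). All heavy base atoms
# lie in z = 0. The C1' anchor is included; the backbone is reduced to a
# single P pseudo-atom at a fixed fiber-B offset, and a pseudo-O4' placed at
# build time to realise a requested glycosidic torsion.

.base_coords <- list(
  A = matrix(c(
    -1.291, 4.498, 0.000,   # N9
     0.024, 4.897, 0.000,   # C8
     0.877, 3.902, 0.000,   # N7
     0.071, 2.771, 0.000,   # C5
     0.369, 1.398, 0.000,   # C6
     1.611, 0.909, 0.000,   # N6
    -0.668, 0.532, 0.000,   # N1
    -1.912, 1.023, 0.000,   # C2
    -2.320, 2.290, 0.000,   # N3
    -1.267, 3.124, 0.000,   # C4
    -2.479, 5.346, 0.000),  # C1'
    ncol = 3L, byrow = TRUE,
    dimnames = list(c("N9","C8","N7","C5","C6","N6","N1","C2","N3","C4","C1'"), NULL)),
  G = matrix(c(
    -1.289, 4.551, 0.000,   # N9
     0.023, 4.962, 0.000,   # C8
     0.870, 3.969, 0.000,   # N7
     0.071, 2.833, 0.000,   # C5
     0.424, 1.460, 0.000,   # C6
     1.554, 0.955, 0.000,   # O6
    -0.700, 0.641, 0.000,   # N1
    -1.999, 1.087, 0.000,   # C2
    -2.949, 0.139, 0.000,   # N2
    -2.342, 2.364, 0.000,   # N3
    -1.265, 3.177, 0.000,   # C4
    -2.477, 5.399, 0.000),  # C1'
    ncol = 3L, byrow = TRUE,
    dimnames = list(c("N9","C8","N7","C5","C6","O6","N1","C2","N2","N3","C4","C1'"), NULL)),
  C = matrix(c(
    -1.285, 4.542, 0.000,   # N1
    -1.472, 3.158, 0.000,   # C2
    -2.628, 2.709, 0.000,   # O2
    -0.391, 2.344, 0.000,   # N3
     0.837, 2.868, 0.000,   # C4
     1.875, 2.027, 0.000,   # N4
     1.056, 4.275, 0.000,   # C5
    -0.023, 5.068, 0.000,   # C6
    -2.477, 5.402, 0.000),  # C1'
    ncol = 3L, byrow = TRUE,
    dimnames = list(c("N1","C2","O2","N3","C4","N4","C5","C6","C1'"), NULL)),
  T = matrix(c(
    -1.284, 4.500, 0.000,   # N1
    -1.462, 3.135, 0.000,   # C2
    -2.562, 2.608, 0.000,   # O2
    -0.298, 2.407, 0.000,   # N3
     0.994, 2.897, 0.000,   # C4
     1.944, 2.119, 0.000,   # O4
     1.106, 4.338, 0.000,   # C5
     2.466, 4.961, 0.000,   # C7
    -0.024, 5.057, 0.000,   # C6
    -2.481, 5.354, 0.000),  # C1'
    ncol = 3L, byrow = TRUE,
    dimnames = list(c("N1","C2","O2","N3","C4","O4","C5","C7","C6","C1'"), NULL))
)

# Fixed fiber-B offset of the backbone phosphorus pseudo-atom in the base
# frame (x, y, z): at the canonical ~9 A helical radius, phased and lifted
# so a straight fiber build reproduces B-DNA groove dimensions (raw
# cross-strand P-P minima ~11.7 A minor / ~18.2 A major).
.p_offset <- c(-5.00, 7.42, 1.60)

.purines <- c("A", "G")

.is_purine <- function(base) base %in% .purines

# glycosidic nitrogen and the chi reference ring atom per base type
.glyco_n <- function(base) if (.is_purine(base)) "N9" else "N1"
.chi_ref <- function(base) if (.is_purine(base)) "C4" else "C2"

# atoms used when fitting a base reference frame: the planar base heavy
# atoms (rings + exocyclic partners), excluding C1'/O4'/P which carry the
# sugar/backbone degrees of freedom.
.frame_atoms <- function(base) {
  nm <- rownames(.base_coords[[base]])
  setdiff(nm, "C1'")
}

# Hydrogen-bond chemistry of the reduced-atom bases. Donors carry implicit
# hydrogens reconstructed from the heavy-atom geometry; "ante" lists the
# covalent neighbours used to orient the pseudo-hydrogen(s).
.hb_donors <- list(
  A = list(N6 = c("C6")),
  G = list(N1 = c("C2", "C6"), N2 = c("C2")),
  C = list(N4 = c("C4")),
  T = list(N3 = c("C2", "C4"))
)

.hb_acceptors <- list(
  A = c("N1", "N3", "N7"),
  G = c("O6", "N3", "N7"),
  C = c("O2", "N3"),
  T = c("O2", "O4")
)

# sugar acceptor present on every nucleotide of the reduced model
.sugar_acceptors <- "O4'"

.complement <- c(A = "T", T = "A", G = "C", C = "G")

#' Idealized base geometry
#'
#' Heavy-atom coordinates of one idealized planar base (plus the C1' anchor)
#' in its standard reference frame.
#'
#' @param base one of "A", "C", "G", "T".
#' @return matrix of coordinates (rows named by atom).
#' @export
standard_base <- function(base) {
  base <- match.arg(base, c("A", "C", "G", "T"))
  .base_coords[[base]]
}
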