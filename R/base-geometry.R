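# Idealized planar nucleobase geometries, transcribed from the standard
# reference-frame coordinate convention for nucleic acid bases (Olson et al.
# 2001, J Mol Biol 313:229-237). Each base lies in the z = 0 plane with its
# glycosidic C1' included; coordinates in Angstrom. Internal consistency of
# the transcription is asserted by the package tests (ring bond lengths and
# the Watson-Crick face geometry).

.base_coords <- local({
  m <- function(...) {
    v <- c(...)
    out <- matrix(as.numeric(v[c(FALSE, TRUE, TRUE)]), ncol = 2, byrow = TRUE)
    out <- cbind(out, 0)
    rownames(out) <- v[c(TRUE, FALSE, FALSE)]
    colnames(out) <- c("x", "y", "z")
    out
  }
  list(
    A = m("C1'", -2.479, 5.346,  "N9", -1.291, 4.498,  "C8", 0.024, 4.897,
          "N7", 0.877, 3.902,  "C5", 0.071, 2.771,  "C6", 0.369, 1.398,
          "N6", 1.611, 0.909,  "N1", -0.668, 0.532,  "C2", -1.912, 1.023,
          "N3", -2.320, 2.290,  "C4", -1.267, 3.124),
    G = m("C1'", -2.477, 5.399,  "N9", -1.289, 4.551,  "C8", 0.023, 4.962,
          "N7", 0.870, 3.969,  "C5", 0.071, 2.833,  "C6", 0.424, 1.460,
          "O6", 1.554, 0.955,  "N1", -0.700, 0.641,  "C2", -1.999, 1.087,
          "N2", -2.949, 0.139,  "N3", -2.342, 2.364,  "C4", -1.265, 3.177),
    C = m("C1'", -2.477, 5.402,  "N1", -1.285, 4.542,  "C2", -1.472, 3.158,
          "O2", -2.628, 2.709,  "N3", -0.391, 2.344,  "C4", 0.837, 2.868,
          "N4", 1.875, 2.027,  "C5", 1.056, 4.275,  "C6", -0.023, 5.068),
    U = m("C1'", -2.481, 5.354,  "N1", -1.284, 4.500,  "C2", -1.462, 3.131,
          "O2", -2.563, 2.608,  "N3", -0.302, 2.397,  "C4", 0.989, 2.884,
          "O4", 1.935, 2.094,  "C5", 1.089, 4.311,  "C6", -0.024, 5.053)
  )
})

# covalent bonds within each base (used for donor-angle checks and the
# ring-geometry sanity test)
.base_bonds <- list(
  A = rbind(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
            c("C5", "C4"), c("C4", "N9"), c("C5", "C6"), c("C6", "N6"),
            c("C6", "N1"), c("N1", "C2"), c("C2", "N3"), c("N3", "C4")),
  G = rbind(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
            c("C5", "C4"), c("C4", "N9"), c("C5", "C6"), c("C6", "O6"),
            c("C6", "N1"), c("N1", "C2"), c("C2", "N2"), c("C2", "N3"),
            c("N3", "C4")),
  C = rbind(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
            c("N3", "C4"), c("C4", "N4"), c("C4", "C5"), c("C5", "C6"),
            c("C6", "N1")),
  U = rbind(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
            c("N3", "C4"), c("C4", "O4"), c("C4", "C5"), c("C5", "C6"),
            c("C6", "N1"))
)

# H-bond chemistry inferred from heavy atoms (hydrogens are not required)
.base_donors <- list(A = c("N6"), G = c("N1", "N2"), C = c("N4"), U = c("N3"))
.base_acceptors <- list(A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
                        C = c("O2", "N3"), U = c("O2", "O4"))

# Leontis-Westhof edge membership; atoms on the border of two edges (N6/O6
# between WC and Hoogsteen, C2/N2/O2 between WC and Sugar) belong to both,
# and the majority vote over a pair's H-bonded atoms resolves the edge.
.edge_members <- list(
  purine = list(WC = c("N1", "C2", "N6", "O6"),
                Hoogsteen = c("N7", "C8", "N6", "O6"),
                Sugar = c("N3", "C2", "N2", "O2'")),
  pyrimidine = list(WC = c("N3", "N4", "O4", "O2"),
                    Hoogsteen = c("C5", "C6", "N4", "O4"),
                    Sugar = c("O2", "O2'"))
)

# H-bond templates for idealized pair construction: list of (atom on base5,
# atom on base3) heavy-atom contacts closed at 2.9 A. Keys are
# base5|edge5|base3|edge3|orientation.
.pair_templates <- list(
  # canonical cis Watson-Crick/Watson-Crick
  "A|WC|U|WC|cis" = list(c("N1", "N3"), c("N6", "O4")),
  "U|WC|A|WC|cis" = list(c("N3", "N1"), c("O4", "N6")),
  "G|WC|C|WC|cis" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  "C|WC|G|WC|cis" = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
  # GoU wobble (cis WC/WC family)
  "G|WC|U|WC|cis" = list(c("N1", "O2"), c("O6", "N3")),
  "U|WC|G|WC|cis" = list(c("O2", "N1"), c("N3", "O6")),
  # trans Watson-Crick/Watson-Crick (reverse WC): the 15/48 tertiary pair
  "G|WC|C|WC|trans" = list(c("N1", "O2"), c("N2", "N3")),
  "C|WC|G|WC|trans" = list(c("O2", "N1"), c("N3", "N2")),
  "A|WC|U|WC|trans" = list(c("N1", "N3"), c("N6", "O2")),
  "U|WC|A|WC|trans" = list(c("N3", "N1"), c("O2", "N6")),
  "A|WC|A|WC|trans" = list(c("N6", "N1"), c("N1", "N6")),
  # trans Watson-Crick/Hoogsteen: the 54/58 T-loop pair (U54oA58 is the
  # reverse Hoogsteen, bonding through O2 of U) and its A54oA58 variant
  "U|WC|A|Hoogsteen|trans" = list(c("N3", "N7"), c("O2", "N6")),
  "A|WC|A|Hoogsteen|trans" = list(c("N6", "N7"), c("N1", "N6"))
)

# PDB residue name -> parent base for modified residues
.residue_parent <- c(
  A = "A", ADE = "A", RA = "A", `1MA` = "A", MIA = "A", `6MA` = "A", MA6 = "A",
  G = "G", GUA = "G", RG = "G", `2MG` = "G", M2G = "G", `7MG` = "G",
  OMG = "G", YG = "G", QUO = "G", G7M = "G",
  C = "C", CYT = "C", RC = "C", `5MC` = "C", OMC = "C",
  U = "U", URA = "U", URI = "U", RU = "U", `5MU` = "U", T = "U", PSU = "U",
  H2U = "U", `4SU` = "U", UMS = "U", DHU = "U"
)

#' Residue-name to parent-base table
#'
#' Editable mapping from PDB residue names (including common modified
#' nucleotides such as 5MU, 1MA, PSU, H2U) to the parent base A/C/G/U.
#'
#' @param extra Optional named character vector of additional mappings.
#' @return Named character vector, names are residue names.
#' @export
residue_parent_table <- function(extra = NULL) {
  tab <- .residue_parent
  if (!is.null(extra)) tab[names(extra)] <- extra
  tab
}

#' Idealized coordinates of a standard base
#'
#' @param base One of "A", "C", "G", "U".
#' @return A \code{residue_coords} object in the base's standard reference
#'   frame (planar, z = 0), including C1'.
#' @export
standard_base <- function(base) {
  base <- match.arg(base, RNA_BASES)
  new_residue_coords(base, base, .base_coords[[base]])
}
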