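# Embedded nonbonded parameter table (AMBER ff14SB-family heavy atoms) for
# the residues used in adhesive modules: Pro, Gly, Arg, Glu. Hydrogens are
# subsumed into heavy-atom charges (united-atom style); each residue's
# charges sum to its formal charge. sigma in Angstrom, epsilon in kcal/mol.
# The table is data and can be swapped wholesale via build arguments.

ff_table <- function() {
  bb <- function(resid, npro = FALSE) {
    data.frame(
      resid = resid,
      atom = c("N", "CA", "C", "O"),
      charge = c(if (npro) -0.25 else -0.15, 0.10, 0.60, -0.55),
      sigma = c(3.25, 3.40, 3.40, 2.96),
      epsilon = c(0.17, 0.1094, 0.086, 0.21),
      sidechain = FALSE)
  }
  side <- function(resid, atom, charge, sigma, epsilon) {
    data.frame(resid = resid, atom = atom, charge = charge,
               sigma = sigma, epsilon = epsilon, sidechain = TRUE)
  }
  rbind(
    bb("G"),
    bb("P", npro = TRUE),
    side("P", c("CB", "CG", "CD"), c(0.03, 0.02, 0.05),
         rep(3.40, 3), rep(0.1094, 3)),
    bb("R"),
    side("R", c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
         c(0.05, 0.05, 0.10, 0.15, 0.35, 0.15, 0.15),
         c(3.40, 3.40, 3.40, 3.25, 3.40, 3.25, 3.25),
         c(0.1094, 0.1094, 0.1094, 0.17, 0.086, 0.17, 0.17)),
    bb("E"),
    side("E", c("CB", "CG", "CD", "OE1", "OE2"),
         c(0.00, -0.10, 0.50, -0.70, -0.70),
         c(3.40, 3.40, 3.40, 2.96, 2.96),
         c(0.1094, 0.1094, 0.086, 0.21, 0.21))
  )
}

# Backbone-independent mini rotamer library for the two charged sidechains:
# azimuth alpha (deg, about the helix axis) and elevation beta (deg, toward
# the axis direction) of the sidechain extension vector.
rotamer_library <- function() {
  list(
    R = data.frame(alpha = c(0, 40, -40), beta = c(0, 25, -25)),
    E = data.frame(alpha = c(0, 40, -40), beta = c(0, 25, -25))
  )
}
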