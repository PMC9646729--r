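# Shared fixtures and independent oracles.

# Literal enumeration oracle for the stagger scan: every ordered pair (i, j)
# with |i - (j + shift)| within the class window contributes its pair score.
# Kept independent of the package's scan implementation.
oracle_stagger_scan <- function(seq1, seq2, params = score_params()) {
  class_of <- function(ch) {
    if (ch %in% params$basic) "basic"
    else if (ch %in% params$acidic) "acidic"
    else if (ch %in% params$hydrophobic) "hyd"
    else "other"
  }
  c1 <- vapply(strsplit(seq1, "")[[1]], class_of, character(1))
  c2 <- vapply(strsplit(seq2, "")[[1]], class_of, character(1))
  n1 <- length(c1); n2 <- length(c2)
  shifts <- seq(-(n2 - 1L), n1 - 1L)
  score <- integer(length(shifts))
  for (si in seq_along(shifts)) {
    s <- shifts[si]
    total <- 0L
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        d <- abs(i - (j + s))
        a <- c1[i]; b <- c2[j]
        if (a %in% c("basic", "acidic") && b %in% c("basic", "acidic")) {
          if (d <= params$charge_window) {
            total <- total + if (a == b) -1L else 1L
          }
        } else if (a == "hyd" && b == "hyd") {
          if (d <= params$hydrophobic_window) total <- total + 1L
        }
      }
    }
    score[si] <- total
  }
  data.frame(shift = shifts, score = score)
}

rand_collagen_seq <- function(n_res, pool = c("A", "S", "K", "E", "P", "L", "G", "T")) {
  paste(sample(pool, n_res, replace = TRUE), collapse = "")
}

# Minimal hand-built model for closed-form energy checks: one atom per
# "helix", mirroring the triple_helix atom-table contract.
point_model <- function(x = 0, y = 0, z = 0, charge = 0, sigma = 3.0,
                        epsilon = 0.2, resid = "G", atom = "CA",
                        chain = 1L, resno = 1L) {
  structure(list(
    sequence = resid,
    atoms = data.frame(chain = chain, resno = resno, resid = resid,
                       atom = atom, x = x, y = y, z = z, charge = charge,
                       sigma = sigma, epsilon = epsilon, sidechain = FALSE),
    charged = list()),
    class = "triple_helix")
}

# The observed banding outcomes for the full design panel.
competent_designs <- c("P8-B-P8", "P10-B-P10", "P12-B-P12", "P10-A-P10",
                       "P10-C-P10", "P10-B-B-P10", "P10-A-B-C-P10", "R5-B-E5")
incompetent_designs <- c("P5-B-P5", "P5-B-B-P5", "R3-B-E3", "R1-B-E1",
                         "P10-B", "B-P10", "Bh-P10-Bh")
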