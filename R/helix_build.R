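# Idealized triple-helix coordinate builder.
#
# Three Xaa-Yaa-Gly chains are placed on a left-handed superhelix of the
# 7/2 symmetry class (7 triplets per 2 superhelical turns, i.e. -34.29 deg
# twist per residue) with a configurable per-residue axial rise, chains
# related by a 120 deg rotation and a one-residue axial stagger. Glycine
# C-alphas sit at a smaller radius than Xaa/Yaa C-alphas, so Gly faces the
# core as in the collagen fold. Backbone and sidechain atoms are placed from
# simple local-frame offsets; this is a coarse rigid model built for
# inter-helix packing energetics, not a crystallographic reconstruction.

#' Geometry configuration for the triple-helix builder
#'
#' @param rise axial rise per residue in Angstrom (default 2.9).
#' @param twist_per_residue superhelical twist per residue in degrees
#'   (default -360 * 2 / 21, the 7/2 symmetry class).
#' @param radius_ca C-alpha superhelix radius for Xaa/Yaa residues (Angstrom).
#' @param radius_gly C-alpha radius for Gly (smaller: Gly faces the core).
#' @return a `helix_config` list.
#' @export
helix_config <- function(rise = 2.9, twist_per_residue = -360 * 2 / 21,
                         radius_ca = 2.7, radius_gly = 2.2) {
  stopifnot(rise > 0, radius_ca > radius_gly, radius_gly > 0)
  structure(list(rise = rise, twist = twist_per_residue * pi / 180,
                 radius_ca = radius_ca, radius_gly = radius_gly),
            class = "helix_config")
}

# sidechain atom offsets from CA in the local frame (u outward radial,
# tv tangential, k axial); returns matrix with rownames = atom names.
sidechain_geometry <- function(resid, CA, N, u, tv, k, alpha = 0, beta = 0) {
  rot_dir <- function(a, b) {
    ar <- a * pi / 180; br <- b * pi / 180
    d <- cos(br) * (cos(ar) * u + sin(ar) * tv) + sin(br) * k
    d / sqrt(sum(d^2))
  }
  unit <- function(v) v / sqrt(sum(v^2))
  if (resid == "P") {
    # pyrrolidine ring closing back to N (fixed, no rotamers)
    rbind(
      CB = CA + 1.52 * unit(u + 0.25 * tv - 0.35 * k),
      CG = CA + 2.35 * unit(u + 0.10 * tv - 0.55 * k),
      CD = N + 1.47 * unit(0.8 * u + 0.4 * tv))
  } else if (resid == "R") {
    d <- rot_dir(alpha, beta)
    b1 <- unit(d - sum(d * k) * k); b2 <- k # branch plane
    CZ <- CA + 5 * 1.45 * d
    rbind(
      CB = CA + 1.45 * d, CG = CA + 2 * 1.45 * d, CD = CA + 3 * 1.45 * d,
      NE = CA + 4 * 1.45 * d, CZ = CZ,
      NH1 = CZ + 1.33 * unit(cos(55 * pi / 180) * d + sin(55 * pi / 180) * b2),
      NH2 = CZ + 1.33 * unit(cos(55 * pi / 180) * d - sin(55 * pi / 180) * b2))
  } else if (resid == "E") {
    d <- rot_dir(alpha, beta)
    b2 <- k
    CD <- CA + 3 * 1.45 * d
    rbind(
      CB = CA + 1.45 * d, CG = CA + 2 * 1.45 * d, CD = CD,
      OE1 = CD + 1.25 * unit(cos(55 * pi / 180) * d + sin(55 * pi / 180) * b2),
      OE2 = CD + 1.25 * unit(cos(55 * pi / 180) * d - sin(55 * pi / 180) * b2))
  } else {
    NULL
  }
}

#' Build an idealized triple-helix model
#'
#' @param sequence one chain's residue string (Gly every third residue); the
#'   model is a homotrimer of this chain. Supported residues: P, G, R, E.
#' @param config a [helix_config()].
#' @return a `triple_helix` object: atom table (chain, resno, resid, atom,
#'   coordinates, charge, LJ sigma/epsilon), per-residue local frames, and
#'   precomputed rotamer coordinate sets for Arg/Glu sidechains. Coordinates
#'   are centered so the helix axis is the z-axis through the origin.
#' @export
build_triple_helix <- function(sequence, config = helix_config()) {
  chars <- seq_chars(sequence)
  nres <- length(chars)
  if (nres < 3L || nres %% 3L != 0L) stop("sequence must be whole triplets")
  if (!all(chars[seq(3, nres, by = 3)] == "G")) {
    stop("non-collagen sequence: Gly required at every third position")
  }
  if (!all(chars %in% c("P", "G", "R", "E"))) {
    stop("unsupported residue(s): builder covers P, G, R, E")
  }
  ff <- ff_table()
  rots <- rotamer_library()

  rows <- list(); frames <- list(); ri <- 0L
  for (chain in 0:2) {
    for (t in seq_len(nres) - 1L) {
      ri <- ri + 1L
      resid <- chars[t + 1L]
      phi <- config$twist * t + chain * 2 * pi / 3
      rad <- if (resid == "G") config$radius_gly else config$radius_ca
      z <- (t + chain) * config$rise
      u <- c(cos(phi), sin(phi), 0)
      tv <- c(-sin(phi), cos(phi), 0)
      k <- c(0, 0, 1)
      CA <- rad * u + c(0, 0, z)
      tang <- config$twist * rad * tv + config$rise * k
      tang <- tang / sqrt(sum(tang^2))
      N <- CA - 1.30 * tang
      C <- CA + 1.00 * tang
      w <- c(tang[2] * u[3] - tang[3] * u[2],
             tang[3] * u[1] - tang[1] * u[3],
             tang[1] * u[2] - tang[2] * u[1])
      O <- C + 1.23 * w / sqrt(sum(w^2))
      xyz <- rbind(N = N, CA = CA, C = C, O = O)
      sc <- sidechain_geometry(resid, CA, N, u, tv, k)
      if (!is.null(sc)) xyz <- rbind(xyz, sc)
      pars <- ff[ff$resid == resid, ]
      pars <- pars[match(rownames(xyz), pars$atom), ]
      rows[[ri]] <- data.frame(chain = chain + 1L, resno = t + 1L,
                               resid = resid, atom = rownames(xyz),
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               charge = pars$charge, sigma = pars$sigma,
                               epsilon = pars$epsilon,
                               sidechain = pars$sidechain)
      frames[[ri]] <- list(chain = chain + 1L, resno = t + 1L, resid = resid,
                           CA = CA, N = N, u = u, tv = tv, k = k)
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  ctr <- colMeans(atoms[, c("x", "y", "z")])
  atoms$x <- atoms$x - ctr[1]; atoms$y <- atoms$y - ctr[2]; atoms$z <- atoms$z - ctr[3]

  # precompute rotamer coordinate sets for charged sidechains
  charged <- list()
  for (fr in frames) {
    if (!fr$resid %in% c("R", "E")) next
    idx <- which(atoms$chain == fr$chain & atoms$resno == fr$resno & atoms$sidechain)
    lib <- rots[[fr$resid]]
    coords <- lapply(seq_len(nrow(lib)), function(r) {
      sc <- sidechain_geometry(fr$resid, fr$CA, fr$N, fr$u, fr$tv, fr$k,
                               alpha = lib$alpha[r], beta = lib$beta[r])
      sweep(sc, 2, ctr) # same centering as the atom table
    })
    charged[[length(charged) + 1L]] <- list(chain = fr$chain, resno = fr$resno,
                                            resid = fr$resid, rows = idx,
                                            coords = coords, rotamer = 1L)
  }
  structure(list(sequence = sequence, atoms = atoms, config = config,
                 charged = charged),
            class = "triple_helix")
}

#' @export
print.triple_helix <- function(x, ...) {
  cat(sprintf("<triple_helix> %d residues/chain x 3 chains, %d atoms, %d rotameric sidechains\n",
              nchar(x$sequence), nrow(x$atoms), length(x$charged)))
  invisible(x)
}

#' Set sidechain rotamers on a triple-helix model
#'
#' @param model a `triple_helix`.
#' @param rotamers integer vector, one entry per charged (Arg/Glu) sidechain
#'   in `model$charged` order.
#' @return the model with sidechain coordinates rebuilt.
#' @export
set_rotamers <- function(model, rotamers) {
  stopifnot(length(rotamers) == length(model$charged))
  for (i in seq_along(model$charged)) {
    ch <- model$charged[[i]]
    r <- rotamers[i]
    stopifnot(r >= 1L, r <= length(ch$coords))
    model$atoms[ch$rows, c("x", "y", "z")] <- ch$coords[[r]]
    model$charged[[i]]$rotamer <- r
  }
  model
}

coords_matrix <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

#' Principal-axis alignment diagnostics
#'
#' Returns the dominant principal axis of the atom cloud; for a model built
#' by [build_triple_helix()] this is the z-axis (the projection of the
#' inertial long axis on the x-y plane is minimal by construction).
#'
#' @param model a `triple_helix`.
#' @return unit vector of the first principal component.
#' @export
principal_axis <- function(model) {
  p <- prcomp(coords_matrix(model), center = TRUE)
  v <- p$rotation[, 1]
  v / sqrt(sum(v^2))
}
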