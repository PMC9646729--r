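# Rigid-body association energetics of two triple helices.
#
# A pose of the off-centered helix relative to the central one is described
# by five parameters: Omega (tilt, 0 or 180 deg for parallel/antiparallel),
# theta (revolution about the central helix), phi (self-rotation), r
# (inter-axial distance, Angstrom) and dh (axial offset, Angstrom). The
# interaction energy is the inter-model pairwise sum only (both helices are
# internally rigid): 12-6 Lennard-Jones with a 6.0 A cutoff plus Coulomb
# with a distance-dependent dielectric. Poses are optimized by Metropolis
# simulated annealing; for Arg/Glu-bearing models the move set includes
# discrete sidechain rotamer swaps.

#' Rigid-body pose of the off-centered helix
#'
#' @param omega tilt angle in degrees, 0 (parallel) or 180 (antiparallel).
#' @param theta revolution angle about the central helix (degrees).
#' @param phi self-rotation of the off-centered helix (degrees).
#' @param r inter-axial distance (Angstrom, > 0).
#' @param dh axial offset (Angstrom).
#' @return a `rigid_pose` list.
#' @export
rigid_pose <- function(omega = 0, theta = 0, phi = 0, r = 12, dh = 0) {
  stopifnot(omega %in% c(0, 180), r > 0)
  structure(list(omega = omega, theta = theta, phi = phi, r = r, dh = dh),
            class = "rigid_pose")
}

#' Nonbonded energy parameters
#'
#' @param lj_cutoff Lennard-Jones distance cutoff (Angstrom, default 6.0).
#' @param coul_cutoff Coulomb cutoff (default 12.0; electrostatics are
#'   longer-ranged than packing).
#' @param dielectric_k distance-dependent dielectric slope, eps(d) =
#'   `dielectric_k * d` (default 4, standard implicit-solvent screening for
#'   rigid vacuum docking).
#' @param coulomb_const electrostatic constant in kcal*A/(mol*e^2).
#' @return an `energy_params` list.
#' @export
energy_params <- function(lj_cutoff = 6.0, coul_cutoff = 12.0,
                          dielectric_k = 4.0, coulomb_const = 332.0637) {
  structure(list(lj_cutoff = lj_cutoff, coul_cutoff = coul_cutoff,
                 dielectric_k = dielectric_k, coulomb_const = coulomb_const),
            class = "energy_params")
}

# Apply a rigid pose to a coordinate matrix: self-rotate (phi), tilt (Omega
# about x), offset by (r, 0, dh), then revolve about the central axis (theta).
transform_pose <- function(xyz, pose) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  rx <- function(a) {
    a <- a * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  }
  out <- xyz %*% t(rx(pose$omega) %*% rz(pose$phi))
  out[, 1] <- out[, 1] + pose$r
  out[, 3] <- out[, 3] + pose$dh
  out %*% t(rz(pose$theta))
}

#' Inter-helix interaction energy of a pose
#'
#' @param m1,m2 `triple_helix` models (m1 is the fixed central helix).
#' @param pose a [rigid_pose()].
#' @param params an [energy_params()].
#' @return an `energy_report`: list with `lj_kcal_mol`, `coulomb_kcal_mol`,
#'   `total_kcal_mol`.
#' @export
interaction_energy <- function(m1, m2, pose, params = energy_params()) {
  xyz2 <- transform_pose(coords_matrix(m2), pose)
  e <- cpp_pair_energy(coords_matrix(m1), xyz2,
                       m1$atoms$charge, m2$atoms$charge,
                       m1$atoms$sigma, m2$atoms$sigma,
                       m1$atoms$epsilon, m2$atoms$epsilon,
                       params$lj_cutoff, params$coul_cutoff,
                       params$dielectric_k, params$coulomb_const)
  energy_report(e[1], e[2])
}

energy_report <- function(lj, coul) {
  structure(list(lj_kcal_mol = lj, coulomb_kcal_mol = coul,
                 total_kcal_mol = lj + coul),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> LJ %.2f + Coulomb %.2f = %.2f kcal/mol\n",
              x$lj_kcal_mol, x$coulomb_kcal_mol, x$total_kcal_mol))
  invisible(x)
}

#' Simulated-annealing configuration
#'
#' @param steps Metropolis steps (default 16000).
#' @param t_start,t_end temperature schedule endpoints (default 40 to 0.001;
#'   geometric cooling).
#' @param seed RNG seed.
#' @param move_theta,move_phi,move_r,move_dh move half-widths per step
#'   (degrees, degrees, Angstrom, Angstrom).
#' @param rotamer_prob probability of proposing a rotamer swap instead of a
#'   rigid-body move when rotameric sidechains are present.
#' @return an `anneal_config` list.
#' @export
anneal_config <- function(steps = 16000L, t_start = 40, t_end = 0.001,
                          seed = 1L, move_theta = 10, move_phi = 10,
                          move_r = 0.5, move_dh = 1.0, rotamer_prob = 0.2) {
  stopifnot(steps >= 1L, t_start > t_end, t_end > 0)
  structure(list(steps = as.integer(steps), t_start = t_start, t_end = t_end,
                 seed = seed, move_theta = move_theta, move_phi = move_phi,
                 move_r = move_r, move_dh = move_dh,
                 rotamer_prob = rotamer_prob),
            class = "anneal_config")
}

#' Optimize the rigid-body association of two triple helices
#'
#' Metropolis simulated annealing over (theta, phi, r, dh) at fixed Omega,
#' with discrete Arg/Glu rotamer swaps when either model carries rotameric
#' sidechains. Cooling is geometric between the configured endpoints.
#'
#' @param m1,m2 `triple_helix` models.
#' @param omega tilt angle, 0 or 180 degrees.
#' @param anneal an [anneal_config()].
#' @param params an [energy_params()].
#' @param pose0 optional starting [rigid_pose()]; by default the helices
#'   start side by side just outside contact.
#' @param diagnostics record every uphill proposal (for acceptance-rate
#'   checks); off by default.
#' @return list with `pose` (best), `energy` (energy_report at best),
#'   `trajectory` (best-so-far total energy per step, non-increasing),
#'   `rotamers1`/`rotamers2` (best rotamer assignments), `m1`/`m2` (models
#'   with best rotamers applied) and optionally `uphill` diagnostics.
#' @export
optimize_pose <- function(m1, m2, omega = 0, anneal = anneal_config(),
                          params = energy_params(), pose0 = NULL,
                          diagnostics = FALSE) {
  radial <- function(m) max(sqrt(m$atoms$x^2 + m$atoms$y^2))
  if (is.null(pose0)) {
    pose0 <- rigid_pose(omega = omega, r = radial(m1) + radial(m2) + 1.5)
  } else {
    pose0$omega <- omega
  }
  nrot1 <- length(m1$charged); nrot2 <- length(m2$charged)
  with_seed(anneal$seed, {
    pose <- pose0
    rot1 <- rep(1L, nrot1); rot2 <- rep(1L, nrot2)
    if (nrot1) m1 <- set_rotamers(m1, rot1)
    if (nrot2) m2 <- set_rotamers(m2, rot2)
    e <- interaction_energy(m1, m2, pose, params)$total_kcal_mol
    best <- list(pose = pose, rot1 = rot1, rot2 = rot2, e = e)
    traj <- numeric(anneal$steps)
    cool <- (anneal$t_end / anneal$t_start)^(1 / anneal$steps)
    temp <- anneal$t_start
    # axial offsets beyond half the helix length lose the contact interface;
    # dh moves reflect at that bound
    dh_max <- max(diff(range(m1$atoms$z)), diff(range(m2$atoms$z))) / 2
    restart_every <- max(100L, anneal$steps %/% 4L)
    up_de <- numeric(0); up_t <- numeric(0); up_acc <- logical(0)
    do_rot <- (nrot1 + nrot2) > 0
    for (k in seq_len(anneal$steps)) {
      # move widths shrink with temperature so the late quench refines the
      # minimum instead of proposing only rejectable jumps
      ws <- max(0.3, sqrt(temp / anneal$t_start))
      cand_pose <- pose; cand1 <- rot1; cand2 <- rot2
      if (do_rot && runif(1) < anneal$rotamer_prob) {
        i <- sample.int(nrot1 + nrot2, 1)
        if (i <= nrot1) {
          nr <- length(m1$charged[[i]]$coords)
          cand1[i] <- sample(setdiff(seq_len(nr), rot1[i]), 1)
        } else {
          i2 <- i - nrot1
          nr <- length(m2$charged[[i2]]$coords)
          cand2[i2] <- sample(setdiff(seq_len(nr), rot2[i2]), 1)
        }
      } else {
        which_par <- sample(4L, 1)
        if (which_par == 1L) {
          cand_pose$theta <- cand_pose$theta + runif(1, -1, 1) * ws * anneal$move_theta
        } else if (which_par == 2L) {
          cand_pose$phi <- cand_pose$phi + runif(1, -1, 1) * ws * anneal$move_phi
        } else if (which_par == 3L) {
          r <- cand_pose$r + runif(1, -1, 1) * ws * anneal$move_r
          cand_pose$r <- if (r < 2) 4 - r else r # reflect at r = 2
        } else {
          dh <- cand_pose$dh + runif(1, -1, 1) * ws * anneal$move_dh
          if (dh > dh_max) dh <- 2 * dh_max - dh
          if (dh < -dh_max) dh <- -2 * dh_max - dh
          cand_pose$dh <- dh
        }
      }
      if (!identical(cand1, rot1)) m1 <- set_rotamers(m1, cand1)
      if (!identical(cand2, rot2)) m2 <- set_rotamers(m2, cand2)
      ecand <- interaction_energy(m1, m2, cand_pose, params)$total_kcal_mol
      de <- ecand - e
      accept <- de <= 0 || runif(1) < exp(-de / temp)
      if (diagnostics && de > 0) {
        up_de <- c(up_de, de); up_t <- c(up_t, temp); up_acc <- c(up_acc, accept)
      }
      if (accept) {
        pose <- cand_pose; rot1 <- cand1; rot2 <- cand2; e <- ecand
        if (e < best$e) best <- list(pose = pose, rot1 = rot1, rot2 = rot2, e = e)
      } else {
        if (!identical(cand1, rot1)) m1 <- set_rotamers(m1, rot1)
        if (!identical(cand2, rot2)) m2 <- set_rotamers(m2, rot2)
      }
      traj[k] <- best$e
      temp <- temp * cool
      # periodic return to the best-so-far basin so the quench refines it
      # instead of whatever the hot phase wandered into
      if (k %% restart_every == 0L && e > best$e) {
        pose <- best$pose; rot1 <- best$rot1; rot2 <- best$rot2; e <- best$e
        if (nrot1) m1 <- set_rotamers(m1, rot1)
        if (nrot2) m2 <- set_rotamers(m2, rot2)
      }
    }
    if (nrot1) m1 <- set_rotamers(m1, best$rot1)
    if (nrot2) m2 <- set_rotamers(m2, best$rot2)
    out <- list(pose = best$pose,
                energy = interaction_energy(m1, m2, best$pose, params),
                trajectory = traj, rotamers1 = best$rot1, rotamers2 = best$rot2,
                m1 = m1, m2 = m2)
    if (diagnostics) {
      out$uphill <- data.frame(de = up_de, temp = up_t, accepted = up_acc)
    }
    out
  })
}

#' Detect interhelical salt bridges in a pose
#'
#' Pairs an Arg guanidinium nitrogen (NE/NH1/NH2) of one model with a Glu
#' carboxylate oxygen (OE1/OE2) of the other, in both directions, within the
#' distance cutoff.
#'
#' @param m1,m2 `triple_helix` models (with rotamers applied, e.g. the models
#'   returned by [optimize_pose()]).
#' @param pose the [rigid_pose()] relating them.
#' @param cutoff maximum N-O distance in Angstrom (default 4.0).
#' @return data.frame of bridges sorted by distance (possibly empty).
#' @export
find_salt_bridges <- function(m1, m2, pose, cutoff = 4.0) {
  xyz2 <- transform_pose(coords_matrix(m2), pose)
  a1 <- m1$atoms; a2 <- m2$atoms
  pick <- function(a, resid, atoms) which(a$resid == resid & a$atom %in% atoms)
  guan <- c("NE", "NH1", "NH2"); carb <- c("OE1", "OE2")
  out <- list()
  cross <- function(iN, iO, xyzN, xyzO, aN, aO, dir) {
    if (!length(iN) || !length(iO)) return(NULL)
    d <- sqrt(outer(xyzN[iN, 1], xyzO[iO, 1], "-")^2 +
              outer(xyzN[iN, 2], xyzO[iO, 2], "-")^2 +
              outer(xyzN[iN, 3], xyzO[iO, 3], "-")^2)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(
      arg_model = if (dir == 1) 1L else 2L,
      arg_chain = aN$chain[iN[hit[, 1]]], arg_resno = aN$resno[iN[hit[, 1]]],
      arg_atom = aN$atom[iN[hit[, 1]]],
      glu_chain = aO$chain[iO[hit[, 2]]], glu_resno = aO$resno[iO[hit[, 2]]],
      glu_atom = aO$atom[iO[hit[, 2]]],
      distance = d[hit])
  }
  xyz1 <- coords_matrix(m1)
  out[[1]] <- cross(pick(a1, "R", guan), pick(a2, "E", carb), xyz1, xyz2, a1, a2, 1)
  out[[2]] <- cross(pick(a2, "R", guan), pick(a1, "E", carb), xyz2, xyz1, a2, a1, 2)
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(arg_model = integer(0), arg_chain = integer(0),
                      arg_resno = integer(0), arg_atom = character(0),
                      glu_chain = integer(0), glu_resno = integer(0),
                      glu_atom = character(0), distance = numeric(0))
  }
  out[order(out$distance), , drop = FALSE]
}

#' Write one or two posed triple helices as a PDB file
#'
#' Chains A-C hold the central helix; when a second model and pose are given
#' its transformed copy occupies chains D-F.
#'
#' @param m1 central `triple_helix`.
#' @param file output path.
#' @param m2 optional off-centered model.
#' @param pose pose of `m2` (required with `m2`).
#' @return `file`, invisibly.
#' @export
write_helix_pdb <- function(m1, file, m2 = NULL, pose = NULL) {
  three <- c(P = "PRO", G = "GLY", R = "ARG", E = "GLU")
  tab <- m1$atoms
  tab$chain_id <- LETTERS[tab$chain]
  xyz <- coords_matrix(m1)
  if (!is.null(m2)) {
    stopifnot(!is.null(pose))
    t2 <- m2$atoms
    t2$chain_id <- LETTERS[3L + t2$chain]
    nres1 <- max(tab$resno)
    xyz <- rbind(xyz, transform_pose(coords_matrix(m2), pose))
    tab <- rbind(tab, t2)
  }
  bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)),
                   resno = tab$resno, resid = three[tab$resid],
                   chain = tab$chain_id, elety = tab$atom,
                   eleno = seq_len(nrow(tab)))
  invisible(file)
}

#' Association-energy series over adhesive module lengths
#'
#' Builds adhesive-module homotrimer models and optimizes their pairwise
#' association for a series of module lengths, repeating over seeds. For
#' hydrophobic modules both helices are (PPG)n; for electrostatic modules an
#' Arg helix is packed against a Glu helix (charged triplets adjacent to the
#' interface as in the designs).
#'
#' @param n_values triplet counts to evaluate.
#' @param type `"P"` (hydrophobic) or `"RE"` (electrostatic).
#' @param seeds integer vector of anneal seeds (one run per seed).
#' @param anneal base [anneal_config()]; its seed is replaced per run.
#' @param params an [energy_params()].
#' @param omega tilt angle for all runs.
#' @return data.frame with one row per (n, seed): best total/LJ/Coulomb
#'   energy and optimized inter-axial distance `r`.
#' @export
energy_series <- function(n_values, type = c("P", "RE"), seeds = 1:5,
                          anneal = anneal_config(steps = 3000L),
                          params = energy_params(), omega = 0) {
  type <- match.arg(type)
  rows <- list()
  for (n in n_values) {
    if (type == "P") {
      s1 <- s2 <- strrep("PPG", n)
    } else {
      s1 <- strrep("PRG", n)
      s2 <- strrep("EPG", n)
    }
    m1 <- build_triple_helix(s1)
    m2 <- build_triple_helix(s2)
    for (sd in seeds) {
      a <- anneal; a$seed <- sd
      fit <- optimize_pose(m1, m2, omega = omega, anneal = a, params = params)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, seed = sd, type = type,
        total_kcal_mol = fit$energy$total_kcal_mol,
        lj_kcal_mol = fit$energy$lj_kcal_mol,
        coulomb_kcal_mol = fit$energy$coulomb_kcal_mol,
        r = fit$pose$r, theta = fit$pose$theta, dh = fit$pose$dh)
    }
  }
  do.call(rbind, rows)
}

#' Report designs against an assembly-energy threshold band
#'
#' Computes, per adhesive length, the mean optimized association energy and
#' where it falls relative to a configurable assembly threshold band
#' (default -30 to -50 kcal/mol). The comparison with the banding-competence
#' classifier is reported, not asserted: force-field fidelity differs from
#' an all-atom pipeline.
#'
#' @param series output of [energy_series()].
#' @param band numeric length-2 threshold band (kcal/mol).
#' @return data.frame per n: mean energy, band position
#'   (`above`/`within`/`below`), and the classifier's verdict for the
#'   corresponding symmetric design.
#' @export
energy_threshold_report <- function(series, band = c(-30, -50)) {
  lo <- min(band); hi <- max(band)
  out <- do.call(rbind, lapply(split(series, series$n), function(d) {
    e <- mean(d$total_kcal_mol)
    data.frame(n = d$n[1], type = d$type[1], mean_total_kcal_mol = e,
               band_position = if (e > hi) "above" else if (e < lo) "below" else "within")
  }))
  rownames(out) <- NULL
  out
}
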