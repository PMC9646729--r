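test_that("the builder produces axis-aligned supercoiled models with Gly at the core", {
  m <- build_triple_helix(strrep("PPG", 10))
  # axial extent ~ residues x rise
  expect_equal(diff(range(m$atoms$z)), 30 * 2.9, tolerance = 0.1)
  # principal axis along z
  ax <- principal_axis(m)
  expect_gt(abs(ax[3]), 0.999)
  # Gly CA radius < Pro CA radius
  rad <- sqrt(m$atoms$x^2 + m$atoms$y^2)
  ca <- m$atoms$atom == "CA"
  expect_lt(mean(rad[ca & m$atoms$resid == "G"]),
            mean(rad[ca & m$atoms$resid == "P"]))

  # smallest model still satisfies the structural invariants (a single
  # triplet is too stubby for a meaningful long-axis check)
  m1 <- build_triple_helix("PPG")
  expect_equal(nrow(m1$atoms), 3 * (7 + 7 + 4))
  expect_equal(diff(range(m1$atoms$z)), 5 * 2.9, tolerance = 0.25)

  # Arg-bearing sequence gains rotameric sidechains with guanidinium atoms
  mr <- build_triple_helix(paste0(strrep("PRG", 5), strrep("PPG", 5)))
  expect_equal(length(mr$charged), 15) # 5 Arg x 3 chains
  expect_true(all(c("NE", "CZ", "NH1", "NH2") %in%
                  mr$atoms$atom[mr$atoms$resid == "R"]))

  expect_error(build_triple_helix("PPA"), "Gly required")
  expect_error(build_triple_helix("PKG"), "unsupported")
})

test_that("the pair energy matches the 12-6 closed form and vanishes beyond cutoff", {
  sig <- 3.0; eps <- 0.2
  m1 <- point_model(0, 0, 0, sigma = sig, epsilon = eps)
  mk_at_distance <- function(d, r = 20) point_model(d - r, 0, 0, sigma = sig, epsilon = eps)
  pose <- function(r) rigid_pose(r = r)

  # pair exactly at sigma: LJ term 0
  e <- interaction_energy(m1, mk_at_distance(sig), pose(20))
  expect_equal(e$lj_kcal_mol, 0, tolerance = 1e-10)
  # at 2^(1/6) sigma: -epsilon
  e <- interaction_energy(m1, mk_at_distance(2^(1 / 6) * sig), pose(20))
  expect_equal(e$lj_kcal_mol, -eps, tolerance = 1e-10)
  expect_equal(e$total_kcal_mol, e$lj_kcal_mol + e$coulomb_kcal_mol)

  # Coulomb with eps(d) = 4d: k q1 q2 / (4 d^2)
  mq1 <- point_model(0, 0, 0, charge = 1)
  mq2 <- point_model(-15, 0, 0, charge = -1)
  e <- interaction_energy(mq1, mq2, pose(20)) # distance 5
  expect_equal(e$coulomb_kcal_mol, -332.0637 / (4 * 25), tolerance = 1e-6)
  # beyond the 12 A Coulomb cutoff
  e <- interaction_energy(mq1, mq2, pose(28)) # distance 13
  expect_equal(e$total_kcal_mol, 0)

  # widely separated helices: everything beyond cutoff
  mm <- build_triple_helix(strrep("PPG", 4))
  e <- interaction_energy(mm, mm, rigid_pose(r = 1000))
  expect_equal(e$total_kcal_mol, 0)
  # superposed models: core clash, hugely positive
  e <- interaction_energy(mm, mm, rigid_pose(r = 1e-9))
  expect_gt(e$total_kcal_mol, 1e3)
})

test_that("annealing is deterministic, monotone in best energy, and Metropolis-correct", {
  m <- build_triple_helix(strrep("PPG", 3))
  a <- anneal_config(steps = 400, seed = 5)
  f1 <- optimize_pose(m, m, anneal = a)
  f2 <- optimize_pose(m, m, anneal = a)
  expect_identical(f1$pose, f2$pose)
  expect_identical(f1$energy, f2$energy)
  expect_true(all(diff(f1$trajectory) <= 0))
  f3 <- optimize_pose(m, m, anneal = anneal_config(steps = 400, seed = 6))
  expect_false(identical(f1$pose, f3$pose))

  # near-fixed high temperature: uphill acceptance frequency tracks exp(-dE/T)
  ah <- anneal_config(steps = 3000, t_start = 8, t_end = 7.999, seed = 2)
  fh <- optimize_pose(m, m, anneal = ah, diagnostics = TRUE)
  up <- fh$uphill
  expect_gt(nrow(up), 100)
  p_exp <- mean(pmin(1, exp(-up$de / up$temp)))
  p_obs <- mean(up$accepted)
  se <- sqrt(p_exp * (1 - p_exp) / nrow(up))
  expect_lt(abs(p_obs - p_exp), 4 * se + 0.02)
})

test_that("salt-bridge detection finds constructed pairs and nothing else", {
  # one Arg NH1 and one Glu OE1 placed 3.3 A apart under the pose
  m_arg <- point_model(0, 0, 0, charge = 0.15, resid = "R", atom = "NH1")
  m_glu <- point_model(-1.7, 0, 0, charge = -0.7, resid = "E", atom = "OE1")
  pose <- rigid_pose(r = 5) # transformed Glu lands at x = 3.3
  sb <- find_salt_bridges(m_arg, m_glu, pose)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.3, tolerance = 1e-10)
  expect_equal(sb$arg_atom, "NH1")
  expect_equal(sb$glu_atom, "OE1")

  # cutoff excludes it
  expect_equal(nrow(find_salt_bridges(m_arg, m_glu, pose, cutoff = 3)), 0)
  expect_equal(nrow(find_salt_bridges(m_arg, m_glu, pose, cutoff = 0)), 0)

  # all-Pro models carry no charged atoms
  mp <- build_triple_helix(strrep("PPG", 3))
  expect_equal(nrow(find_salt_bridges(mp, mp, rigid_pose(r = 10))), 0)
})

test_that("posed helices export as standard PDB records", {
  m <- build_triple_helix(strrep("PPG", 2))
  f <- tempfile(fileext = ".pdb")
  write_helix_pdb(m, f, m2 = m, pose = rigid_pose(r = 12))
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), 2 * nrow(m$atoms))
  expect_setequal(unique(pdb$atom$chain), LETTERS[1:6])
  expect_setequal(unique(pdb$atom$resid), c("PRO", "GLY"))
})

test_that("the threshold report places mean energies relative to the band", {
  series <- data.frame(n = rep(c(5, 12), each = 2), seed = c(1, 2, 1, 2),
                       type = "P", total_kcal_mol = c(-10, -12, -60, -64))
  rep <- energy_threshold_report(series)
  expect_equal(rep$band_position[rep$n == 5], "above")
  expect_equal(rep$band_position[rep$n == 12], "below")
  series$total_kcal_mol <- c(-35, -40, -35, -40)
  expect_true(all(energy_threshold_report(series)$band_position == "within"))
})
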