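test_that("designs map to coarse-grained rods with the triplet-to-sphere rule", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  expect_equal(rod$n_adhesive, c(10L, 10L))
  expect_equal(rod$n_driver, 25L) # 27 triplets x 25/27
  expect_equal(rod$n_spheres, 45L)
  expect_equal(rod$period, 35L)

  rod2 <- rod_from_design(parse_design("P10-B-B-P10"))
  expect_equal(rod2$n_driver, 50L) # 54 x 25/27
  expect_equal(rod2$n_spheres, 70L)

  # degenerate two-sphere rod (direct construction)
  tiny <- rod_from_design(n_adhesive = c(1L, 1L), n_driver = 0L,
                          sticky = c("P", "P"))
  expect_equal(tiny$n_spheres, 2L)
  expect_equal(tiny$labels, c("adhesiveN", "adhesiveC"))

  expect_error(rod_from_design(parse_design("P5-B-P5")), "not banding-competent")
  expect_warning(rod_from_design(parse_design("P5-B-P5"), force = TRUE),
                 "not banding-competent")
})

test_that("step probabilities realise the 4L/(pi D) cylinder anisotropy", {
  one <- rod_from_design(n_adhesive = c(1L, 0L), n_driver = 0L,
                         sticky = c("P", "P"))
  sp <- step_probabilities(one)
  expect_equal(sp$ratio, 4 / pi)
  expect_equal(sp$p_axial + sp$p_lateral, 1)

  rod <- rod_from_design(parse_design("P10-B-P10"))
  sp <- step_probabilities(rod)
  expect_equal(sp$ratio, 4 * 45 / pi)
  expect_equal(sp$p_axial / sp$p_lateral, sp$ratio)
})

test_that("a single-rod run is just the seed and two-rod runs stick in register", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  agg1 <- run_dla(rod, sim_config(n_rods = 1, seed = 1))
  expect_equal(nrow(agg1$bases), 1)
  expect_equal(nrow(agg1$sites), 45)
  d <- fiber_dimensions(agg1)
  expect_equal(d$length_nm, 45)
  expect_equal(d$thickness_nm, 1)
  expect_equal(d$aspect_ratio, 45)
  # flat unit density profile
  expect_true(all(axial_density(agg1)$n == 1))

  for (sd in 1:5) {
    agg2 <- run_dla(rod, sim_config(n_rods = 2, seed = sd))
    b <- agg2$bases
    # lateral hexagonal adjacency of the columns
    dq <- b[2, 1] - b[1, 1]; dr <- b[2, 2] - b[1, 2]
    expect_true(paste(dq, dr) %in%
                c("1 0", "-1 0", "0 1", "0 -1", "1 -1", "-1 1"))
    # full module register: base offset is a multiple of the period
    expect_equal(((b[2, 3] - b[1, 3]) %% 35 + 35) %% 35, 0)
    expect_equal(nrow(agg2$contacts), 1)
  }
})

test_that("aggregates are deterministic by seed and satisfy conservation invariants", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  a1 <- run_dla(rod, sim_config(n_rods = 40, seed = 9))
  a2 <- run_dla(rod, sim_config(n_rods = 40, seed = 9))
  expect_identical(a1$bases, a2$bases)
  a3 <- run_dla(rod, sim_config(n_rods = 40, seed = 10))
  expect_false(identical(a1$bases, a3$bases))

  expect_invisible(check_aggregate(a1))
  expect_equal(nrow(a1$sites), 40 * 45) # mass conservation
  key <- with(a1$sites, paste(q, r, z))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(2:40 %in% a1$contacts$rod_i)) # every non-seed rod stuck
})

test_that("R/E rods only bind heterotypically, producing staggered stacking", {
  rod <- rod_from_design(parse_design("R5-B-E5"))
  expect_equal(unique(rod$type[rod$labels == "adhesiveN"]), "R")
  expect_equal(unique(rod$type[rod$labels == "adhesiveC"]), "E")
  agg <- run_dla(rod, sim_config(n_rods = 10, seed = 3))
  check_aggregate(agg)
  b <- agg$bases
  # R-R and E-E contacts are disallowed, so laterally adjacent rods must be
  # offset by a non-zero multiple of the period (R against E)
  for (e in seq_len(nrow(agg$contacts))) {
    i <- agg$contacts$rod_i[e]; j <- agg$contacts$rod_j[e]
    dz <- b[i, 3] - b[j, 3]
    expect_equal((dz %% rod$period + rod$period) %% rod$period, 0)
    expect_true(dz != 0)
  }
})

test_that("constructed two-column stacks give the expected density and thickness", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  # hand-built aggregate: two rods in perfect register, adjacent columns
  agg <- run_dla(rod, sim_config(n_rods = 1, seed = 1))
  s2 <- agg$sites
  s2$rod <- 2L; s2$q <- s2$q + 1L
  s2$x <- s2$q + 0.5 * s2$r
  agg$sites <- rbind(agg$sites, s2)
  agg$bases <- rbind(agg$bases, agg$bases)
  dens <- axial_density(agg)
  expect_true(all(dens$n == 2)) # full register doubles every bin
  d <- fiber_dimensions(agg)
  expect_equal(d$thickness_nm, 2) # bounding circle spans both columns
  expect_equal(d$length_nm, 45)
})

test_that("a one-replicate ensemble reduces to a single run", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  ens <- ensemble_run(rod, rod_counts = 20, reps = 1, seed = 4)
  cfg <- sim_config(n_rods = 20, seed = derive_seed(4, 20, 1))
  d <- fiber_dimensions(run_dla(rod, cfg))
  expect_equal(ens$runs$length_nm, d$length_nm)
  expect_equal(ens$runs$thickness_nm, d$thickness_nm)
  expect_equal(ens$summary$mean_length_nm, d$length_nm)
  expect_equal(ens$summary$wmean_length_nm, d$length_nm)
})

test_that("projections are banded, invertible images consistent with axial density", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  agg1 <- run_dla(rod, sim_config(n_rods = 1, seed = 1))
  img <- render_projection(agg1)
  expect_equal(dim(img)[2], 45) # one column per z site
  expect_true(all(unclass(img) %in% c(0, 1)))
  expect_equal(unclass(invert_image(invert_image(img))), unclass(img))

  agg <- run_dla(rod, sim_config(n_rods = 150, seed = 2))
  img <- render_projection(agg)
  tr <- detrend_band_trace(projection_trace(img))
  est <- fft_periodicity(tr, detrend = "none")
  expect_equal(est$period_nm, 35, tolerance = 0.06)
})

test_that("aggregate exports are readable round trips", {
  rod <- rod_from_design(parse_design("P10-B-P10"))
  agg <- run_dla(rod, sim_config(n_rods = 5, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_aggregate(agg, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 5 * 45)
  expect_true(all(c("rod", "x", "y", "z", "label") %in% names(back)))
  fx <- tempfile(fileext = ".xyz")
  write_aggregate(agg, fx, format = "xyz")
  expect_equal(as.integer(readLines(fx, n = 1)), 5 * 45)
})
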