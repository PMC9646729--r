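test_that("pair scores follow the contact rules", {
  expect_equal(pair_score("K", "E"), 1L)
  expect_equal(pair_score("R", "R"), -1L)
  expect_equal(pair_score("D", "E"), -1L)
  expect_equal(pair_score("A", "S"), 0L)
  expect_equal(pair_score("P", "L"), 1L)
  expect_equal(pair_score("K", "L"), 0L) # charged vs hydrophobic
  expect_error(pair_score("B", "A"), "non-standard")
})

test_that("the scan matches literal brute-force enumeration on random pairs", {
  params <- score_params()
  set.seed(42)
  for (case in 1:40) {
    s1 <- rand_collagen_seq(sample(3:40, 1))
    s2 <- rand_collagen_seq(sample(3:40, 1))
    got <- stagger_scan(s1, s2, params)
    want <- oracle_stagger_scan(s1, s2, params)
    expect_identical(got$shift, want$shift)
    expect_identical(got$score, want$score)
  }
  # smallest mixed-charge example
  got <- stagger_scan("KGE", "EGK")
  want <- oracle_stagger_scan("KGE", "EGK")
  expect_identical(got$score, want$score)
})

test_that("scan symmetry, bound, and windowed-count properties hold", {
  params <- score_params()
  set.seed(7)
  for (case in 1:20) {
    s1 <- rand_collagen_seq(sample(5:30, 1))
    s2 <- rand_collagen_seq(sample(5:30, 1))
    p12 <- stagger_scan(s1, s2, params)
    p21 <- stagger_scan(s2, s1, params)
    # score(s1, s2, s) == score(s2, s1, -s)
    expect_identical(p12$score, rev(p21$score))
    # bound: |score| <= overlap x total window sizes
    n1 <- nchar(s1); n2 <- nchar(s2)
    ov <- pmin(n1, n2, n1 - p12$shift, n2 + p12$shift)
    bound <- ov * (2 * params$charge_window + 1 + 2 * params$hydrophobic_window + 1)
    expect_true(all(abs(p12$score) <= pmax(bound, 0)))
  }
})

test_that("self-scan of adhesive-flanked designs peaks at the full-overlap register", {
  set.seed(11)
  # charge-free drivers of random composition
  for (case in 1:5) {
    n_trip <- sample(5:15, 1)
    xs <- sample(c("A", "S", "T", "Q", "N"), n_trip, replace = TRUE)
    ys <- sample(c("A", "S", "T", "Q", "N"), n_trip, replace = TRUE)
    frag <- module_spec("fragment", triplets = paste0(xs, ys, "G"), name = "X")
    d <- parse_design("P10-X-P10", fragments = list(X = frag))
    prof <- stagger_scan(d$sequence, d$sequence)
    best <- top_poses(prof, 1)
    # global maximum within the triplet-lattice width of full overlap
    expect_lte(abs(best$shift), 2)
  }
})

test_that("the periodic gap scan reduces to a self-scan and finds lattice repeats", {
  s <- "PKGEPGPPGAPG"
  p0 <- scan_with_gap(s, score_params(gap_length = 0))
  p1 <- stagger_scan(s, s)
  expect_identical(p0$score, p1$score)

  # periodic sequence: unit of 26 triplets with charged + hydrophobic motif
  unit <- paste0("KEGLPG", strrep("ASGTQG", 12))
  seqp <- strrep(unit, 3) # 234 residues, internal period 78
  prm <- score_params(gap_length = 30)
  prof <- scan_with_gap(seqp, prm)
  expect_true(isTRUE(attr(prof, "periodic")))
  expect_equal(attr(prof, "repeat_length"), nchar(seqp) + 30)
  expect_equal(nrow(prof), nchar(seqp) + 30)
  # peaks at the internal sequence period (78) and at zero
  sc <- function(sh) prof$score[prof$shift == sh]
  expect_gte(sc(0), max(prof$score) - 1L)
  expect_gt(sc(78), sc(70))
  expect_gt(sc(78), sc(86))

  expect_error(scan_with_gap("PPG", score_params(gap_length = 156)), "smaller")
})

test_that("top poses rank by score with deterministic tie-breaks", {
  prof <- bandfib:::new_score_profile(shift = c(-5, -2, 0, 2, 5),
                                      score = c(9L, 7L, 3L, 7L, 9L))
  top <- top_poses(prof, 5)
  # ties: smaller |shift| first, then positive before negative
  expect_equal(top$shift, c(5, -5, 2, -2, 0))
  expect_equal(top$score, c(9L, 9L, 7L, 7L, 3L))
  expect_equal(top_poses(prof, 1)$shift, 5)
  expect_error(top_poses(prof, 6), "exceeds")
})
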