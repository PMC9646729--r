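test_that("grammar parsing builds annotated chains with correct module arithmetic", {
  d <- parse_design("P10-B-P10")
  expect_s3_class(d, "collagen_design")
  expect_equal(nchar(d$sequence), 30 + 81 + 30)
  expect_equal(length(d$annotation), 141)
  expect_equal(d$modules[[1]]$triplets, rep("PPG", 10))

  e <- parse_design("R5-B-E5")
  expect_equal(e$modules[[1]]$triplets, rep("PRG", 5))
  expect_equal(e$modules[[3]]$triplets, rep("EPG", 5))
  expect_equal(nchar(module_sequence(e$modules[[1]])), 15)
  expect_equal(nchar(module_sequence(e$modules[[3]])), 15)

  # padding PPG triplets sit distal to the driver
  r3 <- parse_design("R3-B-E3")
  expect_equal(r3$modules[[1]]$triplets, c("PPG", "PPG", "PRG", "PRG", "PRG"))
  expect_equal(r3$modules[[3]]$triplets, c("EPG", "EPG", "EPG", "PPG", "PPG"))
  expect_equal(nchar(module_sequence(r3$modules[[1]])), 15)

  expect_error(parse_design("P10-ZZZ-P10"), "unknown fragment")
  expect_error(parse_design("P10--P10"), "malformed")
  expect_error(parse_design("P10-B-P1!0"), "malformed")
  expect_error(parse_design("R6-B-E6"), "at most 5")
})

test_that("every generated design obeys the Gly-every-third rule", {
  grammars <- c("P10-B-P10", "R5-B-E5", "R1-B-E1", "P5-B-B-P5",
                "P10-A-B-C-P10", "Bh-P10-Bh", "B-P10")
  for (sd in 1:10) {
    lib <- fragment_library(seed = sd)
    for (g in grammars) {
      d <- parse_design(g, fragments = lib)
      chars <- strsplit(d$sequence, "")[[1]]
      expect_true(all(chars[seq(3, length(chars), by = 3)] == "G"),
                  info = paste(g, "seed", sd))
    }
  }
})

test_that("fragment classes satisfy their compositional contracts over many seeds", {
  charged <- c("K", "R", "D", "E")
  count_charged <- function(f) sum(strsplit(module_sequence(f), "")[[1]] %in% charged)
  for (sd in 1:100) {
    a <- make_fragment("A", 27, seed = sd)
    expect_equal(count_charged(a), 0)
    expect_equal(nchar(module_sequence(a)), 81)

    b <- make_fragment("B", 27, seed = sd)
    s <- module_sequence(b)
    expect_equal(length(gregexpr("GFPGER", s)[[1]][gregexpr("GFPGER", s)[[1]] > 0]), 1)
    expect_lte(count_charged(b) - 2L, 2L) # motif E+R plus at most 2 others

    cf <- make_fragment("C", 27, seed = sd)
    chars <- strsplit(module_sequence(cf), "")[[1]]
    xy <- chars[-seq(3, length(chars), by = 3)]
    expect_gte(mean(xy %in% charged), 0.30)
    net <- sum(xy %in% c("K", "R")) - sum(xy %in% c("D", "E"))
    expect_lte(abs(net), 2)
  }
  # determinism contract
  expect_identical(make_fragment("C", 27, seed = 1), make_fragment("C", 27, seed = 1))
  expect_false(identical(module_sequence(make_fragment("C", 27, seed = 1)),
                         module_sequence(make_fragment("C", 27, seed = 2))))
  expect_error(make_fragment("B", 2), ">= 3 triplets")
})

test_that("competence verdicts carry the matching reason codes", {
  expect_equal(classify_banding(parse_design("P5-B-P5"))$reason,
               "hydrophobic-below-threshold")
  expect_equal(classify_banding(parse_design("R3-B-E3"))$reason,
               "electrostatic-below-threshold")
  expect_equal(classify_banding(parse_design("P10-B"))$reason,
               "topology-missing-flank")
  v <- classify_banding(parse_design("R5-B-E5"))
  expect_true(v$competent)
  expect_equal(v$reason, "ok")
  # reason == ok iff competent
  for (g in c(competent_designs, incompetent_designs)) {
    v <- classify_banding(parse_design(g))
    expect_equal(v$reason == "ok", v$competent, info = g)
  }
})

test_that("FASTA round trip preserves sequences and rejects bad letters", {
  designs <- lapply(c("P10-B-P10", "R5-B-E5"), parse_design)
  f <- tempfile(fileext = ".fasta")
  write_fasta(designs, f)
  back <- read_fasta(f)
  expect_equal(unname(back["P10BP10"]), designs[[1]]$sequence)
  expect_equal(unname(back["R5BE5"]), designs[[2]]$sequence)
  expect_equal(attr(back, "modules"), c("P10-B-P10", "R5-B-E5"))

  # empty input -> empty output
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(list(), f2)
  expect_length(read_fasta(f2), 0)

  # non-amino-acid character -> error
  f3 <- tempfile(fileext = ".fasta")
  writeLines(c(">bad", "PPGOPG"), f3)
  expect_error(read_fasta(f3), "non-standard")
})
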