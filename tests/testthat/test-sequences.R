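test_that("repeat notation expands correctly", {
  s <- parse_sequence("(HP)30")
  expect_length(s, 60)
  expect_equal(labels_of(s)[1:4], c("H", "P", "H", "P"))

  expect_length(parse_sequence("H"), 1)

  s2 <- parse_sequence("(HPP)33H")
  expect_length(s2, 100)
  expect_true(all(s2[seq(1, 100, by = 3)] == "H"))
  expect_true(all(s2[setdiff(1:100, seq(1, 100, by = 3))] == "P"))

  s3 <- parse_sequence("PP(HHHHPPPP)7HH")
  expect_length(s3, 60)
  expect_equal(sum(s3 == "H"), 30)

  # counts on single letters, whitespace tolerated
  expect_equal(labels_of(parse_sequence("H3 P2")), c("H", "H", "H", "P", "P"))
})

test_that("malformed repeat notation is rejected with informative errors", {
  expect_error(parse_sequence("(HP"), "unbalanced")
  expect_error(parse_sequence("HP)"), "unbalanced")
  expect_error(parse_sequence("(HP)0"), "count")
  expect_error(parse_sequence("(HX)3"), "X")
  expect_error(parse_sequence("Q"), "unknown token")
  expect_error(parse_sequence("((HP)2)3"), "nested")
})

test_that("SCD reproduces the reference patch-family scores", {
  expected <- c("(HP)30" = -0.410, "(PHHP)15" = -0.537, "(PHHHPP)10" = -0.778,
                "PP(HHHHPPPP)7HH" = -1.002, "(PPHHHHHPPP)6" = -1.319)
  got <- vapply(names(expected), function(s) compute_scd(s), 0)
  expect_equal(round(got, 3), expected, ignore_attr = TRUE, tolerance = 1e-9)
  # |SCD| strictly increases with patch size at fixed composition
  expect_true(all(diff(abs(got)) > 0))
})

test_that("SCD of the blocky 50-mer polyampholyte has magnitude 2.070", {
  s <- generate_polyampholyte(25, 25, "blocks", block_size = 5)
  expect_equal(round(abs(compute_scd(s)), 3), 2.070, tolerance = 1e-9)
})

test_that("SCD direct evaluation and edge cases", {
  expect_equal(compute_scd(cg_sequence(c("+", "-"))), -0.5)
  expect_error(compute_scd(cg_sequence("H")), "length")
  expect_error(compute_scd("(HP)3", charge_map = c("H" = -1)), "cover")
})

test_that("SCD matches a naive double loop and is reversal/sign invariant", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(10:200, 1)
    labs <- sample(c("P", "H"), n, replace = TRUE)
    s <- cg_sequence(labs)
    q <- ifelse(labs == "P", 1, -1)
    expect_equal(compute_scd(s), scd_naive(q), tolerance = 1e-12)
    expect_equal(compute_scd(cg_sequence(rev(labs))), compute_scd(s),
                 tolerance = 1e-12)
    flipped <- cg_sequence(ifelse(labs == "P", "H", "P"))
    expect_equal(compute_scd(flipped), compute_scd(s), tolerance = 1e-12)
  }
})

test_that("kappa normalisation, limits and brute-force agreement", {
  diblock <- generate_polyampholyte(25, 25, "blocks", block_size = 25)
  expect_equal(compute_kappa(diblock), 1)

  alt <- generate_polyampholyte(25, 25, "alternating")
  expect_lt(compute_kappa(alt), 0.01)

  blocks5 <- generate_polyampholyte(25, 25, "blocks", block_size = 5)
  q5 <- ifelse(unclass(blocks5) == "+", 1, -1)
  expect_equal(compute_kappa(blocks5), kappa_naive(q5), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:5) {
    s <- generate_polyampholyte(15, 10, "shuffled", seed = rep)
    k <- compute_kappa(s)
    expect_gte(k, 0)
    expect_lte(k, 1)
    q <- ifelse(unclass(s) == "+", 1, -1)
    expect_equal(k, kappa_naive(q), tolerance = 1e-12)
  }
  expect_error(compute_kappa("(HP)5", charge_map = c("H" = 0, "P" = 0)),
               "uncharged")
})

test_that("patch sequence generator reproduces the study family", {
  expect_equal(labels_of(generate_patch_sequence(30, 30, 1)),
               labels_of(parse_sequence("(HP)30")))
  expect_equal(labels_of(generate_patch_sequence(2, 0, 2)), c("H", "H"))
  # patch 5 matches (PPHHHHHPPP)6 up to a cyclic shift
  g5 <- paste(labels_of(generate_patch_sequence(30, 30, 5)), collapse = "")
  ref <- paste(labels_of(parse_sequence("(PPHHHHHPPP)6")), collapse = "")
  expect_true(grepl(g5, paste0(ref, ref), fixed = TRUE))
  expect_error(generate_patch_sequence(4, 4, 6), "patch_size")
  # remainder rule keeps composition exact
  comp <- composition(generate_patch_sequence(30, 30, 4))
  expect_equal(comp$f_H, 0.5)
  expect_equal(comp$n, 60)
})

test_that("polyampholyte generator modes and determinism", {
  expect_equal(labels_of(generate_polyampholyte(1, 1, "alternating")), c("+", "-"))
  b <- generate_polyampholyte(25, 25, "blocks", block_size = 5)
  expect_equal(labels_of(b)[1:10], c(rep("-", 5), rep("+", 5)))
  expect_length(b, 50)
  s1 <- generate_polyampholyte(25, 25, "shuffled", seed = 42)
  s2 <- generate_polyampholyte(25, 25, "shuffled", seed = 42)
  expect_identical(unclass(s1), unclass(s2))
  expect_error(generate_polyampholyte(25, 25, "blocks", block_size = 7),
               "divide")
})

test_that("composition fractions sum to one", {
  comp <- composition(generate_polyampholyte(10, 15, "alternating"))
  expect_equal(comp$f_H + comp$f_plus + comp$f_minus + comp$f_P, 1)
  expect_equal(comp$f_plus, 0.4)
})

test_that("FASTA reduction maps residues onto the four-letter alphabet", {
  skip_if_not_installed("Biostrings")
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">toy1", "KRDEFLP", ">toy2", "GGSSA"), path)
  seqs <- read_fasta_sequences(path)
  expect_equal(labels_of(seqs[[1]]), c("+", "+", "-", "-", "H", "H", "P"))
  expect_true(all(seqs[[2]] == "P"))
  expect_equal(attr(seqs[[1]], "name"), "toy1")
})

test_that("sequence_metrics returns one tidy row per sequence", {
  tbl <- tibble::tibble(spec = c("(HP)30", "PP(HHHHPPPP)7HH"))
  m <- sequence_metrics(tbl)
  expect_equal(nrow(m), 2)
  expect_equal(m$n, c(60, 60))
  expect_equal(round(m$scd, 3), c(-0.410, -1.002))
  expect_true(all(is.na(m$kappa))) # uncharged sequences
  m2 <- sequence_metrics(tibble::tibble(
    sequence = list(generate_polyampholyte(25, 25, "blocks", block_size = 5))))
  expect_false(is.na(m2$kappa))
})
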