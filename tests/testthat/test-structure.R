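test_that("fallback folding matches exhaustive enumeration on tiny sequences", {
  # pairless sequence
  st <- fold("AAAAA", engine = "fallback")
  expect_equal(st$db, ".....")
  expect_equal(st$mfe, 0)

  # stem: maximum is 3 pairs and the stated traceback yields this structure
  st <- fold("GGGAAAACCC", engine = "fallback")
  expect_equal(st$db, "(((....)))")
  expect_equal(st$mfe, -3)

  set.seed(5)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "U", "N"), sample(5:14, 1),
                      replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    st <- fold(s, engine = "fallback")
    expect_equal(nchar(st$db), nchar(s))
    npairs <- sum(strsplit(st$db, "")[[1]] == "(")
    expect_equal(npairs, oracle_max_pairs(s), info = s)
    expect_equal(st$mfe, -npairs)   # pseudo-energy = -(pairs)
    # N never pairs
    pt <- pair_table(st$db)
    ch <- strsplit(s, "")[[1]]
    expect_true(all(pt[ch == "N"] == 0L))
  }
})

test_that("folding is deterministic and validates its input", {
  a <- fold("GCGCAAAAGCGC", engine = "fallback")
  b <- fold("GCGCAAAAGCGC", engine = "fallback")
  expect_identical(a, b)
  expect_error(fold("ACGT"), "normalized RNA")
  expect_error(fold(strrep("A", 7501)), "7500")
  expect_error(fold("ACGU", engine = "vienna", rnafold = ""), "fallback")
})

test_that("external engine adapter parses dot-bracket and energy", {
  # RNAfold ships with the environment this package targets
  st <- fold("GGGGAAAACCCC", engine = "vienna")
  expect_equal(st$engine, "external-mfe")
  expect_equal(nchar(st$db), 12L)
  expect_lt(st$mfe, 0)
  expect_true(grepl("^[().]+$", st$db))
})

test_that("pair_table maps brackets and rejects unbalanced strings", {
  expect_equal(pair_table("(...)"), c(5L, 0L, 0L, 0L, 1L))
  expect_equal(pair_table("((.))"), c(5L, 4L, 0L, 2L, 1L))
  p <- pair_table("((..((...))..((...))..))")
  paired <- which(p > 0)
  expect_true(all(p[p[paired]] == paired))   # symmetry
  expect_error(pair_table(")("), "unbalanced")
  expect_error(pair_table("(()"), "unbalanced")
  expect_error(pair_table("(x)"), "only")
})

test_that("loop decomposition matches the worked structures", {
  expect_equal(unclass(decompose_loops("........")),
               c(hairpin = 0L, external = 0L, internal = 0L, multi = 0L,
                 total = 0L))
  expect_equal(unclass(decompose_loops("((((...))))")),
               c(hairpin = 1L, external = 1L, internal = 0L, multi = 0L,
                 total = 2L))
  expect_equal(unclass(decompose_loops("((..((...))..((...))..))")),
               c(hairpin = 2L, external = 1L, internal = 0L, multi = 1L,
                 total = 4L))
  expect_equal(unclass(decompose_loops("((.(...)))")),
               c(hairpin = 1L, external = 1L, internal = 1L, multi = 0L,
                 total = 3L))
})

test_that("loop decomposition invariants hold on random structures", {
  set.seed(9)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(20:60, 1), replace = TRUE),
               collapse = "")
    db <- fold(s, engine = "fallback")$db
    lc <- decompose_loops(db)
    expect_equal(lc[["total"]],
                 lc[["hairpin"]] + lc[["external"]] + lc[["internal"]] +
                   lc[["multi"]])
    expect_true(lc[["external"]] %in% c(0L, 1L))
    if (any(pair_table(db) > 0)) expect_gte(lc[["hairpin"]], 1L)
  }
})

test_that("upstream AUGs are counted in every frame, N never matches", {
  expect_equal(count_uaugs("AUGAUG"), 2L)
  expect_equal(count_uaugs("ACGUACGU"), 0L)
  expect_equal(count_uaugs("AAUGGAUGC"), 2L)
  expect_equal(count_uaugs("AUGUG"), 1L)      # overlap handled
  expect_equal(count_uaugs("AUNG"), 0L)
  expect_equal(count_uaugs("AU"), 0L)
})
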