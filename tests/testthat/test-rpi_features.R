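test_that("conjoint-triad encoding has 343 bins, normalizes, drops X windows", {
  v <- encode_protein("AAA")
  expect_length(v, 343L)
  expect_equal(unname(v["t111"]), 1)     # A, G, V are class 1
  expect_equal(sum(v), 1)
  expect_error(encode_protein("AA"), "too short")

  # R and K are class 5; D/E class 6; C class 7
  v <- encode_protein("RKC")
  expect_equal(unname(v["t557"]), 1)

  set.seed(3)
  for (i in 1:10) {
    p <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"), 30,
                      replace = TRUE), collapse = "")
    v <- encode_protein(p)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(abs(sum(v) - 1) < 1e-12 || sum(v) == 0)
  }
  # X-containing windows are dropped, not errors
  v <- encode_protein("AXAAA")   # countable windows: AAA only
  expect_equal(unname(v["t111"]), 1)
})

test_that("RNA k-mer encoding has 256 bins, normalizes, drops N windows", {
  v <- encode_rna("AAAA")
  expect_length(v, 256L)
  expect_equal(unname(v["AAAA"]), 1)
  v <- encode_rna("AAAAA")                 # two identical windows
  expect_equal(unname(v["AAAA"]), 1)
  v <- encode_rna("ACGUN")                 # window 2 contains N, dropped
  expect_equal(unname(v["ACGU"]), 1)
  expect_equal(sum(v), 1)
  expect_error(encode_rna("ACG"), "too short")
  # sense strand only: a sequence and its reverse encode differently
  expect_false(identical(encode_rna("AACGUUGG"),
                         encode_rna(paste(rev(strsplit("AACGUUGG", "")[[1]]),
                                          collapse = ""))))
})

test_that("interaction model learns the planted motif task and is seeded", {
  pairs <- fx("pairs")
  set.seed(7)
  idx <- sample(nrow(pairs))           # generator emits positives first
  tr <- pairs[idx[1:160], ]
  te <- pairs[idx[161:220], ]
  m1 <- train_interaction_model(tr, ntree = 80, seed = 7)
  p1 <- interaction_probability(m1, te$rna, te$protein)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gte(mean((p1 > 0.5) == (te$label == 1)), 0.8)

  # determinism: retrain with the same seed, identical probabilities
  m2 <- train_interaction_model(tr, ntree = 80, seed = 7)
  p2 <- interaction_probability(m2, te$rna, te$protein)
  expect_identical(p1, p2)

  # training-positive pairs score above 0.5
  pos <- tr[tr$label == 1, ][1:5, ]
  expect_true(all(interaction_probability(m1, pos$rna, pos$protein) > 0.5))

  one <- tr[tr$label == 1, ]
  expect_error(train_interaction_model(one, seed = 1), "both")
  expect_error(train_interaction_model(tr[0, ], seed = 1), "empty")
})

test_that("ssrp_profile returns 27 ordered probabilities and enforces panel size", {
  panel <- fx("panel")
  rpi <- fx("rpi")
  prof <- ssrp_profile("ACGUACGUACGUACGU", panel, rpi)
  expect_length(prof, 27L)
  expect_named(prof, panel$id)
  expect_true(all(prof >= 0 & prof <= 1))

  expect_error(ssrp_profile("ACGU", panel[1:26, ], rpi), "27")
  small <- ssrp_profile("ACGUACGU", panel[1:5, ], rpi, override = TRUE)
  expect_length(small, 5L)

  # permutation stability: shuffling the panel permutes the profile
  perm <- sample(27)
  prof2 <- ssrp_profile("ACGUACGUACGUACGU", panel[perm, ], rpi)
  expect_equal(unname(prof2), unname(prof[perm]))
})

test_that("precomputed tables override the model and missing cells error", {
  panel <- fx("panel")
  tab <- data.frame(rna_id = "q1", protein_id = panel$id,
                    probability = seq(0, 1, length.out = 27),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  it <- read_interaction_table(f)
  prof <- ssrp_profile("ACGU", panel, it, rna_id = "q1")
  expect_equal(unname(prof), tab$probability)
  expect_error(ssrp_profile("ACGU", panel, it, rna_id = "q2"), "missing cell")

  tab$probability[1] <- 2
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_interaction_table(f), "\\[0, 1\\]")
})
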