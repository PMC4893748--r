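sep_ft <- generate_feature_table(100, shift = c(rep(2, 5), rep(0, 30)),
                                 seed = 42)

test_that("LibSVM-style flag strings parse to configurations", {
  cfg <- parse_config("-s 2 -t 0 -d 1 -g 3.1192 -c 0.0347")
  expect_equal(cfg[c("s", "t", "d", "g", "c")],
               list(s = 2L, t = 0L, d = 1L, g = 3.1192, c = 0.0347))
  cfg2 <- parse_config("-s 1 -t 1 -d 1 -g 1.8022 -c 0.0347")
  expect_equal(cfg2$s, 1L)
  expect_equal(cfg2$g, 1.8022)
  expect_error(parse_config("-q foo"), "unknown flag")
  expect_error(parse_config("-s"), "malformed")
  expect_error(svm_config(c = -1), "c must be")
  expect_error(svm_config(g = 0), "g must be")
  expect_error(svm_config(t = 9), "t must be")
  # round trip through the flag string
  expect_equal(parse_config(format(cfg)), cfg)
})

test_that("training separates shifted Gaussians and validates inputs", {
  m <- train_ires_model(sep_ft$X, sep_ft$y, svm_config(0, 0, 1, 1, 1),
                        seed = 1)
  pred <- predict(m, sep_ft$X)
  expect_gte(mean(pred$label == sep_ft$y), 0.99)   # training accuracy

  expect_error(train_ires_model(sep_ft$X, rep("IP", 200), seed = 1), "both")
  expect_error(train_ires_model(sep_ft$X, sub("IN", "neg", sep_ft$y),
                                seed = 1), "IP or IN")
  Xna <- sep_ft$X; Xna[3, 3] <- NA
  expect_error(train_ires_model(Xna, sep_ft$y, seed = 1), "row IP0003")
})

test_that("one-class configs are rejected on labeled data unless allowed", {
  cfg <- parse_config("-s 2 -t 0 -d 1 -g 3.1192 -c 0.0347")
  expect_error(train_ires_model(sep_ft$X, sep_ft$y, cfg, seed = 1),
               "one-class")
  m <- train_ires_model(sep_ft$X, sep_ft$y, cfg, seed = 1,
                        allow_one_class = TRUE)
  pred <- predict(m, sep_ft$X)
  expect_setequal(unique(pred$label), c("IP", "IN"))
})

test_that("prediction thresholds the decision value at 0 and checks inputs", {
  m <- train_ires_model(sep_ft$X, sep_ft$y, svm_config(0, 0, 1, 1, 1),
                        seed = 1)
  pred <- predict(m, sep_ft$X)
  expect_equal(pred$label, ifelse(pred$decision_value >= 0, "IP", "IN"))
  # row order invariance
  perm <- sample(nrow(sep_ft$X))
  pred2 <- predict(m, sep_ft$X[perm, ])
  expect_equal(pred2$decision_value, pred$decision_value[perm])

  expect_error(predict(m, sep_ft$X[, 1:34]), "34")
  Xeng <- sep_ft$X
  attr(Xeng, "engine") <- "external-mfe"
  meng <- train_ires_model(sep_ft$X, sep_ft$y, seed = 1,
                           engine = "fallback-maxpair")
  expect_error(predict(meng, Xeng), "refusing to mix engines")
})

test_that("cross-validation is stratified, seeded and permutation-invariant", {
  cv <- cross_validate(sep_ft$X, sep_ft$y, svm_config(0, 0, 1, 1, 1),
                       k = 10, seed = 5)
  expect_gte(cv, 90)
  expect_identical(cv, cross_validate(sep_ft$X, sep_ft$y,
                                      svm_config(0, 0, 1, 1, 1),
                                      k = 10, seed = 5))
  # folds fixed by sorted id: row permutation does not change the result
  perm <- sample(nrow(sep_ft$X))
  cvp <- cross_validate(sep_ft$X[perm, ], sep_ft$y[perm],
                        svm_config(0, 0, 1, 1, 1), k = 10, seed = 5)
  expect_equal(cvp, cv)
  expect_error(cross_validate(sep_ft$X, sep_ft$y, k = 1), "k must be")
  # default fold count is 10
  expect_equal(eval(formals(cross_validate)$k), 10L)
})

test_that("shuffled labels give chance-level cross-validation accuracy", {
  set.seed(99)
  ysh <- sample(sep_ft$y)
  cv <- cross_validate(sep_ft$X, ysh, svm_config(0, 0, 1, 1, 1),
                       k = 5, seed = 5)
  expect_gte(cv, 40)
  expect_lte(cv, 60)
})

test_that("grid and swarm searches find a separating configuration, seeded", {
  spec <- search_spec(strategy = "grid", t_values = 0L, d_values = 1L,
                      log2g_range = c(0, 0), log2c_range = c(-3.32, 3.32),
                      grid_points = 3, k = 5, seed = 5)
  out <- optimize_svm(sep_ft$X, sep_ft$y, spec)
  expect_gte(out$cv_accuracy, 95)
  expect_equal(out$evaluations, 9L)   # 3 gamma x 3 cost points

  pspec <- search_spec(strategy = "pso", t_values = c(0L, 2L), d_values = 1L,
                       swarm = 4, iterations = 3, k = 4, seed = 5)
  o1 <- optimize_svm(sep_ft$X, sep_ft$y, pspec)
  o2 <- optimize_svm(sep_ft$X, sep_ft$y, pspec)
  expect_gte(o1$cv_accuracy, 90)
  expect_identical(o1$config, o2$config)        # same spec + seed
  expect_identical(o1$cv_accuracy, o2$cv_accuracy)
  expect_equal(o1$evaluations, 4L * 4L)         # swarm x (iterations + init)

  expect_error(search_spec(swarm = 0), "swarm")
})

test_that("models serialize and round-trip to identical predictions", {
  m <- train_ires_model(sep_ft$X, sep_ft$y, svm_config(0, 2, 1, 0.1, 10),
                        seed = 1, panel_ids = sprintf("SSRP%02d", 1:27),
                        engine = "fallback-maxpair")
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, sep_ft$X), predict(m, sep_ft$X))
  expect_equal(m2$panel_ids, m$panel_ids)

  m$format_version <- 99L
  f2 <- tempfile(fileext = ".rds")
  saveRDS(m, f2)
  expect_error(load_model(f2), "newer")
  saveRDS(list(a = 1), f2)
  expect_error(load_model(f2), "not an IRES model")
})
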