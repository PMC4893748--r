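test_that("confusion counts follow the standard contingency assignment", {
  expect_equal(unclass(confusion(c("IP", "IN"), c("IP", "IN"))),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  expect_equal(unclass(confusion(c("IP", "IP", "IN", "IN"),
                                 c("IP", "IN", "IP", "IN"))),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_error(confusion(c("IP"), c("IP", "IN")), "same length")
  expect_error(confusion(c("IP", "pos"), c("IP", "IN")), "IP or IN")
})

test_that("metrics match the worked example and degenerate-count policy", {
  rep <- metrics(c(TP = 9, TN = 8, FP = 2, FN = 1))
  expect_equal(rep$accuracy, 85)
  expect_equal(rep$sensitivity, 90)
  expect_equal(rep$specificity, 80)
  expect_equal(rep$precision, 81.8182, tolerance = 1e-4)
  expect_equal(rep$mcc, 0.7035, tolerance = 1e-4)

  perfect <- metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  # zero denominators reported as NA with a reason, never coerced to 0
  deg <- metrics(c(TP = 0, TN = 10, FP = 0, FN = 10))
  expect_true(is.na(deg$precision))
  expect_true(is.na(deg$mcc))
  expect_equal(deg$specificity, 100)
  expect_equal(deg$sensitivity, 0)
  expect_true(any(grepl("precision", deg$undefined)))

  expect_error(metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "all counts zero")
})

test_that("splits are stratified, independent and reproducible", {
  rec <- data.frame(id = sprintf("r%03d", 1:40),
                    label = rep(c("IP", "IN"), each = 20),
                    stringsAsFactors = FALSE)
  splits <- make_splits(rec, seed = 3)
  expect_length(splits, 5L)              # default split count
  for (sp in splits) {
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), rec$id)
    lab <- setNames(rec$label, rec$id)
    expect_equal(sum(lab[sp$train] == "IP"), 10L)   # 50% per class
    expect_equal(sum(lab[sp$test] == "IN"), 10L)
  }
  expect_identical(make_splits(rec, seed = 3), splits)
  expect_false(identical(splits[[1]]$train, splits[[2]]$train))

  # odd class counts: train receives the extra record
  odd <- rec[1:39, ]
  sp <- make_splits(odd, n_splits = 1, seed = 1)[[1]]
  lab <- setNames(odd$label, odd$id)
  expect_equal(sum(lab[sp$train] == "IN"), 10L)     # ceiling(19/2)
  expect_equal(sum(lab[sp$test] == "IN"), 9L)

  expect_error(make_splits(rec[1:20, ], seed = 1), "both classes")
})

test_that("the 5-split protocol recovers a separable synthetic contrast", {
  ft <- generate_feature_table(40, shift = c(rep(2.5, 5), rep(0, 30)),
                               seed = 21)
  rec <- data.frame(id = names(ft$y), label = unname(ft$y),
                    stringsAsFactors = FALSE)
  spec <- search_spec(strategy = "grid", t_values = 0L, d_values = 1L,
                      log2g_range = c(0, 0), log2c_range = c(0, 6),
                      grid_points = 2, k = 4, seed = 21)
  res <- run_protocol(rec, spec = spec, n_splits = 5, seed = 21,
                      features = ft$X)
  expect_equal(nrow(res$report), 5L)
  expect_equal(colnames(res$report),
               c("Model", "s", "t", "d", "g", "c", "CV", "Acc", "Sn", "Sp",
                 "Pr", "MCC"))
  expect_true(all(res$report$Acc >= 90))
  # selection rule: best test accuracy, ties by MCC then split index
  best <- res$best_split
  expect_equal(res$report$Acc[best], max(res$report$Acc))

  # scaling leakage guard: model scaling comes from the training rows only
  for (i in seq_along(res$models)) {
    tr_ids <- res$splits[[i]]$train
    expect_equal(res$models[[i]]$scaling$min,
                 apply(ft$X[tr_ids, , drop = FALSE], 2, min))
    expect_equal(res$models[[i]]$scaling$max,
                 apply(ft$X[tr_ids, , drop = FALSE], 2, max))
  }

  # reruns with the same seed are identical
  res2 <- run_protocol(rec, spec = spec, n_splits = 5, seed = 21,
                       features = ft$X)
  expect_identical(res2$report, res$report)
})

test_that("balanced test sets satisfy Acc = (Sn + Sp) / 2 exactly", {
  set.seed(14)
  for (i in 1:50) {
    npos <- sample(1:15, 1)
    tp <- sample(0:npos, 1); fn <- npos - tp
    tn <- sample(0:npos, 1); fp <- npos - tn
    rep <- metrics(c(TP = tp, TN = tn, FP = fp, FN = fn))
    expect_equal(rep$accuracy, (rep$sensitivity + rep$specificity) / 2)
  }
})
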