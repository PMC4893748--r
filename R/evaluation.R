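#' Confusion counts for binary IP/IN predictions
#'
#' @param y_true,y_pred Character vectors of labels in \{IP, IN\}, equal
#'   length. `positive_label` (default IP) defines the positive class.
#' @param positive_label The positive class label.
#' @return Object of class `confusion_counts`: named integer vector
#'   (TP, TN, FP, FN).
#' @export
confusion <- function(y_true, y_pred, positive_label = "IP") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  bad <- setdiff(unique(c(y_true, y_pred)), c("IP", "IN"))
  if (length(bad) > 0L) stop("labels must be IP or IN; found: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  pos_t <- y_true == positive_label
  pos_p <- y_pred == positive_label
  out <- c(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
           FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Performance metrics from confusion counts
#'
#' Computes the five standard binary-classification measures:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP) and the Matthews
#' correlation coefficient
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Percentages are on the 0-100 scale. A measure whose denominator is zero
#' is reported as NA with the reason recorded in the `undefined` attribute
#' — never silently coerced to 0, because a silent zero corrupts model
#' selection.
#'
#' @param cc A `confusion_counts` vector (or named vector with TP, TN, FP,
#'   FN).
#' @return Object of class `eval_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision` (percent), `mcc` and
#'   `counts`.
#' @export
metrics <- function(cc) {
  cc <- cc[c("TP", "TN", "FP", "FN")]
  if (anyNA(cc) || any(cc < 0)) stop("counts must be non-negative TP/TN/FP/FN",
                                     call. = FALSE)
  tp <- as.numeric(cc[["TP"]]); tn <- as.numeric(cc[["TN"]])
  fp <- as.numeric(cc[["FP"]]); fn <- as.numeric(cc[["FN"]])
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated records (all counts zero)", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, sprintf("%s undefined: zero denominator", what))
      NA_real_
    } else num / den
  }
  acc <- 100 * (tp + tn) / total
  sn <- 100 * ratio(tp, tp + fn, "sensitivity")
  sp <- 100 * ratio(tn, tn + fp, "specificity")
  pr <- 100 * ratio(tp, tp + fp, "precision")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    undefined <- c(undefined, "MCC undefined: zero denominator")
    NA_real_
  } else (tp * tn - fp * fn) / mcc_den
  structure(list(accuracy = acc, sensitivity = sn, specificity = sp,
                 precision = pr, mcc = mcc, counts = cc,
                 undefined = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf("Acc %s%%  Sn %s%%  Sp %s%%  Pr %s%%  MCC %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$precision),
              if (is.na(x$mcc)) "NA" else sprintf("%.4f", x$mcc)))
  if (length(x$undefined) > 0L) cat("  note:", paste(x$undefined, collapse = "; "),
                                    "\n")
  invisible(x)
}

#' Generate repeated stratified train/test splits
#'
#' Draws `n_splits` independent seeded splits, each stratified by class so
#' that train and test have equal class proportions. With the default
#' training fraction of 0.5, half of the positives and half of the
#' negatives go to training. For odd class counts the training side
#' receives the extra record (ceiling).
#'
#' @param records Data frame with `id` and `label` (IP/IN).
#' @param n_splits Number of splits (default 5).
#' @param train_frac Training fraction per class (default 0.5).
#' @param seed Integer seed; split k uses sub-seed `seed + k - 1`.
#' @return List of `data_split` objects: lists with `train`, `test` (id
#'   vectors), `index`, `seed`.
#' @export
make_splits <- function(records, n_splits = 5L, train_frac = 0.5, seed = 1L) {
  stopifnot(is.data.frame(records), all(c("id", "label") %in% names(records)))
  classes <- unique(records$label)
  if (length(classes) < 2L) stop("both classes must be present to split",
                                 call. = FALSE)
  tab <- table(records$label)
  if (any(tab < 2L)) stop("need at least 2 records per class", call. = FALSE)
  lapply(seq_len(n_splits), function(k) {
    set.seed(as.integer(seed) + k - 1L)
    train <- character(0)
    for (cl in sort(classes)) {
      ids <- sort(records$id[records$label == cl])
      n_tr <- ceiling(length(ids) * train_frac)
      train <- c(train, sample(ids, n_tr))
    }
    structure(list(train = sort(train),
                   test = sort(setdiff(records$id, train)),
                   index = k, seed = as.integer(seed) + k - 1L),
              class = "data_split")
  })
}

#' Run the full split/train/evaluate protocol
#'
#' For each of `n_splits` stratified 50/50 splits: extract the 35 features
#' for every record (once, shared across splits since features do not
#' depend on the split), fit scaling on the training rows only, search the
#' SVM hyperparameter space by cross-validation on the training rows, train
#' the model, and evaluate on the held-out test rows. The final model is
#' the one with the best test accuracy (ties broken by higher MCC, then by
#' lower split index).
#'
#' @param records Labeled sequence records (`id`, `seq`, `label`).
#' @param panel SSRP panel.
#' @param source Interaction model or table.
#' @param spec A [search_spec()].
#' @param n_splits,train_frac,seed Split protocol parameters (see
#'   [make_splits()]).
#' @param engine Folding engine.
#' @param features Optional precomputed feature matrix (rows named by
#'   record id) to skip extraction, e.g. from [extract_feature_matrix()].
#' @return Object of class `protocol_result`: list with `report` (one row
#'   per split: s, t, d, g, c, CV, Acc, Sn, Sp, Pr, MCC), `best_model`,
#'   `best_split`, `splits`, `models`, `reports`.
#' @export
run_protocol <- function(records, panel = NULL, source = NULL,
                         spec = search_spec(), n_splits = 5L,
                         train_frac = 0.5, seed = 1L,
                         engine = c("fallback", "vienna"), features = NULL) {
  engine <- match.arg(engine)
  stopifnot(all(c("id", "label") %in% names(records)))
  if (is.null(features)) {
    features <- extract_feature_matrix(records, panel, source, engine = engine)
  }
  if (!all(records$id %in% rownames(features))) {
    stop("feature matrix is missing rows for some records", call. = FALSE)
  }
  eng_tag <- attr(features, "engine") %||% engine
  y <- stats::setNames(records$label, records$id)
  splits <- make_splits(records, n_splits = n_splits, train_frac = train_frac,
                        seed = seed)
  rows <- list(); models <- list(); reports <- list()
  for (sp in splits) {
    i <- sp$index
    Xtr <- features[sp$train, , drop = FALSE]
    Xte <- features[sp$test, , drop = FALSE]
    res <- tryCatch({
      scal <- fit_scaling(Xtr)
      opt <- optimize_svm(Xtr, y[sp$train], spec)
      model <- train_ires_model(Xtr, y[sp$train], opt$config, seed = seed,
                                scaling = scal,
                                panel_ids = if (!is.null(panel)) panel$id,
                                engine = eng_tag,
                                cv_accuracy = opt$cv_accuracy)
      attr(Xte, "engine") <- eng_tag
      pred <- predict(model, Xte)
      rep <- metrics(confusion(y[sp$test], pred$label))
      list(opt = opt, model = model, rep = rep)
    }, error = function(e) {
      stop("protocol failed at split ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    models[[i]] <- res$model
    reports[[i]] <- res$rep
    rows[[i]] <- data.frame(
      Model = i, s = res$opt$config$s, t = res$opt$config$t,
      d = res$opt$config$d, g = res$opt$config$g, c = res$opt$config$c,
      CV = res$opt$cv_accuracy, Acc = res$rep$accuracy,
      Sn = res$rep$sensitivity, Sp = res$rep$specificity,
      Pr = res$rep$precision, MCC = res$rep$mcc)
  }
  report <- do.call(rbind, rows)
  # best by test accuracy, tie-break: higher MCC, then lower split index
  acc <- report$Acc
  mcc <- ifelse(is.na(report$MCC), -Inf, report$MCC)
  best <- order(-acc, -mcc, report$Model)[1L]
  structure(list(report = report, best_model = models[[best]],
                 best_split = best, splits = splits, models = models,
                 reports = reports, seed = as.integer(seed)),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("Split/train/evaluate protocol (", nrow(x$report), " splits)\n", sep = "")
  print(format(x$report, digits = 4), row.names = FALSE)
  cat("Selected model: split", x$best_split, "\n")
  invisible(x)
}

#' Write the protocol report as TSV
#' @param result A `protocol_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol_report <- function(result, path) {
  utils::write.table(result$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
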