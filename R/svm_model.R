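MODEL_FORMAT_VERSION <- 1L

#' Construct an SVM configuration (LibSVM-style parameter coding)
#'
#' Parameters follow the svm-train coding: `s` is the SVM type (0 = C-SVC,
#' 1 = nu-SVC, 2 = one-class), `t` the kernel (0 linear, 1 polynomial,
#' 2 RBF, 3 sigmoid), `d` the polynomial degree, `g` the kernel gamma and
#' `c` the cost (interpreted as nu for s = 1 and s = 2).
#'
#' @param s,t,d,g,c Numeric parameters as above.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(s = 0, t = 0, d = 1, g = 1, c = 1) {
  s <- as.integer(s); t <- as.integer(t); d <- as.integer(d)
  if (!s %in% 0:2) stop("s must be 0 (C-SVC), 1 (nu-SVC) or 2 (one-class)",
                        call. = FALSE)
  if (!t %in% 0:3) stop("t must be 0 (linear), 1 (polynomial), 2 (RBF) or ",
                        "3 (sigmoid)", call. = FALSE)
  if (d < 1L) stop("degree d must be >= 1", call. = FALSE)
  if (g <= 0) stop("gamma g must be > 0", call. = FALSE)
  if (c <= 0) stop("cost c must be > 0", call. = FALSE)
  structure(list(s = s, t = t, d = d, g = g, c = c), class = "svm_config")
}

#' Parse a LibSVM-style flag string into an [svm_config()]
#'
#' @param text Flag string, e.g. `"-s 2 -t 0 -d 1 -g 3.1192 -c 0.0347"`.
#'   `s = 2` (one-class) is accepted at parse time; training on labeled
#'   two-class data rejects it unless explicitly allowed (see
#'   [train_ires_model()]).
#' @return An `svm_config`.
#' @export
parse_config <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) %% 2L != 0L) stop("malformed flag string: ", text,
                                     call. = FALSE)
  args <- list(s = 0, t = 0, d = 1, g = 1, c = 1)
  for (i in seq(1L, length(toks), by = 2L)) {
    key <- sub("^-", "", toks[i])
    if (!grepl("^-", toks[i]) || !key %in% names(args)) {
      stop("unknown flag '", toks[i], "' (expected -s -t -d -g -c)",
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(toks[i + 1L]))
    if (is.na(val)) stop("non-numeric value for -", key, ": ", toks[i + 1L],
                         call. = FALSE)
    args[[key]] <- val
  }
  do.call(svm_config, args)
}

#' @method format svm_config
#' @export
format.svm_config <- function(x, ...) {
  sprintf("-s %d -t %d -d %d -g %g -c %g", x$s, x$t, x$d, x$g, x$c)
}

#' @export
print.svm_config <- function(x, ...) {
  cat("svm_config:", format(x), "\n")
  invisible(x)
}

.e1071_kernel <- c("linear", "polynomial", "radial", "sigmoid")

.fit_svm <- function(Xs, yf, cfg, seed) {
  set.seed(as.integer(seed))
  kern <- .e1071_kernel[cfg$t + 1L]
  if (cfg$s == 0L) {
    e1071::svm(x = Xs, y = yf, type = "C-classification", kernel = kern,
               degree = cfg$d, gamma = cfg$g, coef0 = 0, cost = cfg$c,
               scale = FALSE)
  } else if (cfg$s == 1L) {
    e1071::svm(x = Xs, y = yf, type = "nu-classification", kernel = kern,
               degree = cfg$d, gamma = cfg$g, coef0 = 0, nu = cfg$c,
               scale = FALSE)
  } else {
    # one-class: fit on the positive (IP) rows only
    e1071::svm(x = Xs[yf == "IP", , drop = FALSE], type = "one-classification",
               kernel = kern, degree = cfg$d, gamma = cfg$g, coef0 = 0,
               nu = cfg$c, scale = FALSE)
  }
}

# Signed decision values oriented so that >= 0 means IP.
.decision_ip <- function(fit, Xs) {
  pr <- stats::predict(fit, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  d <- as.numeric(dv[, 1L])
  cn <- colnames(dv)[1L]
  if (!is.null(cn) && grepl("^IN/", cn)) d <- -d
  d
}

#' Train the IRES SVM classifier
#'
#' Fits a LibSVM-backed SVM on scaled 35-feature vectors. Scaling parameters
#' are fitted on the supplied training matrix (or passed in, e.g. by the
#' evaluation protocol which fits them on the training split only) and are
#' stored inside the model together with the panel order and folding-engine
#' tag, so a saved model predicts standalone and refuses features produced
#' under a different engine or panel.
#'
#' `s = 2` selects LibSVM's one-class SVM, which ignores the negative class;
#' for labeled two-class data this is almost always a mistake, so it is
#' rejected with a diagnostic unless `allow_one_class = TRUE`, in which case
#' the model is fitted on the IP rows only and classifies by the sign of the
#' one-class decision value.
#'
#' @param X Numeric feature matrix (unscaled), rows = records.
#' @param y Labels, `"IP"`/`"IN"`.
#' @param cfg An [svm_config()].
#' @param seed Integer seed.
#' @param scaling Optional pre-fitted [fit_scaling()] result.
#' @param panel_ids Character vector of SSRP panel ids (recorded).
#' @param engine Engine tag of the features (recorded).
#' @param allow_one_class Permit `s = 2` on labeled data.
#' @param cv_accuracy Optional cross-validation accuracy to record.
#' @return Object of class `ires_model`.
#' @export
train_ires_model <- function(X, y, cfg = svm_config(), seed = 1L,
                             scaling = NULL, panel_ids = NULL,
                             engine = NA_character_,
                             allow_one_class = FALSE, cv_accuracy = NA_real_) {
  stopifnot(inherits(cfg, "svm_config"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y",
                                 call. = FALSE)
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0L)[1L]
    stop("missing feature values in row ",
         if (!is.null(rownames(X))) rownames(X)[bad] else bad, call. = FALSE)
  }
  bad <- setdiff(unique(y), c("IP", "IN"))
  if (length(bad) > 0L) stop("labels must be IP or IN; found: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes (IP and IN) must be present",
                                   call. = FALSE)
  if (cfg$s == 2L && !allow_one_class) {
    stop("config selects a one-class SVM (-s 2) but the training data are ",
         "labeled two-class; a one-class model ignores the IN class. Pass ",
         "allow_one_class = TRUE to train on the IP rows only.",
         call. = FALSE)
  }
  if (cfg$s %in% c(1L, 2L) && cfg$c >= 1) {
    stop("for s = ", cfg$s, " the -c value is interpreted as nu and must ",
         "lie in (0, 1)", call. = FALSE)
  }
  if (is.null(scaling)) scaling <- fit_scaling(X)
  Xs <- apply_scaling(X, scaling)
  yf <- factor(y, levels = c("IP", "IN"))
  fit <- .fit_svm(Xs, yf, cfg, seed)
  structure(list(fit = fit, config = cfg, scaling = scaling,
                 panel_ids = panel_ids, engine = engine,
                 seed = as.integer(seed), cv_accuracy = cv_accuracy,
                 one_class = cfg$s == 2L,
                 feature_names = colnames(X),
                 format_version = MODEL_FORMAT_VERSION,
                 package_version = as.character(utils::packageVersion("irespred"))),
            class = "ires_model")
}

#' Predict IP/IN labels for feature vectors
#'
#' Applies the model's stored scaling, computes the signed SVM decision
#' value oriented so that positive means IRES-positive, and thresholds at 0
#' (a decision value of exactly 0 is called IP). Prediction refuses feature
#' matrices produced under a different folding engine or panel order than
#' the model was trained with, because such features are not comparable.
#'
#' @param object An `ires_model`.
#' @param X Feature vector (length 35) or matrix (rows = records), unscaled.
#' @param ... Unused.
#' @return Data frame with columns `id`, `label` (IP/IN), `decision_value`.
#' @export
predict.ires_model <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list("query", names(X)))
  X <- as.matrix(X)
  eng <- attr(X, "engine")
  if (!is.null(eng) && !is.na(object$engine) && !identical(eng, object$engine)) {
    stop("features were computed with engine '", eng, "' but the model was ",
         "trained with engine '", object$engine, "'; refusing to mix engines",
         call. = FALSE)
  }
  if (ncol(X) != length(object$scaling$min)) {
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         length(object$scaling$min), call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(object$feature_names) &&
      !identical(colnames(X), object$feature_names)) {
    stop("feature names/order do not match the model (panel mismatch?)",
         call. = FALSE)
  }
  Xs <- apply_scaling(X, object$scaling)
  d <- .decision_ip(object$fit, Xs)
  data.frame(id = rownames(X) %||% as.character(seq_len(nrow(X))),
             label = ifelse(d >= 0, "IP", "IN"),
             decision_value = d,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validation accuracy
#'
#' Folds are assigned per class on records sorted by id (row name), using a
#' seeded permutation, so the partition depends only on (ids, labels, seed)
#' and the reported accuracy is invariant to row order. Returns the mean
#' fold accuracy in percent.
#'
#' @param X Unscaled feature matrix.
#' @param y IP/IN labels.
#' @param cfg An [svm_config()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param allow_one_class Passed to [train_ires_model()].
#' @return Mean cross-validation accuracy, percent.
#' @export
cross_validate <- function(X, y, cfg = svm_config(), k = 10L, seed = 1L,
                           allow_one_class = FALSE) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (nrow(X) < k) stop("need at least k rows", call. = FALSE)
  ids <- rownames(X) %||% sprintf("row%08d", seq_len(nrow(X)))
  ord <- order(ids)
  fold <- integer(nrow(X))
  set.seed(as.integer(seed))
  for (cl in sort(unique(y))) {
    idx <- ord[y[ord] == cl]
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (!any(te)) next                  # class sizes < k can leave empty folds
    if (length(unique(y[tr])) < 2L) stop("fold ", f, " lost a class; ",
                                         "reduce k", call. = FALSE)
    m <- train_ires_model(X[tr, , drop = FALSE], y[tr], cfg, seed = seed,
                          allow_one_class = allow_one_class)
    pred <- predict(m, X[te, , drop = FALSE])
    acc[f] <- mean(pred$label == y[te])
  }
  100 * mean(acc, na.rm = TRUE)
}

#' Define a hyperparameter search space
#'
#' @param strategy `"pso"` (particle swarm, the default) or `"grid"`.
#' @param s_values,t_values,d_values Discrete candidate sets for SVM type,
#'   kernel and degree. `s = 2` is excluded by default (see
#'   [train_ires_model()]).
#' @param log2g_range,log2c_range Ranges for log2(gamma) and log2(cost/nu).
#' @param swarm Swarm size.
#' @param iterations PSO iterations.
#' @param inertia,accel_personal,accel_global PSO constants.
#' @param grid_points Number of grid points per continuous dimension for the
#'   grid strategy.
#' @param k Cross-validation folds used as the objective.
#' @param seed Integer seed.
#' @return Object of class `search_spec`.
#' @export
search_spec <- function(strategy = c("pso", "grid"),
                        s_values = 0L, t_values = c(0L, 2L), d_values = 1:3,
                        log2g_range = c(-8, 3), log2c_range = c(-5, 8),
                        swarm = 20L, iterations = 50L, inertia = 0.729,
                        accel_personal = 1.49445, accel_global = 1.49445,
                        grid_points = 4L, k = 10L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(length(s_values) >= 1L, length(t_values) >= 1L,
            length(d_values) >= 1L,
            diff(range(log2g_range)) >= 0, diff(range(log2c_range)) >= 0)
  if (swarm < 1L) stop("swarm size must be >= 1", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  structure(list(strategy = strategy, s_values = as.integer(s_values),
                 t_values = as.integer(t_values), d_values = as.integer(d_values),
                 log2g_range = range(log2g_range),
                 log2c_range = range(log2c_range),
                 swarm = as.integer(swarm), iterations = as.integer(iterations),
                 inertia = inertia, accel_personal = accel_personal,
                 accel_global = accel_global, grid_points = as.integer(grid_points),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "search_spec")
}

.cfg_from_position <- function(pos, spec) {
  snap <- function(v, set) set[which.min(abs(set - v))]
  g <- 2 ^ pos[4L]
  c_ <- 2 ^ pos[5L]
  s <- snap(pos[1L], spec$s_values)
  if (s %in% c(1L, 2L)) c_ <- min(c_, 0.99)   # nu must stay in (0, 1)
  svm_config(s = s, t = snap(pos[2L], spec$t_values),
             d = snap(pos[3L], spec$d_values), g = g, c = c_)
}

.cv_objective <- function(X, y, cfg, spec) {
  tryCatch(cross_validate(X, y, cfg, k = spec$k, seed = spec$seed),
           error = function(e) -Inf)
}

#' Optimize SVM hyperparameters by particle swarm or grid search
#'
#' The objective is stratified k-fold cross-validation accuracy on the
#' supplied (training) data. The particle swarm runs a standard global-best
#' PSO with inertia 0.729 and acceleration constants 1.49445 over
#' (s, t, d, log2 g, log2 c), with the discrete coordinates snapped to their
#' candidate sets; everything is seeded. The grid strategy deterministically
#' enumerates the discretized space and is the exhaustive fallback. Ties are
#' broken by first configuration found.
#'
#' @param X Unscaled feature matrix (training split only).
#' @param y IP/IN labels.
#' @param spec A [search_spec()].
#' @return List with `config` (best [svm_config()]), `cv_accuracy`
#'   (percent) and `evaluations` (number of CV evaluations).
#' @export
optimize_svm <- function(X, y, spec = search_spec()) {
  stopifnot(inherits(spec, "search_spec"))
  if (spec$strategy == "grid") {
    gvals <- 2 ^ seq(spec$log2g_range[1L], spec$log2g_range[2L],
                     length.out = spec$grid_points)
    cvals <- 2 ^ seq(spec$log2c_range[1L], spec$log2c_range[2L],
                     length.out = spec$grid_points)
    best <- NULL; best_acc <- -Inf; nev <- 0L
    for (s in spec$s_values) for (t in spec$t_values) {
      dset <- if (t == 1L) spec$d_values else spec$d_values[1L]
      for (d in dset) for (g in gvals) for (c_ in cvals) {
        if (s %in% c(1L, 2L)) c_ <- min(c_, 0.99)
        cfg <- svm_config(s, t, d, g, c_)
        acc <- .cv_objective(X, y, cfg, spec)
        nev <- nev + 1L
        if (acc > best_acc) { best_acc <- acc; best <- cfg }
      }
    }
    if (is.null(best)) stop("empty search space", call. = FALSE)
    return(list(config = best, cv_accuracy = best_acc, evaluations = nev))
  }
  # particle swarm
  set.seed(spec$seed)
  lo <- c(min(spec$s_values), min(spec$t_values), min(spec$d_values),
          spec$log2g_range[1L], spec$log2c_range[1L])
  hi <- c(max(spec$s_values), max(spec$t_values), max(spec$d_values),
          spec$log2g_range[2L], spec$log2c_range[2L])
  nd <- 5L
  P <- matrix(stats::runif(spec$swarm * nd, rep(lo, each = spec$swarm),
                           rep(hi, each = spec$swarm)), spec$swarm, nd)
  V <- matrix(stats::runif(spec$swarm * nd, -1, 1), spec$swarm, nd) *
    matrix(rep((hi - lo) * 0.1 + 1e-9, each = spec$swarm), spec$swarm, nd)
  pbest <- P
  pbest_val <- rep(-Inf, spec$swarm)
  gbest <- P[1L, ]; gbest_val <- -Inf; gbest_cfg <- NULL
  nev <- 0L
  for (it in seq_len(spec$iterations + 1L)) {    # first pass evaluates init
    for (p in seq_len(spec$swarm)) {
      cfg <- .cfg_from_position(P[p, ], spec)
      acc <- .cv_objective(X, y, cfg, spec)
      nev <- nev + 1L
      if (acc > pbest_val[p]) { pbest_val[p] <- acc; pbest[p, ] <- P[p, ] }
      if (acc > gbest_val) { gbest_val <- acc; gbest <- P[p, ]; gbest_cfg <- cfg }
    }
    if (it > spec$iterations) break
    r1 <- matrix(stats::runif(spec$swarm * nd), spec$swarm, nd)
    r2 <- matrix(stats::runif(spec$swarm * nd), spec$swarm, nd)
    V <- spec$inertia * V +
      spec$accel_personal * r1 * (pbest - P) +
      spec$accel_global * r2 * (matrix(gbest, spec$swarm, nd, byrow = TRUE) - P)
    P <- P + V
    P <- pmin(pmax(P, matrix(lo, spec$swarm, nd, byrow = TRUE)),
              matrix(hi, spec$swarm, nd, byrow = TRUE))
  }
  list(config = gbest_cfg, cv_accuracy = gbest_val, evaluations = nev)
}

#' Save a trained IRES model to disk
#'
#' The file bundles the classifier, configuration, scaling parameters, panel
#' ids, engine tag, seeds and a format version; loading a file written by a
#' newer format fails cleanly.
#'
#' @param model An `ires_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ires_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a trained IRES model
#' @param path Path written by [save_model()].
#' @return An `ires_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ires_model")) stop("not an IRES model file: ", path,
                                           call. = FALSE)
  if (model$format_version > MODEL_FORMAT_VERSION) {
    stop("model file format version ", model$format_version,
         " is newer than this package supports (", MODEL_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  model
}

#' @export
print.ires_model <- function(x, ...) {
  cat("IRES SVM model\n")
  cat("  config      :", format(x$config), "\n")
  cat("  engine      :", x$engine, "\n")
  cat("  CV accuracy :",
      if (is.na(x$cv_accuracy)) "not recorded" else sprintf("%.2f%%", x$cv_accuracy),
      "\n")
  cat("  panel       :", if (is.null(x$panel_ids)) "none recorded" else
    paste0(length(x$panel_ids), " proteins"), "\n")
  invisible(x)
}
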