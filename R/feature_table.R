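#' Canonical names of the 35 features, in order
#'
#' Features 1-8 are general sequence/structure properties of the UTR:
#' length (bases), number of upstream AUGs, the hairpin / external /
#' internal / multibranch / total loop counts of the predicted secondary
#' structure, and its folding energy (kcal/mol; pseudo-energy under the
#' fallback engine). Features 9-35 are the interaction probabilities with
#' the 27 panel proteins, in panel order.
#'
#' @param panel_ids Optional character vector of 27 panel ids; when given,
#'   the interaction features are named `p_<id>` instead of `p_ssrp_<k>`.
#' @return Character vector of length 35.
#' @export
feature_names <- function(panel_ids = NULL) {
  general <- c("length", "n_uaug", "n_hairpin", "n_external", "n_internal",
               "n_multi", "n_total", "folding_energy")
  if (is.null(panel_ids)) {
    c(general, sprintf("p_ssrp_%02d", 1:27))
  } else {
    stopifnot(length(panel_ids) == 27L)
    c(general, paste0("p_", panel_ids))
  }
}

#' Extract the ordered 35-feature vector for one sequence record
#'
#' Deterministic composition of the structure features (fold, loop
#' decomposition, upstream-AUG count, length, folding energy) and the
#' 27-protein interaction profile, in the canonical order of
#' [feature_names()].
#'
#' @param record One-row data frame with `id` and `seq` (or an RNA string).
#' @param panel SSRP panel from [load_ssrp_panel()].
#' @param source Interaction model or precomputed table (see
#'   [ssrp_profile()]).
#' @param engine Folding engine selector, passed to [fold()].
#' @return Named numeric vector of length 35 with attribute `engine`.
#' @export
extract_features <- function(record, panel, source,
                             engine = c("fallback", "vienna")) {
  engine <- match.arg(engine)
  if (is.character(record)) {
    record <- data.frame(id = "query", seq = record, stringsAsFactors = FALSE)
  }
  id <- record$id[1L]
  seq <- record$seq[1L]
  out <- tryCatch({
    st <- fold(seq, engine = engine)
    lc <- decompose_loops(st$db)
    prof <- ssrp_profile(seq, panel, source, rna_id = id)
    v <- c(nchar(seq), count_uaugs(seq), lc[["hairpin"]], lc[["external"]],
           lc[["internal"]], lc[["multi"]], lc[["total"]], st$mfe, prof)
    names(v) <- feature_names()
    attr(v, "engine") <- st$engine
    v
  }, error = function(e) {
    stop("feature extraction failed for record '", id, "': ",
         conditionMessage(e), call. = FALSE)
  })
  out
}

#' Extract the feature matrix for a batch of records
#'
#' @param records Data frame of sequence records.
#' @inheritParams extract_features
#' @return Numeric matrix (records x 35) with rownames = record ids and
#'   attribute `engine`.
#' @export
extract_feature_matrix <- function(records, panel, source,
                                   engine = c("fallback", "vienna")) {
  engine <- match.arg(engine)
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  X <- matrix(NA_real_, nrow(records), 35L,
              dimnames = list(records$id, feature_names()))
  eng <- NULL
  for (i in seq_len(nrow(records))) {
    v <- extract_features(records[i, , drop = FALSE], panel, source,
                          engine = engine)
    X[i, ] <- v
    eng <- attr(v, "engine")
  }
  attr(X, "engine") <- eng
  X
}

#' Fit per-feature linear scaling parameters on a training matrix
#'
#' Captures the per-feature minimum and maximum of the training matrix for
#' scaling to \[-1, +1\] (the svm-scale convention). Constant features are
#' flagged; their scaled value is 0 for every input.
#'
#' @param X Numeric matrix (>= 2 rows).
#' @return Object of class `scaling_params`.
#' @export
fit_scaling <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit scaling", call. = FALSE)
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  mn <- apply(X, 2L, min)
  mx <- apply(X, 2L, max)
  structure(list(min = mn, max = mx, constant = mx == mn,
                 feature_names = colnames(X)),
            class = "scaling_params")
}

#' Apply fitted scaling to a feature matrix
#'
#' x' = 2 (x - min) / (max - min) - 1. Training data maps into \[-1, +1\];
#' unseen values extrapolate linearly without clipping (silent clipping
#' would discard information at prediction time). Constant features scale
#' to 0.
#'
#' @param X Numeric matrix or vector with the same columns as at fit time.
#' @param sp A `scaling_params` object.
#' @return Scaled matrix of the same shape.
#' @export
apply_scaling <- function(X, sp) {
  stopifnot(inherits(sp, "scaling_params"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (ncol(X) != length(sp$min)) {
    stop("column count (", ncol(X), ") does not match scaling parameters (",
         length(sp$min), ")", call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(sp$feature_names) &&
      !identical(colnames(X), sp$feature_names)) {
    stop("feature names do not match scaling parameters", call. = FALSE)
  }
  rng <- sp$max - sp$min
  rng[sp$constant] <- 1        # avoid 0/0; constant columns forced to 0 below
  S <- sweep(sweep(X, 2L, sp$min), 2L, rng, "/") * 2 - 1
  S[, sp$constant] <- 0
  S
}

#' Invert fitted scaling (round-trip utility)
#' @param S Scaled matrix.
#' @param sp A `scaling_params` object.
#' @return Matrix on the original feature scale; constant features are
#'   restored to their fitted constant value.
#' @export
invert_scaling <- function(S, sp) {
  stopifnot(inherits(sp, "scaling_params"))
  S <- as.matrix(S)
  rng <- sp$max - sp$min
  rng[sp$constant] <- 0
  X <- sweep(sweep((S + 1) / 2, 2L, rng, "*"), 2L, sp$min, "+")
  X[, sp$constant] <- matrix(sp$min[sp$constant], nrow(X),
                             sum(sp$constant), byrow = TRUE)
  X
}

#' Write a feature table to TSV
#'
#' Header: `id`, optionally `label`, then the 35 canonical feature names.
#'
#' @param X Feature matrix with rownames = ids.
#' @param path Output path.
#' @param labels Optional named label vector (IP/IN) keyed by id.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(X, path, labels = NULL) {
  df <- data.frame(id = rownames(X), stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- unname(labels[df$id])
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return List with `X` (matrix, rownames = ids) and `labels` (named vector
#'   or NULL).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature table must have an 'id' column",
                                 call. = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- stats::setNames(df$label, df$id)
    df$label <- NULL
  }
  X <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(X) <- df$id
  list(X = X, labels = labels)
}
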