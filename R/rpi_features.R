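# Conjoint-triad classes: residues grouped by dipole and side-chain volume.
TRIAD_CLASSES <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C")
)

.triad_class_of <- local({
  map <- integer(0)
  for (k in seq_along(TRIAD_CLASSES)) map[TRIAD_CLASSES[[k]]] <- k
  map
})

#' Names of the 343 conjoint-triad features
#' @return Character vector `t<EOL>` of class-triple labels like "t123".
#' @keywords internal
triad_names <- function() {
  g <- expand.grid(a = 1:7, b = 1:7, c = 1:7)
  # vary last index fastest: canonical odometer order
  g <- g[order(g$a, g$b, g$c), ]
  sprintf("t%d%d%d", g$a, g$b, g$c)
}

#' Encode a protein as normalized conjoint-triad frequencies
#'
#' Residues are mapped to 7 physicochemical classes
#' (\{AGV\}, \{ILFP\}, \{YMTS\}, \{HNQW\}, \{RK\}, \{DE\}, \{C\}); every
#' overlapping 3-residue window contributes one count to its class triple,
#' and counts are normalized by the number of counted windows. Windows
#' containing a residue outside the 7-class alphabet (X and other
#' non-standard codes) are dropped rather than erroring, for robustness to
#' database sequences.
#'
#' @param seq Amino-acid string (length >= 3), or a one-row protein record.
#' @return Numeric vector of length 343 summing to 1 (all-zero when no
#'   window is countable).
#' @export
encode_protein <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$seq[1L]
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 3L) stop("protein too short to encode (need >= 3 residues)",
                   call. = FALSE)
  cls <- .triad_class_of[strsplit(toupper(seq), "")[[1]]]
  v <- stats::setNames(numeric(343L), triad_names())
  a <- cls[1:(n - 2L)]; b <- cls[2:(n - 1L)]; d <- cls[3:n]
  ok <- !is.na(a) & !is.na(b) & !is.na(d)
  if (any(ok)) {
    idx <- (a[ok] - 1L) * 49L + (b[ok] - 1L) * 7L + d[ok]
    tab <- tabulate(idx, nbins = 343L)
    v[] <- tab / sum(tab)
  }
  v
}

#' Names of the RNA k-mer features
#' @param k Word size.
#' @return Character vector of the 4^k k-mers, last position fastest.
#' @keywords internal
kmer_names <- function(k = 4L) {
  bases <- c("A", "C", "G", "U")
  g <- do.call(expand.grid, rep(list(bases), k))
  g <- g[do.call(order, as.list(g)), , drop = FALSE]
  apply(g, 1L, paste, collapse = "")
}

#' Encode an RNA as normalized overlapping k-mer frequencies
#'
#' Counts every overlapping k-mer over \{A, C, G, U\} (windows containing N
#' are dropped) and divides by the number of counted windows. Only the sense
#' strand is encoded; no reverse complementing is applied.
#'
#' @param seq Normalized RNA string of length >= k.
#' @param k Word size (default 4, giving 256 features).
#' @return Numeric vector of length 4^k summing to 1 (all-zero when every
#'   window contains N).
#' @export
encode_rna <- function(seq, k = 4L) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L)
  n <- nchar(seq)
  if (n < k) stop("RNA too short to encode (need >= ", k, " bases)",
                  call. = FALSE)
  base_idx <- stats::setNames(1:4, c("A", "C", "G", "U"))
  code <- base_idx[strsplit(seq, "")[[1]]]          # NA for N
  nm <- kmer_names(k)
  v <- stats::setNames(numeric(4L^k), nm)
  nw <- n - k + 1L
  idx <- rep(0L, nw)
  ok <- rep(TRUE, nw)
  for (off in 0:(k - 1L)) {
    b <- code[(1L + off):(nw + off)]
    ok <- ok & !is.na(b)
    idx <- idx * 4L + ifelse(is.na(b), 0L, b - 1L)
  }
  if (any(ok)) {
    tab <- tabulate(idx[ok] + 1L, nbins = 4L^k)
    v[] <- tab / sum(tab)
  }
  v
}

.encode_pair_matrix <- function(rnas, prots, k = 4L) {
  pm <- t(vapply(prots, encode_protein, numeric(343L)))
  rm_ <- t(vapply(rnas, encode_rna, numeric(4L^k), k = k))
  cbind(pm, rm_)
}

#' Train an RNA-protein interaction classifier
#'
#' A locally trainable surrogate for partner-specific RNA-protein
#' interaction prediction: a seeded random forest over the concatenated
#' 343-dimensional conjoint-triad protein encoding and 256-dimensional RNA
#' 4-mer encoding (599 features total). A precomputed-table path
#' ([ssrp_profile()]) exists for users who already hold interaction
#' probabilities from an external predictor.
#'
#' @param pairs Data frame with columns `rna` (RNA strings), `protein`
#'   (amino-acid strings) and `label` (0/1, 1 = interacting).
#' @param ntree Number of trees.
#' @param seed Integer seed; training is reproducible given the seed.
#' @return Object of class `interaction_model`.
#' @export
train_interaction_model <- function(pairs, ntree = 200L, seed) {
  stopifnot(is.data.frame(pairs),
            all(c("rna", "protein", "label") %in% names(pairs)))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (nrow(pairs) == 0L) stop("empty training set", call. = FALSE)
  y <- factor(pairs$label, levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) {
    stop("both interaction classes (0 and 1) must be present", call. = FALSE)
  }
  X <- .encode_pair_matrix(pairs$rna, pairs$protein)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = X, y = y, ntree = as.integer(ntree))
  structure(list(forest = rf, ntree = as.integer(ntree),
                 seed = as.integer(seed), family = "random-forest",
                 n_train = nrow(pairs)),
            class = "interaction_model")
}

#' Predicted probability that an RNA and a protein interact
#'
#' @param model An `interaction_model` from [train_interaction_model()].
#' @param rna RNA string (one or more).
#' @param protein Amino-acid string (recycled against `rna`).
#' @return Numeric vector of probabilities of the interacting class, in
#'   \[0, 1\].
#' @export
interaction_probability <- function(model, rna, protein) {
  if (!inherits(model, "interaction_model")) {
    stop("model must be a fitted interaction_model", call. = FALSE)
  }
  n <- max(length(rna), length(protein))
  rna <- rep_len(rna, n); protein <- rep_len(protein, n)
  X <- .encode_pair_matrix(rna, protein)
  unname(stats::predict(model$forest, X, type = "prob")[, "1"])
}

#' Load or validate a panel of small-subunit ribosomal proteins
#'
#' The predictive model uses interaction probabilities against an ordered
#' panel of exactly 27 small-subunit (40S) ribosomal proteins; the panel
#' order is recorded in every trained model and checked at prediction time.
#' The package ships a synthetic stand-in panel
#' (`inst/extdata/ssrp_panel_synthetic.fasta`) so the pipeline runs without
#' downloads; supply your own protein FASTA of the 27 real sequences for
#' biological use.
#'
#' @param path Protein FASTA path; default is the bundled synthetic panel.
#' @param expected_size Required panel size (27). Set `override = TRUE` to
#'   experiment with other sizes.
#' @param override Allow panel sizes other than 27.
#' @return Data frame of protein records with attribute `panel_ids`.
#' @export
load_ssrp_panel <- function(path = system.file("extdata",
                                               "ssrp_panel_synthetic.fasta",
                                               package = "irespred"),
                            expected_size = 27L, override = FALSE) {
  panel <- read_fasta(path, alphabet = "protein")
  if (!override && nrow(panel) != expected_size) {
    stop("SSRP panel must contain exactly ", expected_size,
         " proteins (found ", nrow(panel), "); use override = TRUE to ",
         "experiment with other sizes", call. = FALSE)
  }
  attr(panel, "panel_ids") <- panel$id
  panel
}

#' Read a precomputed interaction-probability table
#'
#' @param path TSV with columns `rna_id`, `protein_id`, `probability`.
#' @return Data frame of class `interaction_table`.
#' @export
read_interaction_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("rna_id", "protein_id", "probability")
  if (!all(need %in% names(tab))) {
    stop("interaction table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$probability < 0 | tab$probability > 1)) {
    stop("interaction probabilities must lie in [0, 1]", call. = FALSE)
  }
  class(tab) <- c("interaction_table", class(tab))
  tab
}

#' Interaction-probability profile of one RNA against the SSRP panel
#'
#' Returns one probability per panel protein, in panel order. When `source`
#' is a precomputed table it overrides any model: values are looked up by
#' (`rna_id`, `protein_id`) and a missing cell is an error, never silently
#' imputed.
#'
#' @param rna RNA string.
#' @param panel Protein panel from [load_ssrp_panel()].
#' @param source An `interaction_model` or an `interaction_table`.
#' @param rna_id Record id used for table lookup.
#' @param override Allow panel sizes other than 27.
#' @return Named numeric vector of length `nrow(panel)` in \[0, 1\].
#' @export
ssrp_profile <- function(rna, panel, source, rna_id = NULL, override = FALSE) {
  stopifnot(is.data.frame(panel))
  if (!override && nrow(panel) != 27L) {
    stop("SSRP panel must contain exactly 27 proteins (found ",
         nrow(panel), ")", call. = FALSE)
  }
  if (inherits(source, "interaction_table")) {
    if (is.null(rna_id)) stop("rna_id is required for table lookup",
                              call. = FALSE)
    key <- match(paste(rna_id, panel$id), paste(source$rna_id, source$protein_id))
    if (anyNA(key)) {
      stop("interaction table is missing cell(s) for rna '", rna_id,
           "' x protein(s) ", paste(panel$id[is.na(key)], collapse = ", "),
           call. = FALSE)
    }
    stats::setNames(source$probability[key], panel$id)
  } else if (inherits(source, "interaction_model")) {
    stats::setNames(interaction_probability(source, rep(rna, nrow(panel)),
                                            panel$seq), panel$id)
  } else {
    stop("source must be an interaction_model or interaction_table",
         call. = FALSE)
  }
}
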