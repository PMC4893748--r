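#' @useDynLib irespred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U (DNA input is accepted silently because most
#' UTR sequences in public databases are stored as DNA), and maps every IUPAC
#' ambiguity code to N. N never participates in a base pair, a k-mer window
#' or an AUG match downstream.
#'
#' @param raw Character scalar, the raw sequence (whitespace is ignored).
#' @return Character scalar over \{A, C, G, U, N\}.
#' @examples
#' normalize_rna("acgt")   # "ACGU"
#' normalize_rna("ACGRY")  # "ACGNN"
#' @export
normalize_rna <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), IUPAC_NT)
  if (length(bad) > 0L) {
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ch[ch == "T"] <- "U"
  ch[!(ch %in% c("A", "C", "G", "U"))] <- "N"
  paste(ch, collapse = "")
}

#' Read a FASTA file of nucleotide or protein sequences
#'
#' Nucleotide sequences are normalized with [normalize_rna()]; protein
#' sequences are uppercased and checked against the 20 standard residues
#' (X is tolerated and is dropped from encoding windows downstream).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param labels Optional named character vector (or path to a two-column
#'   `id<TAB>label` TSV) assigning class labels `"IP"`/`"IN"` by record id.
#' @return A data frame with columns `id`, `seq` and, for nucleotides,
#'   `label` (NA when unknown) and `source`.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein"),
                       labels = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty) > 0L) {
    stop("FASTA entry with empty sequence: ", ids[empty[1L]], call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  if (alphabet == "nucleotide") {
    seqs <- vapply(seq_along(seqs), function(i) {
      tryCatch(normalize_rna(seqs[[i]]),
               error = function(e) stop("record '", ids[i], "': ",
                                        conditionMessage(e), call. = FALSE))
    }, character(1L))
    rec <- data.frame(id = ids, seq = unname(seqs),
                      label = NA_character_, source = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(labels)) {
      if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
        labels <- read_label_table(labels)
      }
      hit <- match(rec$id, names(labels))
      rec$label <- unname(labels[hit])
    }
    rec
  } else {
    seqs <- toupper(seqs)
    for (i in seq_along(seqs)) {
      bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), c(AA20, "X"))
      if (length(bad) > 0L) {
        stop("record '", ids[i], "': invalid amino-acid character(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
  }
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", records$seq[i])
    cat(">", records$id[i], "\n", body, file = con, sep = "")
  }
  invisible(path)
}

#' Read a two-column id/label TSV
#'
#' @param path TSV with columns `id` and `label`; labels must be IP or IN.
#' @return Named character vector of labels.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label table must have columns 'id' and 'label'", call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), c("IP", "IN"))
  if (length(bad) > 0L) {
    stop("labels must be IP or IN; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(tab$label, tab$id)
}

#' Validate a batch of nucleotide records against the input contract
#'
#' The published prediction service accepts up to 10 nucleotide sequences of
#' 15 to 7500 bases. Library use (e.g. training sets) disables the count
#' limit; the strict limit is a per-request resource policy, not part of the
#' method.
#'
#' @param records Data frame of sequence records (see [read_fasta()]).
#' @param min_len,max_len Accepted length bounds in bases.
#' @param max_count Maximum number of accepted records in strict mode.
#' @param strict Logical; enforce `max_count` as a batch error.
#' @return List with elements `accepted` (data frame) and `rejected`
#'   (data frame with an extra `reason` column).
#' @export
validate_batch <- function(records, min_len = 15L, max_len = 7500L,
                           max_count = 10L, strict = FALSE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  len <- nchar(records$seq)
  reason <- rep(NA_character_, nrow(records))
  reason[len < min_len] <- sprintf("sequence shorter than %d bases", min_len)
  reason[len > max_len] <- sprintf("sequence longer than %d bases", max_len)
  ok <- is.na(reason)
  accepted <- records[ok, , drop = FALSE]
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected) > 0L) rejected$reason <- reason[!ok]
  if (strict && nrow(accepted) > max_count) {
    stop("batch limit exceeded: ", nrow(accepted), " valid sequences, ",
         "at most ", max_count, " accepted per request", call. = FALSE)
  }
  list(accepted = accepted, rejected = rejected)
}
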