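#' Fold an RNA sequence into its predicted secondary structure
#'
#' Two engines are available. `"vienna"` calls an external Vienna-compatible
#' minimum-free-energy folder (by default the `RNAfold` executable on the
#' PATH) through a one-sequence-in, dot-bracket-plus-energy-out adapter, so
#' any conformant engine can be plugged in. `"fallback"` is a built-in
#' deterministic maximum-base-pairing dynamic program (Watson-Crick and G.U
#' pairs, minimum hairpin size 3; traceback prefers leaving the 3' position
#' unpaired, else pairs it with the smallest admissible partner) and reports
#' pseudo-energy = -(number of pairs). Features computed under different
#' engines are not comparable, so every result carries an engine tag that
#' trained models check at prediction time.
#'
#' @param seq RNA string over \{A, C, G, U, N\}.
#' @param engine `"fallback"` or `"vienna"`.
#' @param min_hairpin Minimum unpaired bases inside a hairpin (fallback only).
#' @param rnafold Path to the RNAfold executable for the vienna engine.
#' @return An object of class `dot_bracket`: list with `seq`, `db`, `mfe`
#'   (kcal/mol for vienna; pseudo-energy for the fallback), `engine`.
#' @examples
#' fold("GGGAAAACCC", engine = "fallback")
#' @export
fold <- function(seq, engine = c("fallback", "vienna"), min_hairpin = 3L,
                 rnafold = Sys.which("RNAfold")) {
  engine <- match.arg(engine)
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 1L || n > 7500L) {
    stop("sequence length must be between 1 and 7500 bases", call. = FALSE)
  }
  ch <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(ch, c("A", "C", "G", "U", "N"))
  if (length(bad) > 0L) {
    stop("sequence must be normalized RNA; invalid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (engine == "fallback") {
    res <- .nussinov_fold(seq, as.integer(min_hairpin))
    out <- list(seq = seq, db = res$db, mfe = -as.numeric(res$pairs),
                engine = "fallback-maxpair")
  } else {
    if (!nzchar(rnafold)) {
      stop("external folding engine (RNAfold) not found on PATH; ",
           "use engine = \"fallback\"", call. = FALSE)
    }
    raw <- system2(rnafold, args = c("--noPS"), input = seq,
                   stdout = TRUE, stderr = FALSE)
    line <- raw[length(raw)]
    m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) != 3L) {
      stop("could not parse folding engine output: ", line, call. = FALSE)
    }
    out <- list(seq = seq, db = m[2], mfe = as.numeric(m[3]),
                engine = "external-mfe")
  }
  if (nchar(out$db) != n) stop("engine returned structure of wrong length",
                               call. = FALSE)
  class(out) <- "dot_bracket"
  out
}

#' @export
print.dot_bracket <- function(x, ...) {
  cat(x$seq, "\n", x$db, sprintf(" (%.2f)", x$mfe), "  [", x$engine, "]\n",
      sep = "")
  invisible(x)
}

#' Pairing table of a dot-bracket string
#'
#' @param db Dot-bracket string over `(`, `)`, `.` (nested, no pseudoknots).
#' @return Integer vector p of length nchar(db), 1-based: `p[i] = j` iff
#'   positions i and j are paired, 0 for unpaired positions.
#' @export
pair_table <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "")[[1]]
  if (length(ch) > 0L && !all(ch %in% c("(", ")", "."))) {
    stop("dot-bracket string may contain only '(', ')' and '.'", call. = FALSE)
  }
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string",
                                    call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string", call. = FALSE)
  p
}

#' Decompose a secondary structure into loop counts
#'
#' Standard nested loop decomposition: for each base pair (i, j), let b be
#' the number of helices directly enclosed by it and u the number of directly
#' accessible unpaired bases. b = 0 is a hairpin loop; b = 1 with u = 0 is a
#' stacked pair and counts as no loop; b = 1 with u >= 1 is an internal loop
#' (bulges included); b >= 2 is a multibranch loop. The external loop counts
#' exactly once when the structure has at least one pair, else zero; a
#' pairless structure has zero loops of every kind. `total` is the sum of
#' the four counts.
#'
#' @param db Dot-bracket string.
#' @return Object of class `loop_counts`: named integer vector with elements
#'   `hairpin`, `external`, `internal`, `multi`, `total`.
#' @examples
#' decompose_loops("((((...))))")  # 1 hairpin, 1 external, total 2
#' @export
decompose_loops <- function(db) {
  p <- pair_table(db)
  n <- length(p)
  counts <- c(hairpin = 0L, external = 0L, internal = 0L, multi = 0L)
  if (any(p > 0L)) counts["external"] <- 1L
  # walk each pair's accessible interior
  i <- 1L
  opens <- which(p > seq_len(n))   # 5' partner of every pair
  for (i in opens) {
    j <- p[i]
    u <- 0L
    b <- 0L
    k <- i + 1L
    while (k < j) {
      if (p[k] == 0L) {
        u <- u + 1L
        k <- k + 1L
      } else {
        b <- b + 1L
        k <- p[k] + 1L   # skip the enclosed helix
      }
    }
    if (b == 0L) {
      counts["hairpin"] <- counts["hairpin"] + 1L
    } else if (b == 1L && u >= 1L) {
      counts["internal"] <- counts["internal"] + 1L
    } else if (b >= 2L) {
      counts["multi"] <- counts["multi"] + 1L
    }                                   # b == 1, u == 0: stacked pair
  }
  out <- c(counts, total = sum(counts))
  class(out) <- c("loop_counts", class(out))
  out
}

#' @export
print.loop_counts <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Count AUG trinucleotides in an RNA sequence
#'
#' Every AUG in a submitted 5'UTR lies upstream of the main start codon, so
#' all occurrences are counted, at any offset and in any frame. Windows
#' containing N never match.
#'
#' @param seq Normalized RNA string.
#' @return Integer count.
#' @examples
#' count_uaugs("AUGAUG")    # 2
#' count_uaugs("AAUGGAUGC") # 2
#' @export
count_uaugs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 3L) return(0L)
  hits <- gregexpr("(?=AUG)", seq, perl = TRUE)[[1]]
  sum(hits > 0L)
}
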