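# Independent oracles used to cross-check the implementation.

# Brute-force loop enumeration from the pair table: for every pair (i, j),
# find its direct children by quadratic set scanning (a pair (k, l) is a
# direct child iff it lies inside (i, j) and inside no other pair that is
# itself inside (i, j)), count directly accessible unpaired bases, and
# classify. Deliberately a different route from the package's linear
# interior walk.
oracle_loop_counts <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  # build pair list with a stack (shared primitive, trivially correct)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  np <- nrow(pairs)
  counts <- c(hairpin = 0L, external = as.integer(np > 0L),
              internal = 0L, multi = 0L)
  inside <- function(inner, outer) {
    outer[1] < inner[1] && inner[2] < outer[2]
  }
  paired_pos <- as.vector(pairs)
  for (a in seq_len(np)) {
    ij <- pairs[a, ]
    kids <- integer(0)
    for (b in seq_len(np)) {
      if (b == a || !inside(pairs[b, ], ij)) next
      shadowed <- FALSE
      for (c_ in seq_len(np)) {
        if (c_ == a || c_ == b) next
        if (inside(pairs[c_, ], ij) && inside(pairs[b, ], pairs[c_, ])) {
          shadowed <- TRUE
          break
        }
      }
      if (!shadowed) kids <- c(kids, b)
    }
    interior <- setdiff(seq(ij[1] + 1L, length.out = max(0L, ij[2] - ij[1] - 1L)),
                        integer(0))
    for (b in kids) {
      interior <- setdiff(interior, pairs[b, 1]:pairs[b, 2])
    }
    u <- sum(!(interior %in% paired_pos))
    bnum <- length(kids)
    if (bnum == 0L) counts["hairpin"] <- counts["hairpin"] + 1L
    else if (bnum == 1L && u >= 1L) counts["internal"] <- counts["internal"] + 1L
    else if (bnum >= 2L) counts["multi"] <- counts["multi"] + 1L
  }
  c(counts, total = sum(counts))
}

# All balanced dot-bracket strings of length n (Motzkin words).
all_dotbrackets <- local({
  memo <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 0L) {
      ""
    } else {
      res <- paste0(".", all_dotbrackets(n - 1L))
      if (n >= 2L) for (k in 0:(n - 2L)) {
        res <- c(res, as.vector(outer(paste0("(", all_dotbrackets(k), ")"),
                                      all_dotbrackets(n - 2L - k), paste0)))
      }
      res
    }
    memo[[key]] <<- out
    out
  }
})

# Metric oracle: rebuild the labeled pairs from the confusion counts and
# measure each quantity by direct counting; MCC as the Pearson correlation
# of the two indicator vectors.
oracle_metrics <- function(tp, tn, fp, fn) {
  y_true <- rep(c("IP", "IN", "IN", "IP"), c(tp, tn, fp, fn))
  y_pred <- rep(c("IP", "IN", "IP", "IN"), c(tp, tn, fp, fn))
  pt <- y_true == "IP"
  pp <- y_pred == "IP"
  list(
    accuracy = 100 * mean(y_true == y_pred),
    sensitivity = if (any(pt)) 100 * mean(pp[pt]) else NA_real_,
    specificity = if (any(!pt)) 100 * mean(!pp[!pt]) else NA_real_,
    precision = if (any(pp)) 100 * mean(pt[pp]) else NA_real_,
    mcc = if (isTRUE(stats::var(pt) > 0) && isTRUE(stats::var(pp) > 0)) {
      stats::cor(as.numeric(pt), as.numeric(pp))
    } else NA_real_
  )
}

# Exhaustive enumeration of all nested pairings (min hairpin h) for tiny
# sequences: independent check of the fallback folding engine's optimum.
oracle_max_pairs <- function(seq, h = 3L) {
  ch <- strsplit(seq, "")[[1]]
  can <- function(a, b) {
    p <- paste0(min(ch[a], ch[b]), max(ch[a], ch[b]))
    p %in% c("AU", "CG", "GU")
  }
  rec <- function(i, j) {
    if (j - i < h + 1L) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - h - 1L)) {
      if (!can(k, j)) next
      left <- if (k > i) rec(i, k - 1L) else 0L
      best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
    }
    best
  }
  rec(1L, length(ch))
}
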