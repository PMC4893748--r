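# Shared small fixtures, built once per test run.

fx <- local({
  env <- new.env()
  function(name) {
    if (!exists(name, envir = env, inherits = FALSE)) {
      val <- switch(name,
        panel = load_ssrp_panel(),
        pairs = generate_interaction_pairs(220, seed = 7),
        rpi = train_interaction_model(fx("pairs"), ntree = 80, seed = 7),
        utrs = generate_labeled_utrs(synthetic_spec(
          n_pos = 8, n_neg = 8, len_range_pos = c(60, 160),
          len_range_neg = c(40, 120), seed = 11)),
        X = extract_feature_matrix(fx("utrs"), fx("panel"), fx("rpi"),
                                   engine = "fallback"),
        stop("unknown fixture: ", name)
      )
      assign(name, val, envir = env)
    }
    get(name, envir = env, inherits = FALSE)
  }
})

write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("seqs", tmpdir = dir, fileext = ".fasta")
  write_fasta(records, path)
  path
}

write_tmp_labels <- function(records, dir = tempdir()) {
  path <- tempfile("labels", tmpdir = dir, fileext = ".tsv")
  utils::write.table(records[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}
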