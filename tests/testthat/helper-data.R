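# Shared generators and lazily computed heavy fixtures.

r_cdr3 <- function(n, lmin = 8, lmax = 18, prefix = "") {
  lens <- lmin:lmax
  vapply(seq_len(n), function(i) {
    l <- lens[sample.int(length(lens), 1)]
    body <- paste(sample(tcrgmlp:::AA20, max(0, l - nchar(prefix)),
                         replace = TRUE), collapse = "")
    paste0(prefix, body)
  }, character(1))
}

r_pep <- function(n) r_cdr3(n, 9, 9)

# deterministic substitutions: replace each given position with the next
# residue in the alphabet
mutate_seq_at <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    i <- match(ch[p], tcrgmlp:::AA20)
    ch[p] <- tcrgmlp:::AA20[(i %% 20) + 1]
  }
  paste(ch, collapse = "")
}

mutate_seq <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(tcrgmlp:::AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

tiny_cfg <- function(chain_mode = "paired", ...) {
  model_config(d_model = 8L, d_ffn = 12L, n_blocks = 2L, n_heads = 2L,
               head_dim = 4L, max_cdr3 = 6L, pep_len = 4L,
               head_layers = 5L, chain_mode = chain_mode, ...)
}

tiny_records <- function(n, seed = 1, la = c(3, 6), lb = c(4, 6), lp = 4) {
  tcrgmlp:::with_seed(seed, data.frame(
    cdr3a = r_cdr3(n, la[1], la[2]),
    cdr3b = r_cdr3(n, lb[1], lb[2]),
    peptide = r_cdr3(n, lp, lp),
    label = rep_len(c(1L, 0L), n),
    stringsAsFactors = FALSE))
}

# Heavy shared fixtures for the acceptance suite, computed once per session.
.acc <- new.env(parent = emptyenv())

acc_default_dataset <- function() {
  if (is.null(.acc$dataset)) {
    .acc$dataset <- generate_dataset(generator_config(seed = 1L))
  }
  .acc$dataset
}

acc_default_folds <- function() {
  if (is.null(.acc$folded)) {
    .acc$folded <- make_folds(acc_default_dataset()$records, threshold = 0.9,
                              k = 5L, seed = 1L)
  }
  .acc$folded
}

acc_default_experiment <- function() {
  if (is.null(.acc$experiment)) {
    .acc$experiment <- cognate_target_experiment(
      acc_default_folds(), model_config(),
      train_hyper(epochs = 6L, batch_size = 256L, seed = 1L))
  }
  .acc$experiment
}

acc_default_baseline <- function() {
  if (is.null(.acc$baseline)) {
    .acc$baseline <- cross_validate_baseline(acc_default_folds(), paired = TRUE)
  }
  .acc$baseline
}
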