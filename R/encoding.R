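#' BLOSUM50 substitution matrix
#'
#' Loads the BLOSUM50 amino-acid substitution matrix shipped with the package
#' (plain-text, standard NCBI layout) and returns it with rows and columns
#' reordered to the fixed alphabetical one-letter ordering used throughout the
#' package for feature columns.
#'
#' @return An object of class `substitution_matrix`: a list with `alphabet`
#'   (character vector of the 20 canonical one-letter codes, alphabetical) and
#'   `scores` (20 x 20 integer matrix of substitution scores, dimnamed by the
#'   alphabet).
#' @export
#' @examples
#' m <- load_blosum50()
#' m$scores["A", "A"]  # 5
load_blosum50 <- function() {
  if (!is.null(.blosum_cache$m)) return(.blosum_cache$m)
  path <- system.file("extdata", "blosum50.txt", package = "tcrgmlp")
  if (!nzchar(path)) stop("BLOSUM50 resource not found; is the package installed?")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  rows <- lapply(body, function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1L)
  scores <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(scores) <- list(rn, header)
  alphabet <- sort(header)
  scores <- scores[alphabet, alphabet, drop = FALSE]
  stopifnot(
    length(alphabet) == 20L, !anyDuplicated(alphabet),
    isSymmetric(unname(scores)), all(diag(scores) > 0L)
  )
  m <- structure(list(alphabet = alphabet, scores = scores),
                 class = "substitution_matrix")
  .blosum_cache$m <- m
  m
}

.blosum_cache <- new.env(parent = emptyenv())

#' Encode one amino-acid sequence as a BLOSUM50 matrix
#'
#' Each residue becomes the BLOSUM50 row of scores for substituting it with
#' each of the 20 canonical amino acids (columns in alphabetical order), so a
#' length-l sequence yields an l x 20 block. The block is right-padded with
#' all-zero rows up to `max_len`; a logical mask marks the real rows.
#'
#' @param seq Amino-acid string (canonical residues only, upper case).
#' @param max_len Padded length; must be >= nchar(seq).
#' @param matrix A `substitution_matrix`, by default [load_blosum50()].
#' @return An `encoded_sequence`: list with `matrix` (max_len x 20 numeric),
#'   `length` (integer) and `mask` (logical vector of length max_len).
#' @export
encode_sequence <- function(seq, max_len, matrix = load_blosum50()) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq),
            is.numeric(max_len), max_len >= 1)
  n <- nchar(seq)
  if (n > max_len) {
    stop(sprintf("sequence of length %d exceeds max_len %d", n, max_len))
  }
  out <- array(0, dim = c(max_len, 20L),
               dimnames = list(NULL, matrix$alphabet))
  if (n > 0L) {
    chars <- strsplit(seq, "")[[1]]
    idx <- match(chars, matrix$alphabet)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                   chars[bad], bad, seq))
    }
    out[seq_len(n), ] <- matrix$scores[idx, , drop = FALSE]
  }
  structure(list(matrix = out, length = n,
                 mask = seq_len(max_len) <= n),
            class = "encoded_sequence")
}

#' Encode a TCR-peptide pair record
#'
#' Applies [encode_sequence()] to the up-to-three streams of one example
#' (CDR3 alpha, CDR3 beta, peptide). In `beta_only` mode the alpha slot is
#' flagged absent rather than zero-padded; in `paired` mode a missing alpha
#' chain is an error. Peptides must be exactly `pep_len` residues.
#'
#' @param record List or one-row data.frame with `cdr3a` (may be `NA`),
#'   `cdr3b`, `peptide`.
#' @param max_cdr3 Padded CDR3 length (default 18, the upper length filter).
#' @param pep_len Required peptide length (default 9).
#' @param chain_mode One of "paired", "beta_only", "alpha_only".
#' @param matrix A `substitution_matrix`.
#' @return An `encoded_example`: list with `alpha`, `beta`, `peptide` slots
#'   (each an `encoded_sequence` or `NULL` when the stream is absent) and
#'   `chain_mode`.
#' @export
encode_example <- function(record, max_cdr3 = 18L, pep_len = 9L,
                           chain_mode = c("paired", "beta_only", "alpha_only"),
                           matrix = load_blosum50()) {
  chain_mode <- match.arg(chain_mode)
  rec <- as.list(record)
  enc1 <- function(s, max_len, what) {
    tryCatch(encode_sequence(s, max_len, matrix),
             error = function(e) stop(sprintf("%s: %s", what, conditionMessage(e)),
                                      call. = FALSE))
  }
  pep <- as.character(rec$peptide)
  if (is.na(pep) || nchar(pep) != pep_len) {
    stop(sprintf("peptide: length must be exactly %d, got %d",
                 pep_len, if (is.na(pep)) 0L else nchar(pep)))
  }
  alpha <- NULL
  beta <- NULL
  has_a <- !is.null(rec$cdr3a) && !is.na(rec$cdr3a) && nzchar(rec$cdr3a)
  if (chain_mode %in% c("paired", "alpha_only")) {
    if (!has_a) stop("cdr3a: stream required by chain_mode but absent")
    alpha <- enc1(as.character(rec$cdr3a), max_cdr3, "cdr3a")
  }
  if (chain_mode %in% c("paired", "beta_only")) {
    b <- as.character(rec$cdr3b)
    if (is.null(rec$cdr3b) || is.na(b) || !nzchar(b)) {
      stop("cdr3b: stream required by chain_mode but absent")
    }
    beta <- enc1(b, max_cdr3, "cdr3b")
  }
  structure(list(alpha = alpha, beta = beta,
                 peptide = enc1(pep, pep_len, "peptide"),
                 chain_mode = chain_mode),
            class = "encoded_example")
}

# Batched encoding: stack sequences into a (n*max_len) x 20 matrix with token
# index varying fastest (rows 1..max_len are example 1, etc.). Padding rows are
# zero. Used by the model's batched forward pass.
encode_batch <- function(seqs, max_len, matrix = load_blosum50()) {
  n <- length(seqs)
  lens <- nchar(seqs)
  if (any(lens > max_len)) {
    stop(sprintf("sequence longer than max_len %d", max_len))
  }
  chars <- strsplit(paste0(seqs, collapse = ""), "")[[1]]
  idx <- match(chars, matrix$alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("non-canonical residue '%s' in batch", chars[bad]))
  }
  X <- base::matrix(0, nrow = n * max_len, ncol = 20L)
  tok <- sequence(lens)                       # position within each sequence
  ex <- rep.int(seq_len(n), lens)             # owning example
  rows <- (ex - 1L) * max_len + tok
  X[rows, ] <- matrix$scores[idx, , drop = FALSE]
  mask <- rep(rep(c(TRUE, FALSE), n), times = as.vector(rbind(lens, max_len - lens)))
  list(x = X, mask = mask, lengths = lens)
}
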