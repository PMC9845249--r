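# Sequence-similarity baseline: a query TCR's score for a peptide is its best
# kernel similarity to the known positive TCRs of that peptide.

kmer_odds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- load_blosum50()
      # BLOSUM log-odds (half-bit units) mapped back to odds-ratio space so
      # k-mer scores are strictly positive and self-similarity is maximal
      cache <<- list(alphabet = m$alphabet, odds = 2^(m$scores / 2))
    }
    cache
  }
})

kernel_raw <- function(ia, ib, odds, k) {
  E <- odds[ia, ib, drop = FALSE]
  mu <- length(ia) - k + 1L
  mv <- length(ib) - k + 1L
  C <- E[seq_len(mu), seq_len(mv), drop = FALSE]
  for (i in seq_len(k - 1L)) {
    C <- C * E[i + seq_len(mu), i + seq_len(mv), drop = FALSE]
  }
  sum(C)
}

seq_index <- function(s, alphabet) {
  idx <- match(strsplit(s, "")[[1]], alphabet)
  if (anyNA(idx)) stop(sprintf("non-canonical residue in '%s'", s))
  idx
}

#' BLOSUM50 k-mer string kernel
#'
#' Alignment-free similarity: every k-mer of `a` is compared with every k-mer
#' of `b`, scoring a k-mer pair as the product over positions of the BLOSUM50
#' odds ratio 2^(s/2) (the substitution matrix mapped out of log space, so
#' scores are positive and maximal for identities). The raw kernel is the sum
#' over all k-mer pairs, reported normalized as K(a,b)/sqrt(K(a,a) K(b,b)),
#' hence 1 for identical sequences and symmetric.
#'
#' @param a,b Amino-acid strings of length >= k.
#' @param k k-mer length (default 3).
#' @return Normalized kernel similarity in (0, 1] for canonical sequences.
#' @export
kernel_similarity <- function(a, b, k = 3L) {
  if (nchar(a) < k || nchar(b) < k) {
    stop(sprintf("sequences must be at least k = %d residues long", k))
  }
  km <- kmer_odds()
  ia <- seq_index(a, km$alphabet)
  ib <- seq_index(b, km$alphabet)
  kernel_raw(ia, ib, km$odds, k) /
    sqrt(kernel_raw(ia, ia, km$odds, k) * kernel_raw(ib, ib, km$odds, k))
}

#' Build a positive TCR database
#'
#' Groups the positive records by peptide, dropping duplicate TCRs per
#' peptide. Used as the reference set of the similarity baseline; in
#' cross-validation the database is built from training folds only.
#'
#' @param positives Data frame of label-1 pair records.
#' @param paired Keep alpha chains (requires complete `cdr3a`).
#' @return A `positive_database`: peptide-named list of data frames with
#'   `cdr3b` (and `cdr3a` when paired).
#' @export
build_positive_database <- function(positives, paired = FALSE) {
  positives <- as.data.frame(positives)
  stopifnot(all(positives$label == 1L))
  cols <- if (paired) c("cdr3a", "cdr3b") else "cdr3b"
  if (paired && anyNA(positives$cdr3a)) {
    stop("paired database requires complete cdr3a")
  }
  db <- lapply(split(positives[cols], positives$peptide), function(d) {
    unique(d)
  })
  structure(db, class = "positive_database", paired = paired)
}

db_entries <- function(db, peptide) {
  if (!peptide %in% names(db)) {
    stop(sprintf("unknown peptide '%s'; database covers: %s",
                 peptide, paste(names(db), collapse = ", ")))
  }
  entries <- db[[peptide]]
  if (nrow(entries) == 0L) stop(sprintf("empty database for peptide '%s'", peptide))
  entries
}

#' Similarity score of a query TCR for a peptide
#'
#' The maximum kernel similarity between the query CDR3 beta and the positive
#' CDR3 beta database of the peptide.
#'
#' @param query_cdr3b Query beta chain.
#' @param db A `positive_database`.
#' @param peptide Target peptide (must be in the database).
#' @param k k-mer length.
#' @return Best-match similarity score.
#' @export
similarity_score <- function(query_cdr3b, db, peptide, k = 3L) {
  entries <- db_entries(db, peptide)
  max(vapply(entries$cdr3b, kernel_similarity, numeric(1), a = query_cdr3b, k = k))
}

#' Paired-chain similarity score
#'
#' For each database TCR the alpha and beta kernel similarities to the query
#' are averaged; the score is the best average over database TCRs
#' (max-of-averages, keeping the two chains of a database TCR together).
#'
#' @param query_cdr3a,query_cdr3b Query chains.
#' @inheritParams similarity_score
#' @export
paired_similarity_score <- function(query_cdr3a, query_cdr3b, db, peptide,
                                    k = 3L) {
  if (!isTRUE(attr(db, "paired"))) stop("database was not built with paired = TRUE")
  entries <- db_entries(db, peptide)
  sa <- vapply(entries$cdr3a, kernel_similarity, numeric(1), a = query_cdr3a, k = k)
  sb <- vapply(entries$cdr3b, kernel_similarity, numeric(1), a = query_cdr3b, k = k)
  max((sa + sb) / 2)
}

#' Score records with the similarity baseline
#'
#' @param records Query records (`cdr3b`, `peptide`, and `cdr3a` if paired).
#' @param db A `positive_database`.
#' @param paired Average alpha and beta chain scores.
#' @param k k-mer length.
#' @return Numeric score per record.
#' @export
baseline_scores <- function(records, db, paired = isTRUE(attr(db, "paired")),
                            k = 3L) {
  records <- as.data.frame(records)
  vapply(seq_len(nrow(records)), function(i) {
    if (paired) {
      paired_similarity_score(records$cdr3a[i], records$cdr3b[i], db,
                              records$peptide[i], k)
    } else {
      similarity_score(records$cdr3b[i], db, records$peptide[i], k)
    }
  }, numeric(1))
}

# --- fast vectorized scoring -------------------------------------------------
# All database chains of one kind are concatenated into a single residue-index
# vector; one odds-matrix lookup plus k-1 shifted elementwise products then
# yields every query-kmer x database-kmer score at once, and per-entry raw
# kernels fall out of a grouped column sum (windows crossing entry boundaries
# are excluded). Identical results to kernel_similarity(), checked in tests.

chain_precompute <- function(seqs, odds, alphabet, k) {
  enc <- lapply(seqs, seq_index, alphabet = alphabet)
  lens <- lengths(enc)
  if (any(lens < k)) stop(sprintf("database sequence shorter than k = %d", k))
  cat_idx <- unlist(enc, use.names = FALSE)
  N <- length(cat_idx)
  col_entry <- rep.int(seq_along(enc), lens)[seq_len(N - k + 1L)]
  ends <- cumsum(lens)
  valid <- (seq_len(N - k + 1L) + k - 1L) <= ends[col_entry]
  self <- vapply(enc, function(ia) kernel_raw(ia, ia, odds, k), numeric(1))
  list(cat_idx = cat_idx, col_entry = col_entry, valid = valid, self = self,
       n = length(enc))
}

query_raw_kernels <- function(ia, pre, odds, k) {
  la <- length(ia)
  if (la < k) stop(sprintf("query shorter than k = %d", k))
  E <- odds[ia, pre$cat_idx, drop = FALSE]
  mu <- la - k + 1L
  mv <- length(pre$cat_idx) - k + 1L
  C <- E[seq_len(mu), seq_len(mv), drop = FALSE]
  for (i in seq_len(k - 1L)) {
    C <- C * E[i + seq_len(mu), i + seq_len(mv), drop = FALSE]
  }
  cs <- if (mu == 1L) as.vector(C) else colSums(C)
  raw <- numeric(pre$n)
  gs <- rowsum(cs[pre$valid], pre$col_entry[pre$valid])
  raw[as.integer(rownames(gs))] <- gs
  raw
}

#' Cross-validated baseline scoring
#'
#' For each fold, the positives of the other folds define the database and the
#' fold's records are scored against it, so a query never meets itself. Scores
#' equal [similarity_score()] / [paired_similarity_score()] per record but are
#' computed by a vectorized kernel path.
#'
#' @param records Fold-annotated records (from [make_folds()]).
#' @param paired Use paired-chain averaging.
#' @param k k-mer length.
#' @return `records` with an added `score` column.
#' @export
cross_validate_baseline <- function(records, paired = FALSE, k = 3L) {
  records <- as.data.frame(records)
  stopifnot("fold" %in% names(records))
  km <- kmer_odds()
  records$score <- NA_real_
  for (f in sort(unique(records$fold))) {
    test <- which(records$fold == f)
    pos <- records[-test, , drop = FALSE]
    pos <- pos[pos$label == 1L, , drop = FALSE]
    cols <- if (paired) c("cdr3a", "cdr3b") else "cdr3b"
    entries <- unique(pos[c("peptide", cols)])
    entries <- entries[order(entries$peptide), , drop = FALSE]
    known <- unique(records$peptide[test])
    if (!all(known %in% entries$peptide)) {
      stop(sprintf("fold %d: peptide(s) absent from training database: %s", f,
                   paste(setdiff(known, entries$peptide), collapse = ", ")))
    }
    pre_b <- chain_precompute(entries$cdr3b, km$odds, km$alphabet, k)
    pre_a <- if (paired) chain_precompute(entries$cdr3a, km$odds, km$alphabet, k)
    pep_groups <- split(seq_len(nrow(entries)), entries$peptide)

    # score each distinct test TCR once against the whole database
    qkey <- tcr_key(records[test, , drop = FALSE])
    for (uk in unique(qkey)) {
      rows <- test[qkey == uk]
      r1 <- rows[1]
      ib <- seq_index(records$cdr3b[r1], km$alphabet)
      nb <- query_raw_kernels(ib, pre_b, km$odds, k) /
        sqrt(kernel_raw(ib, ib, km$odds, k) * pre_b$self)
      sim <- if (paired) {
        ia <- seq_index(records$cdr3a[r1], km$alphabet)
        na_ <- query_raw_kernels(ia, pre_a, km$odds, k) /
          sqrt(kernel_raw(ia, ia, km$odds, k) * pre_a$self)
        (nb + na_) / 2
      } else nb
      for (r in rows) {
        records$score[r] <- max(sim[pep_groups[[records$peptide[r]]]])
      }
    }
  }
  records
}
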