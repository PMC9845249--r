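#' Read a TCR-peptide pair table
#'
#' Reads a delimited file with header columns `cdr3b`, `peptide`, `label`
#' (required) and `cdr3a`, `source` (optional). Sequences are upper-cased;
#' labels must parse to 0/1. Line numbers refer to the file (header = line 1).
#'
#' @param path File path.
#' @param delimiter Field delimiter; default `","`, use `"\t"` for TSV.
#' @return Data frame of validated pair records with a `line` column.
#' @export
read_pairs <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  required <- c("cdr3b", "peptide", "label")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  df$line <- seq_len(nrow(df)) + 1L
  bad <- which(!df$label %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("malformed label '%s' at line %d (expected 0 or 1)",
                 df$label[bad[1]], df$line[bad[1]]))
  }
  df$label <- as.integer(df$label)
  df$cdr3b <- toupper(trimws(df$cdr3b))
  df$peptide <- toupper(trimws(df$peptide))
  if ("cdr3a" %in% names(df)) {
    df$cdr3a <- toupper(trimws(df$cdr3a))
    df$cdr3a[df$cdr3a == ""] <- NA_character_
  } else {
    df$cdr3a <- NA_character_
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  keep <- c("cdr3a", "cdr3b", "peptide", "label", "source", "line")
  # fold-annotated files round-trip their partition columns
  for (extra in c("cluster", "fold")) {
    if (extra %in% names(df)) {
      df[[extra]] <- as.integer(df[[extra]])
      keep <- c(keep, extra)
    }
  }
  df[keep]
}

#' Length-filter pair records
#'
#' Keeps records whose CDR3 sequences (beta, and alpha when present) are 8-18
#' residues long and whose peptide is exactly 9 residues, the filters applied
#' to the study data. Rejections carry machine-readable reasons.
#'
#' @param records Pair record data frame.
#' @param cdr3_range Length 2 vector of inclusive CDR3 length bounds.
#' @param pep_len Required peptide length.
#' @return List with `kept` (data frame) and `rejected` (data frame with an
#'   added `reason` column; one row per record, first failing rule wins).
#' @export
filter_records <- function(records, cdr3_range = c(8L, 18L), pep_len = 9L) {
  records <- as.data.frame(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  len_reason <- function(len, current) {
    r <- current
    r[is.na(r) & len < cdr3_range[1]] <- "cdr3_too_short"
    r[is.na(r) & len > cdr3_range[2]] <- "cdr3_too_long"
    r
  }
  reason <- len_reason(nchar(records$cdr3b), reason)
  if ("cdr3a" %in% names(records)) {
    has_a <- !is.na(records$cdr3a)
    la <- ifelse(has_a, nchar(records$cdr3a), cdr3_range[1])
    reason <- len_reason(la, reason)
  }
  reason[is.na(reason) & nchar(records$peptide) != pep_len] <- "peptide_length"
  list(kept = records[is.na(reason), , drop = FALSE],
       rejected = cbind(records[!is.na(reason), , drop = FALSE],
                        reason = reason[!is.na(reason)]))
}

#' Generate negative pairs by cognate-target mispairing
#'
#' Builds the peptide target list from the positives with multiplicity (a
#' peptide bound by many TCRs appears many times), then pairs each positive
#' TCR with `ratio` peptides drawn from that list excluding the TCR's own
#' cognate target(s). Generated negatives therefore share the TCR sequence
#' distribution of the positives and can never duplicate a positive pair.
#' Duplicate positive (TCR, peptide) records are collapsed first, keeping the
#' first source tag.
#'
#' @param positives Data frame of label-1 pair records.
#' @param ratio Negatives per positive TCR.
#' @param seed Integer seed; draws are reproducible.
#' @return List with `negatives` (label-0 data frame) and `report` (counts,
#'   including TCRs skipped because their cognate set covers every peptide).
#' @export
generate_negatives <- function(positives, ratio = 5L, seed = 1L) {
  positives <- as.data.frame(positives)
  stopifnot(all(positives$label == 1L))
  key <- paste(tcr_key(positives), positives$peptide)
  positives <- positives[!duplicated(key), , drop = FALSE]
  pep_list <- positives$peptide          # with multiplicity, after dedup
  if (length(unique(pep_list)) < 2L) {
    stop("negative generation needs at least 2 distinct peptides among the positives")
  }
  keys <- tcr_key(positives)
  tcr_first <- !duplicated(keys)
  cognates <- split(positives$peptide, keys)
  skipped <- character()
  neg <- vector("list", sum(tcr_first))
  with_seed(seed, {
    ii <- 0L
    for (i in which(tcr_first)) {
      k <- keys[i]
      pool <- pep_list[!pep_list %in% cognates[[k]]]
      if (length(pool) == 0L) {
        skipped <- c(skipped, k)
        next
      }
      draw <- sample(pool, ratio, replace = TRUE)
      ii <- ii + 1L
      neg[[ii]] <- data.frame(cdr3a = positives$cdr3a[i],
                              cdr3b = positives$cdr3b[i],
                              peptide = draw, label = 0L,
                              source = "mispaired",
                              stringsAsFactors = FALSE)
    }
    neg <- neg[seq_len(ii)]
  })
  if (length(skipped)) {
    warning(sprintf("%d TCR(s) skipped: cognate set covers all peptides",
                    length(skipped)))
  }
  negatives <- do.call(rbind, neg)
  list(negatives = negatives,
       report = list(n_positive_records = nrow(positives),
                     n_tcrs = sum(tcr_first),
                     n_skipped = length(skipped),
                     skipped_tcrs = skipped,
                     n_negatives = if (is.null(negatives)) 0L else nrow(negatives)))
}

#' Global-alignment sequence identity
#'
#' Fraction of identical positions over the global (Needleman-Wunsch)
#' alignment length, aligning with BLOSUM50 scores and affine gap penalties
#' (open 10, extend 1). Symmetric in its arguments.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  identity_to_many(a, b)[1]
}

# Identity of one subject against many patterns in a single alignment call.
# The global alignment length is la + lb - aligned columns, where aligned
# (residue-residue) columns are nmatch + nmismatch; this avoids materializing
# gapped alignment strings.
identity_to_many <- function(subject, patterns) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = "BLOSUM50", gapOpening = 10, gapExtension = 1,
    type = "global")
  nm <- Biostrings::nmatch(aln)
  alen <- nchar(patterns) + nchar(subject) - (nm + Biostrings::nmismatch(aln))
  nm / alen
}

#' Cluster TCRs by sequence identity
#'
#' Single-linkage clustering: two TCRs are connected when their identity
#' exceeds `threshold` (for paired chains, when the mean of the alpha and beta
#' identities exceeds it); clusters are the connected components of that
#' graph, so no two TCRs in different clusters can exceed the threshold.
#'
#' @param tcrs Data frame with `cdr3b` and optionally `cdr3a` (one row per
#'   distinct TCR), or a character vector of beta chains.
#' @param threshold Identity threshold in (0, 1); the study presets are 0.90,
#'   0.92, 0.94, 0.95, 0.99 and 1.00.
#' @return Integer cluster id per TCR.
#' @export
cluster_by_identity <- function(tcrs, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1 || threshold == 1)
  if (is.character(tcrs)) tcrs <- data.frame(cdr3b = tcrs)
  n <- nrow(tcrs)
  paired <- "cdr3a" %in% names(tcrs) && !anyNA(tcrs$cdr3a)
  if (paired) {
    # mean identity > t requires at least one chain's bound to allow it;
    # compute both chains' edges at the loosest useful bound, then average
    eb <- identity_matrix_sparse(tcrs$cdr3b, 2 * threshold - 1)
    ea <- identity_matrix_sparse(tcrs$cdr3a, 2 * threshold - 1)
    key <- function(e) paste(e$from, e$to)
    allk <- union(key(ea), key(eb))
    ia <- stats::setNames(ea$identity, key(ea))
    ib <- stats::setNames(eb$identity, key(eb))
    mean_id <- (ifelse(allk %in% names(ia), ia[allk], 0) +
                ifelse(allk %in% names(ib), ib[allk], 0)) / 2
    hit <- mean_id > threshold
    parts <- strsplit(allk[hit], " ")
    edges <- data.frame(from = as.integer(vapply(parts, `[`, "", 1L)),
                        to = as.integer(vapply(parts, `[`, "", 2L)))
  } else {
    edges <- identity_matrix_sparse(tcrs$cdr3b, threshold)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  as.integer(igraph::components(g)$membership)
}

# Sparse pairwise identities above a lower bound. Two exact prunes avoid
# aligning pairs that cannot reach the bound: (1) matches <= min(len) while a
# global alignment has >= max(len) columns, so identity <= min/max length;
# (2) identical aligned columns form a common subsequence, so identity > t
# implies LCS > t * max(len) and hence Levenshtein distance (utils::adist)
# < la + lb - 2 * t * max(la, lb). Unrelated CDR3s fail (2) almost always;
# near-duplicates survive and are aligned. For paired-chain averaging the
# bound passed in is 2*threshold - 1: a chain below that cannot lift the mean
# above threshold even when the other chain is identical.
identity_matrix_sparse <- function(seqs, floor_bound) {
  floor_bound <- max(floor_bound, 0)
  n <- length(seqs)
  lens <- nchar(seqs)
  cfrom <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    cand <- j[pmin(lens[i], lens[j]) / pmax(lens[i], lens[j]) > floor_bound]
    if (!length(cand)) next
    lev <- drop(utils::adist(seqs[i], seqs[cand]))
    cand <- cand[lev < lens[i] + lens[cand] -
                   2 * floor_bound * pmax(lens[i], lens[cand])]
    if (length(cand)) cfrom[[i]] <- cand
  }
  from <- rep.int(seq_len(n), lengths(cfrom))
  to <- unlist(cfrom, use.names = FALSE)
  if (!length(from)) {
    return(data.frame(from = integer(), to = integer(), identity = numeric()))
  }
  # all surviving pairs aligned in one elementwise call
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs[from]), Biostrings::AAStringSet(seqs[to]),
    substitutionMatrix = "BLOSUM50", gapOpening = 10, gapExtension = 1,
    type = "global")
  nm <- Biostrings::nmatch(aln)
  alen <- lens[from] + lens[to] - (nm + Biostrings::nmismatch(aln))
  ids <- nm / alen
  hit <- ids > floor_bound
  data.frame(from = from[hit], to = to[hit], identity = ids[hit])
}

#' Assign identity clusters to cross-validation folds
#'
#' Clusters are shuffled (seeded), sorted by decreasing size, and each is
#' greedily placed on the currently smallest fold, so all members of a cluster
#' share a fold and fold sizes differ by at most the largest cluster size.
#'
#' @param clusters Integer cluster id per TCR (from [cluster_by_identity()]).
#' @param k Number of folds.
#' @param seed Integer seed for tie shuffling.
#' @return A `fold_assignment`: list with `fold` (0-based fold per TCR),
#'   `cluster` (the input ids), `k`.
#' @export
assign_folds <- function(clusters, k = 5L, seed = 1L) {
  ids <- unique(clusters)
  if (length(ids) < k) {
    stop(sprintf("only %d clusters for %d folds; use a lower k",
                 length(ids), k))
  }
  sizes <- table(clusters)[as.character(ids)]
  ord <- with_seed(seed, sample(seq_along(ids)))
  ids <- ids[ord]; sizes <- as.integer(sizes[ord])
  ids <- ids[order(-sizes)]; sizes <- sizes[order(-sizes)]
  fold_of <- integer(length(ids))
  load <- integer(k)
  for (i in seq_along(ids)) {
    f <- which.min(load)
    fold_of[i] <- f - 1L
    load[f] <- load[f] + sizes[i]
  }
  structure(list(fold = fold_of[match(clusters, ids)],
                 cluster = clusters, k = as.integer(k)),
            class = "fold_assignment")
}

#' Build leakage-safe folds for a record table
#'
#' Convenience wrapper: dedupes TCRs, clusters them at `threshold`
#' ([cluster_by_identity()]), assigns clusters to `k` folds
#' ([assign_folds()]), and annotates every record with its TCR's `cluster`
#' and `fold`.
#'
#' @inheritParams cluster_by_identity
#' @inheritParams assign_folds
#' @param records Pair record data frame.
#' @return The records with added `cluster` and `fold` columns.
#' @export
make_folds <- function(records, threshold = 0.9, k = 5L, seed = 1L) {
  records <- as.data.frame(records)
  keys <- tcr_key(records)
  first <- !duplicated(keys)
  tcrs <- records[first, c("cdr3a", "cdr3b"), drop = FALSE]
  if (anyNA(tcrs$cdr3a)) tcrs$cdr3a <- NULL
  cl <- cluster_by_identity(tcrs, threshold)
  fa <- assign_folds(cl, k, seed)
  m <- match(keys, keys[first])
  records$cluster <- fa$cluster[m]
  records$fold <- fa$fold[m]
  records
}

#' Write fold-annotated records and a pipeline report
#'
#' @param records Fold-annotated record data frame (from [make_folds()]).
#' @param path Output CSV path.
#' @param report Optional list (e.g. filtering/negative reports) written as
#'   JSON next to `path` with extension `.report.json`.
#' @export
write_pairs <- function(records, path, report = NULL) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(report)) {
    jsonlite::write_json(report, sub("\\.csv$", ".report.json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
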