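#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the probability that a random
#' positive outscores a random negative, with half credit for ties (average
#' ranks).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC is undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Per-peptide AUC
#'
#' AUC restricted to the records of each peptide. Peptides with a single
#' class are reported as `NA` (undefined), not dropped.
#'
#' @param scores,labels As in [roc_auc()].
#' @param peptides Peptide per record.
#' @return Named numeric vector, one entry per distinct peptide.
#' @export
per_peptide_auc <- function(scores, labels, peptides) {
  vapply(split(seq_along(scores), peptides), function(ix) {
    if (length(unique(labels[ix])) < 2L) return(NA_real_)
    roc_auc(scores[ix], labels[ix])
  }, numeric(1))
}

#' Percentile rank of a score against a background
#'
#' Percentage of background scores strictly greater than `score`, with half
#' credit for ties; lower rank means stronger predicted binding.
#'
#' @param score Scalar score.
#' @param background_scores Non-empty numeric background.
#' @return Rank in \[0, 100\].
#' @export
percentile_rank <- function(score, background_scores) {
  if (length(background_scores) == 0L) stop("background must be non-empty")
  100 * (sum(background_scores > score) +
           0.5 * sum(background_scores == score)) / length(background_scores)
}

#' Cross-validate the gMLP model
#'
#' For each fold: train on the remaining folds and score the held-out fold.
#' Folds come from identity clustering ([make_folds()]), so no test TCR shares
#' a >threshold-identity cluster with any training TCR.
#'
#' @param records Fold-annotated record data frame.
#' @param cfg A `gmlp_config`.
#' @param hyper A `gmlp_hyper`; fold f trains with seed `hyper$seed + f`.
#' @param keep_models Keep the per-fold trained models in the report.
#' @param verbose Print fold progress.
#' @return An `eval_report`: list with `scores` (records + `score`),
#'   `pooled_auc`, `fold_auc`, `per_peptide` (pooled per-peptide AUC),
#'   `counts`, and optionally `models`.
#' @export
cross_validate <- function(records, cfg = model_config(), hyper = train_hyper(),
                           keep_models = FALSE, verbose = FALSE) {
  records <- as.data.frame(records)
  stopifnot("fold" %in% names(records))
  folds <- sort(unique(records$fold))
  if (length(folds) < 2L) stop("need at least 2 folds")
  for (f in folds) {
    if (length(unique(records$label[records$fold == f])) < 2L) {
      stop(sprintf("fold %d has a single class", f))
    }
  }
  records$score <- NA_real_
  models <- list()
  for (f in folds) {
    test <- records$fold == f
    h <- hyper
    h$seed <- derive_seed(hyper$seed, 10L + f)
    fit <- train_gmlp(records[!test, , drop = FALSE], cfg, h)
    records$score[test] <- predict(fit, records[test, , drop = FALSE])
    if (verbose) {
      message(sprintf("fold %d: held-out AUC %.3f", f,
                      roc_auc(records$score[test], records$label[test])))
    }
    if (keep_models) models[[as.character(f)]] <- fit
  }
  fold_auc <- vapply(folds, function(f) {
    ix <- records$fold == f
    roc_auc(records$score[ix], records$label[ix])
  }, numeric(1))
  structure(list(scores = records,
                 pooled_auc = roc_auc(records$score, records$label),
                 fold_auc = stats::setNames(fold_auc, folds),
                 per_peptide = per_peptide_auc(records$score, records$label,
                                               records$peptide),
                 counts = c(n = nrow(records), n_pos = sum(records$label == 1L),
                            k = length(folds)),
                 models = if (keep_models) models),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds, %d records (%d positive)\n",
              x$counts["k"], x$counts["n"], x$counts["n_pos"]))
  cat(sprintf("  pooled AUC %.3f (folds: %s)\n", x$pooled_auc,
              paste(sprintf("%.3f", x$fold_auc), collapse = ", ")))
  pp <- x$per_peptide
  cat("  per peptide:",
      paste(sprintf("%s=%.3f", names(pp), pp), collapse = ", "), "\n")
  invisible(x)
}

#' Predict the cognate target of a TCR
#'
#' Scores the TCR against every candidate peptide, converts each score to a
#' percentile rank against that peptide's background score distribution, and
#' returns the candidate with the lowest rank (strongest predicted binding).
#' Rank ties are broken lexicographically and flagged.
#'
#' @param tcr List or one-row data frame with `cdr3b` (and `cdr3a` in paired
#'   mode).
#' @param candidate_peptides At least two candidate peptides.
#' @param model A trained `gmlp_model`.
#' @param backgrounds Named list: peptide -> numeric vector of model scores of
#'   background TCRs for that peptide (or a record data frame to be scored
#'   with `model`).
#' @return List with `peptide`, `ranks` (named), and `tie` flag.
#' @export
predict_target <- function(tcr, candidate_peptides, model, backgrounds) {
  stopifnot(length(candidate_peptides) >= 2L)
  missing_bg <- setdiff(candidate_peptides, names(backgrounds))
  if (length(missing_bg)) {
    stop(sprintf("missing background for candidate(s): %s",
                 paste(missing_bg, collapse = ", ")))
  }
  tcr <- as.list(tcr)
  qdf <- data.frame(cdr3a = tcr$cdr3a %||% NA_character_,
                    cdr3b = tcr$cdr3b,
                    peptide = candidate_peptides,
                    stringsAsFactors = FALSE)
  s <- predict(model, qdf)
  ranks <- vapply(seq_along(candidate_peptides), function(i) {
    bg <- backgrounds[[candidate_peptides[i]]]
    if (is.data.frame(bg)) bg <- predict(model, bg)
    if (length(bg) == 0L) {
      stop(sprintf("empty background for '%s'", candidate_peptides[i]))
    }
    percentile_rank(s[i], bg)
  }, numeric(1))
  names(ranks) <- candidate_peptides
  best <- sort(candidate_peptides[ranks == min(ranks)])
  list(peptide = best[1], ranks = ranks, tie = length(best) > 1L)
}

#' Fraction of correctly assigned cognate targets
#'
#' @param predicted,truth Character vectors of predicted and true peptides.
#' @return List with `overall` fraction, `per_peptide` fractions (by true
#'   peptide) and `counts`.
#' @export
correct_target_fraction <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0L)
  ok <- predicted == truth
  per <- vapply(split(ok, truth), mean, numeric(1))
  list(overall = mean(ok), per_peptide = per,
       counts = vapply(split(ok, truth), length, integer(1)))
}

#' Cognate-target assignment experiment
#'
#' The rank-based target identification: the model is trained by fold-wise
#' cross-validation; every held-out positive TCR whose true target is among
#' `candidates` is scored against each candidate peptide, scores are turned
#' into percentile ranks against the held-out fold's mispaired-negative score
#' distribution for that peptide, and the lowest-rank candidate is the
#' predicted target. Chance level with three candidates is 1/3.
#'
#' @param records Fold-annotated records.
#' @param cfg,hyper Model configuration and training hyperparameters.
#' @param candidates Candidate peptides; default the three most frequent
#'   positive peptides.
#' @param report Optional precomputed `eval_report` with `models` kept (skips
#'   retraining).
#' @param verbose Print fold progress.
#' @return List with `fraction` (from [correct_target_fraction()]),
#'   `assignments` data frame, `n_ties`, and the `report` used.
#' @export
cognate_target_experiment <- function(records, cfg = model_config(),
                                      hyper = train_hyper(),
                                      candidates = NULL, report = NULL,
                                      verbose = FALSE) {
  records <- as.data.frame(records)
  if (is.null(report)) {
    report <- cross_validate(records, cfg, hyper, keep_models = TRUE,
                             verbose = verbose)
  }
  if (is.null(report$models)) stop("report must be built with keep_models = TRUE")
  scored <- report$scores
  if (is.null(candidates)) {
    tab <- sort(table(scored$peptide[scored$label == 1L]), decreasing = TRUE)
    candidates <- names(tab)[seq_len(min(3L, length(tab)))]
  }
  out <- list()
  n_ties <- 0L
  for (f in sort(unique(scored$fold))) {
    model <- report$models[[as.character(f)]]
    fold_rec <- scored[scored$fold == f, , drop = FALSE]
    backgrounds <- lapply(stats::setNames(nm = candidates), function(p) {
      fold_rec$score[fold_rec$label == 0L & fold_rec$peptide == p]
    })
    if (any(lengths(backgrounds) == 0L)) {
      stop(sprintf("fold %d lacks negative background for some candidate", f))
    }
    pos <- fold_rec[fold_rec$label == 1L & fold_rec$peptide %in% candidates, ,
                    drop = FALSE]
    pos <- pos[!duplicated(tcr_key(pos)), , drop = FALSE]
    if (nrow(pos) == 0L) next
    # score all (TCR, candidate) pairs for this fold in one batch
    qdf <- pos[rep(seq_len(nrow(pos)), each = length(candidates)),
               c("cdr3a", "cdr3b"), drop = FALSE]
    qdf$peptide <- rep(candidates, nrow(pos))
    s <- predict(model, qdf)
    for (i in seq_len(nrow(pos))) {
      si <- s[(i - 1L) * length(candidates) + seq_along(candidates)]
      ranks <- vapply(seq_along(candidates), function(j) {
        percentile_rank(si[j], backgrounds[[candidates[j]]])
      }, numeric(1))
      best <- sort(candidates[ranks == min(ranks)])
      n_ties <- n_ties + (length(best) > 1L)
      out[[length(out) + 1L]] <- data.frame(
        cdr3a = pos$cdr3a[i], cdr3b = pos$cdr3b[i], fold = f,
        true_peptide = pos$peptide[i], predicted_peptide = best[1],
        min_rank = min(ranks), stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, out)
  list(fraction = correct_target_fraction(assignments$predicted_peptide,
                                          assignments$true_peptide),
       assignments = assignments, n_ties = n_ties, candidates = candidates,
       report = report)
}
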