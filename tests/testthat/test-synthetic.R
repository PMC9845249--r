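test_that("motif rules validate their fields", {
  expect_error(motif_rule("SHORT", "WDR"), "nchar")
  expect_error(motif_rule("GILGFVFTL", "WDRKjuuu"), "nchar")
  expect_error(motif_rule("GILGFVFTL", "WDR", mutation_rate = 1.5), "mutation")
  r <- motif_rule("GILGFVFTL", "WDR", "NQY", 0.1)
  expect_s3_class(r, "motif_rule")
})

test_that("sampled CDR3s respect length distribution, anchor and motif placement", {
  ld <- stats::setNames(c(0.2, 0.5, 0.3), c(10, 12, 14))
  tcrgmlp:::with_seed(3, {
    draws <- replicate(4000, tcrgmlp:::sample_cdr3(ld, "WDR", 0,
                                                   anchor = "CASS"),
                       simplify = FALSE)
  })
  lens <- vapply(draws, function(d) nchar(d$seq), numeric(1))
  expect_true(all(lens %in% c(10, 12, 14)))
  # chi-square goodness of fit against the configured distribution
  obs <- table(factor(lens, levels = c(10, 12, 14)))
  p <- suppressWarnings(stats::chisq.test(obs, p = c(0.2, 0.5, 0.3))$p.value)
  expect_gt(p, 1e-4)
  for (d in draws[1:200]) {
    expect_identical(substr(d$seq, 1, 4), "CASS")
    expect_identical(substr(d$seq, d$motif_start, d$motif_start + 2), "WDR")
  }
  # infeasible motif/anchor combination errors after bounded retries
  expect_error(tcrgmlp:::with_seed(1, tcrgmlp:::sample_cdr3(
    stats::setNames(1, 8), "WDRK", 0, anchor = "CASSLG")), "longer")
})

test_that("generated datasets meet the count, filter and determinism contracts", {
  cfg <- generator_config(n_positives = 300L, negative_ratio = 1L, seed = 17)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d$records), 600L)
  expect_equal(unname(table(d$records$label)), c(300L, 300L), ignore_attr = TRUE)
  fr <- filter_records(d$records)
  expect_equal(nrow(fr$kept), nrow(d$records))
  d2 <- generate_dataset(cfg)
  expect_identical(d$records, d2$records)
  expect_identical(d$manifest, d2$manifest)
  # no label leakage through CDR3 length at ratio 1
  poslen <- sort(nchar(d$records$cdr3b[d$records$label == 1L]))
  neglen <- sort(nchar(d$records$cdr3b[d$records$label == 0L]))
  expect_identical(poslen, neglen)
  # abundance skew roughly respected
  tab <- table(d$records$peptide[d$records$label == 1L]) / 300
  expect_gt(tab[["GILGFVFTL"]], 0.5)
  expect_lt(tab[["GLCTLVAML"]], 0.2)
})

test_that("manifest records every planted motif exactly at mutation rate 0", {
  cfg <- generator_config(n_positives = 150L, negative_ratio = 1L, seed = 23)
  d <- generate_dataset(cfg, default_motif_rules(names(cfg$peptide_abundances),
                                                 mutation_rate = 0))
  man <- d$manifest
  for (i in seq_len(nrow(man))) {
    expect_identical(substr(man$cdr3b[i], man$beta_start[i],
                            man$beta_start[i] + nchar(man$beta_motif[i]) - 1L),
                     man$beta_motif[i])
    expect_identical(substr(man$cdr3a[i], man$alpha_start[i],
                            man$alpha_start[i] + nchar(man$alpha_motif[i]) - 1L),
                     man$alpha_motif[i])
  }
  # motif containment separates classes perfectly at zero noise
  rules <- d$rules
  contain <- vapply(seq_len(nrow(d$records)), function(i) {
    r <- rules[[d$records$peptide[i]]]
    as.numeric(grepl(r$beta_motif, d$records$cdr3b[i], fixed = TRUE) &&
                 grepl(r$alpha_motif, d$records$cdr3a[i], fixed = TRUE))
  }, numeric(1))
  expect_equal(roc_auc(contain, d$records$label), 1.0)
  # at mutation rate 1 the motif positions are fully randomized
  dr <- generate_dataset(generator_config(n_positives = 100L,
                                          negative_ratio = 1L, seed = 29),
                         default_motif_rules(names(cfg$peptide_abundances),
                                             mutation_rate = 1))
  verb <- mean(vapply(seq_len(nrow(dr$manifest)), function(i) {
    dr$manifest$beta_realized[i] == dr$manifest$beta_motif[i]
  }, logical(1)))
  expect_lt(verb, 0.05)
})

test_that("the split-signal scenario makes single chains ambiguous but the pair decisive", {
  d <- make_paired_signal_split(mutation_rate = 0, seed = 31)
  rules <- d$rules
  score_joint <- vapply(seq_len(nrow(d$records)), function(i) {
    r <- rules[[d$records$peptide[i]]]
    as.numeric(grepl(r$beta_motif, d$records$cdr3b[i], fixed = TRUE) &&
                 grepl(r$alpha_motif, d$records$cdr3a[i], fixed = TRUE))
  }, numeric(1))
  score_beta <- vapply(seq_len(nrow(d$records)), function(i) {
    r <- rules[[d$records$peptide[i]]]
    as.numeric(grepl(r$beta_motif, d$records$cdr3b[i], fixed = TRUE))
  }, numeric(1))
  score_alpha <- vapply(seq_len(nrow(d$records)), function(i) {
    r <- rules[[d$records$peptide[i]]]
    as.numeric(grepl(r$alpha_motif, d$records$cdr3a[i], fixed = TRUE))
  }, numeric(1))
  y <- d$records$label
  expect_equal(roc_auc(score_joint, y), 1.0)
  expect_lt(roc_auc(score_beta, y), 1.0)
  expect_gt(roc_auc(score_beta, y), 0.5)
  expect_lt(roc_auc(score_alpha, y), 1.0)
  expect_gt(roc_auc(score_alpha, y), 0.5)
})

test_that("datasets write to CSV compatible with read_pairs", {
  d <- generate_dataset(generator_config(n_positives = 30L, negative_ratio = 1L,
                                         seed = 37))
  pairs <- tempfile(fileext = ".csv")
  manifest <- tempfile(fileext = ".json")
  write_dataset(d, pairs, manifest)
  back <- read_pairs(pairs)
  expect_equal(nrow(back), nrow(d$records))
  expect_identical(back$cdr3b, d$records$cdr3b)
  expect_true(file.exists(manifest))
})
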