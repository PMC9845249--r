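write_pairs_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("read_pairs validates, normalizes and reports line numbers", {
  df <- data.frame(cdr3a = c("CAVRDN", "", "CAVKWT"),
                   cdr3b = c("casslgwdrtqy", "CASSHKFEQYF", "CASSYEGNTLYF"),
                   peptide = c("GILGFVFTL", "NLVPMVATV", "GLCTLVAML"),
                   label = c(1, 0, 1))
  got <- read_pairs(write_pairs_csv(df))
  expect_equal(nrow(got), 3L)
  expect_identical(got$cdr3b[1], "CASSLGWDRTQY")
  expect_true(is.na(got$cdr3a[2]))
  expect_identical(got$label, c(1L, 0L, 1L))
  # missing required column
  expect_error(read_pairs(write_pairs_csv(df[, c("cdr3b", "label")])),
               "peptide")
  # malformed label names the line
  bad <- df; bad$label[2] <- "yes"
  expect_error(read_pairs(write_pairs_csv(bad)), "line 3")
  expect_error(read_pairs(tempfile()), "not found")
  # TSV dialect
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(nrow(read_pairs(tsv, delimiter = "\t")), 3L)
})

test_that("length filter applies the 8-18 CDR3 and 9-mer peptide rules", {
  recs <- data.frame(
    cdr3a = NA_character_,
    cdr3b = c("CASSLGW", "CASSLGWDRTQY", strrep("A", 19), "CASSHKFEQYF",
              "CASSLGWDRTQYF"),
    peptide = c("GILGFVFTL", "GILGFVFTL", "GILGFVFTL", "GILGFVFTLX",
                "GILGFVFTL"),
    label = 1L)
  fr <- filter_records(recs)
  expect_equal(nrow(fr$kept), 2L)
  expect_identical(fr$rejected$reason,
                   c("cdr3_too_short", "cdr3_too_long", "peptide_length"))
  # filtering is idempotent
  again <- filter_records(fr$kept)
  expect_identical(again$kept, fr$kept)
  expect_equal(nrow(again$rejected), 0L)
  # alpha chain length is enforced when present
  reca <- data.frame(cdr3a = "CAV", cdr3b = "CASSHKFEQYF",
                     peptide = "GILGFVFTL", label = 1L)
  expect_identical(filter_records(reca)$rejected$reason, "cdr3_too_short")
})

test_that("negative generation excludes cognates and never hits positives", {
  set.seed(3)
  pos <- data.frame(cdr3a = NA_character_, cdr3b = r_cdr3(200, 10, 14),
                    peptide = sample(c("GILGFVFTL", "NLVPMVATV", "GLCTLVAML"),
                                     200, TRUE, prob = c(.6, .3, .1)),
                    label = 1L, source = "x")
  out <- generate_negatives(pos, ratio = 3L, seed = 9)
  neg <- out$negatives
  expect_equal(nrow(neg), 3L * out$report$n_tcrs)
  expect_true(all(neg$label == 0L))
  poskey <- paste(pos$cdr3b, pos$peptide)
  expect_length(intersect(paste(neg$cdr3b, neg$peptide), poskey), 0L)
  # cognate exclusion per TCR
  cog <- split(pos$peptide, pos$cdr3b)
  for (i in sample(nrow(neg), 50)) {
    expect_false(neg$peptide[i] %in% cog[[neg$cdr3b[i]]])
  }
  # determinism
  out2 <- generate_negatives(pos, ratio = 3L, seed = 9)
  expect_identical(out$negatives, out2$negatives)
  expect_false(identical(out$negatives,
                         generate_negatives(pos, ratio = 3L, seed = 10)$negatives))
})

test_that("a TCR with one non-cognate option always receives it", {
  pos <- data.frame(cdr3a = NA_character_,
                    cdr3b = c("CASSAAAAAA", "CASSCCCCCC", "CASSDDDDDD"),
                    peptide = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV"),
                    label = 1L, source = "x")
  out <- generate_negatives(pos, ratio = 2L, seed = 1)
  n1 <- out$negatives[out$negatives$cdr3b == "CASSAAAAAA", ]
  expect_true(all(n1$peptide == "NLVPMVATV"))
  # single-peptide positive set is degenerate
  expect_error(generate_negatives(pos[1:2, ], ratio = 1L),
               "2 distinct peptides")
})

test_that("pairwise identity matches a hand-coded affine-gap aligner", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAC"), 0.75)
  expect_lt(pairwise_identity("CASS", "WGYL"), 0.5)
  expect_error(pairwise_identity("", "AAAA"), "non-empty")
  set.seed(17)
  # substitution-only near-duplicates have a unique gapless optimum
  for (r in 1:10) {
    a <- r_cdr3(1, 10, 16)
    b <- mutate_seq(a, sample(1:3, 1))
    o <- o_align_identity(a, b)
    expect_equal(pairwise_identity(a, b), o$identity, tolerance = 1e-12)
    expect_equal(pairwise_identity(b, a), pairwise_identity(a, b))
  }
  # single-indel pair exercises the gap path
  a <- "CASSLGWDRTQYF"
  b <- "CASSLGWDRTQF"   # one residue removed
  expect_equal(pairwise_identity(a, b), o_align_identity(a, b)$identity)
})

test_that("identity clustering is a single-linkage transitive closure", {
  base <- "CASSLGWDRTQYF"
  A <- base
  B <- mutate_seq_at(base, 6)          # 1 substitution: 12/13 ~ 0.92
  C <- mutate_seq_at(B, 10)            # 1 more: B-C 0.92, A-C ~ 0.85
  expect_gt(pairwise_identity(A, B), 0.9)
  expect_gt(pairwise_identity(B, C), 0.9)
  expect_lt(pairwise_identity(A, C), 0.9)
  cl <- cluster_by_identity(c(A, B, C), threshold = 0.9)
  expect_length(unique(cl), 1L)
  # two identical TCRs cluster together; unrelated ones do not
  set.seed(23)
  others <- r_cdr3(5, 12, 16)
  cl2 <- cluster_by_identity(c(A, A, others), threshold = 0.9)
  expect_identical(cl2[1], cl2[2])
  expect_length(unique(cl2), 6L)
})

test_that("paired-chain clustering uses the mean of alpha and beta identity", {
  b1 <- "CASSLGWDRTQYF"
  a1 <- "CAVRDNGGKLTF"
  # beta identical (1.0), alpha ~0.83 -> mean ~0.92 > 0.9
  tcrs <- data.frame(cdr3a = c(a1, mutate_seq_at(a1, c(5, 8))),
                     cdr3b = c(b1, b1))
  expect_length(unique(cluster_by_identity(tcrs, 0.9)), 1L)
  # both chains ~0.83 -> mean ~0.83 < 0.9
  tcrs2 <- data.frame(cdr3a = c(a1, mutate_seq_at(a1, c(5, 8))),
                      cdr3b = c(b1, mutate_seq_at(b1, c(6, 9))))
  expect_length(unique(cluster_by_identity(tcrs2, 0.9)), 2L)
})

test_that("fold assignment balances greedily and respects clusters", {
  fa <- assign_folds(1:10, k = 5, seed = 1)
  expect_identical(as.integer(table(fa$fold)), rep(2L, 5))
  fa2 <- assign_folds(rep(1:5, c(6, 1, 1, 1, 1)), k = 5, seed = 1)
  big_fold <- fa2$fold[fa2$cluster == 1][1]
  expect_identical(sum(fa2$fold == big_fold), 6L)
  expect_error(assign_folds(rep(1, 4), k = 5), "lower k")
  # balance property: spread bounded by the largest cluster
  set.seed(77)
  for (r in 1:100) {
    sizes <- sample(1:8, sample(6:15, 1), replace = TRUE)
    cl <- rep(seq_along(sizes), sizes)
    fa <- assign_folds(cl, k = 5, seed = r)
    load <- table(factor(fa$fold, levels = 0:4))
    expect_lte(max(load) - min(load), max(sizes))
    # all members of a cluster share a fold
    expect_true(all(vapply(split(fa$fold, fa$cluster),
                           function(f) length(unique(f)) == 1L, logical(1))))
  }
})

test_that("make_folds annotates records consistently and write_pairs round-trips", {
  set.seed(31)
  d <- generate_dataset(generator_config(n_positives = 60L, negative_ratio = 1L,
                                         seed = 13))
  recs <- make_folds(d$records, threshold = 0.9, k = 5, seed = 1)
  expect_true(all(c("cluster", "fold") %in% names(recs)))
  # a TCR's records all share one fold
  expect_true(all(vapply(split(recs$fold, tcrgmlp:::tcr_key(recs)),
                         function(f) length(unique(f)) == 1L, logical(1))))
  path <- tempfile(fileext = ".csv")
  write_pairs(recs, path, report = list(n = nrow(recs)))
  back <- read_pairs(path)
  expect_equal(nrow(back), nrow(recs))
  expect_true(file.exists(sub("\\.csv$", ".report.json", path)))
})
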