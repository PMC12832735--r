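test_that("mean log abundance matches hand-computed values", {
  cm <- toy_counts(c(1, 3, 7,
                     0, 0, 0,
                     9, 9, 9), nrow = 3)
  mu <- log_mean_abundance(cm)
  # (ln2 + ln4 + ln8)/3 = ln 4
  expect_equal(unname(mu$scores["g1"]), log(4))
  expect_equal(unname(mu$scores["g2"]), 0)        # all-zero feature
  expect_identical(mu$n_samples, 3L)

  one <- toy_counts(5, nrow = 1)
  expect_equal(unname(log_mean_abundance(one)$scores), log(6))  # n = 1

  # score >= 0, and zero iff all counts zero
  rc <- random_counts(40, 6, lambda = 2)
  s <- log_mean_abundance(rc)$scores
  expect_true(all(s >= 0))
  expect_identical(unname(s == 0), unname(rowSums(rc$counts) == 0))
})

test_that("sample permutation and library scaling behave as documented", {
  set.seed(11)
  rc <- random_counts(30, 8)
  perm <- rc
  perm$counts <- perm$counts[, sample(ncol(perm$counts))]
  expect_equal(log_mean_abundance(rc)$scores,
               log_mean_abundance(perm)$scores)

  # normalize = TRUE rescales to mean library size; equal libraries no-op
  eq <- count_matrix(matrix(c(1, 1, 4, 4), 2, byrow = TRUE,
                            dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(log_mean_abundance(eq, normalize = TRUE)$scores,
               log_mean_abundance(eq)$scores)
})

test_that("top-K selection obeys size, ordering and tie rules", {
  s <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  expect_identical(top_k_features(s, 3)$feature_id, c("a", "b", "c"))
  # boundary tie broken lexicographically
  s2 <- c(a = 3, c = 2, b = 2, d = 1)
  expect_identical(top_k_features(s2, 2)$feature_id, c("a", "b"))
  # K larger than universe returns everything
  expect_identical(nrow(top_k_features(s, 10)), 5L)
  expect_error(top_k_features(s, 0), ">= 1")
  # scores non-increasing along the list
  tk <- top_k_features(s2, 4)
  expect_true(all(diff(tk$score) <= 0))
})

test_that("top-K matches the exhaustive-sort oracle on small matrices", {
  set.seed(42)
  for (rep in 1:20) {
    nf <- sample(5:50, 1); ns <- sample(1:10, 1)
    cm <- random_counts(nf, ns, lambda = sample(c(1, 5, 50), 1))
    k <- sample(seq_len(nf), 1)
    tk <- top_k_features(log_mean_abundance(cm), k)
    # oracle: exhaustive per-feature mean of logs, full sort
    oracle <- vapply(seq_len(nf), function(g)
      sum(log(cm$counts[g, ] + 1)) / ns, numeric(1))
    names(oracle) <- rownames(cm$counts)
    ord <- names(oracle)[order(-oracle, names(oracle), method = "radix")]
    expect_identical(tk$feature_id, ord[seq_len(k)])
    # every selected score >= every excluded score
    if (k < nf)
      expect_gte(min(tk$score), max(oracle[setdiff(names(oracle),
                                                   tk$feature_id)]))
  }
})

test_that("ranking is invariant to log base and monotone in counts", {
  set.seed(7)
  for (rep in 1:10) {
    cm <- random_counts(40, 5)
    ids_e <- top_k_features(log_mean_abundance(cm, base = exp(1)),
                            10)$feature_id
    ids_2 <- top_k_features(log_mean_abundance(cm, base = 2),
                            10)$feature_id
    ids_10 <- top_k_features(log_mean_abundance(cm, base = 10),
                             10)$feature_id
    expect_identical(ids_e, ids_2)
    expect_identical(ids_e, ids_10)

    # boosting one feature's counts never lowers its rank
    f <- sample(rownames(cm$counts), 1)
    before <- rank(-log_mean_abundance(cm)$scores,
                   ties.method = "min")[f]
    cm$counts[f, ] <- cm$counts[f, ] * 3
    after <- rank(-log_mean_abundance(cm)$scores, ties.method = "min")[f]
    expect_lte(after, before)
  }
})

test_that("per-sample top-K recurrence follows the stated rule", {
  # 4 samples; feature 'lA' in the top-1 of exactly 2 of them
  m <- matrix(c(9, 9, 1, 1,
                1, 1, 9, 9,
                5, 5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("lA", "lB", "pc"), paste0("s", 1:4)))
  ann <- feature_annotation(c("lA", "lB", "pc"),
                            c("lncRNA", "lncRNA", "protein_coding"),
                            c("lA", "lB", "pc"))
  cm <- count_matrix(m)
  rec <- topk_recurrence(cm, ann, "lncRNA", k = 1, min_fraction = 0.5)
  expect_setequal(rec$feature_id, c("lA", "lB"))
  expect_equal(rec$fraction, c(0.5, 0.5))
  expect_true(all(rec$recurrent))
  # with min_fraction = 1, neither lncRNA is in every sample's top-1
  rec1 <- topk_recurrence(cm, ann, "lncRNA", k = 1, min_fraction = 1)
  expect_false(any(rec1$recurrent))
  # a feature leading every sample is recurrent with fraction 1
  rec2 <- topk_recurrence(cm, ann, "lncRNA", k = 2, min_fraction = 1)
  expect_true(all(rec2$fraction == 1))
  # protein_coding filter never sees lncRNAs
  rec3 <- topk_recurrence(cm, ann, "protein_coding", k = 1,
                          min_fraction = 0.5)
  expect_identical(rec3$feature_id, "pc")
  expect_error(topk_recurrence(cm, ann, "mystery", k = 1), "biotype")
})
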