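test_that("pathway membership counting is exact set intersection", {
  tk <- as_topk(c("g1", "g2", "g3"))
  expect_identical(members_in_topk(tk, c("g2", "g3", "g4", "g5")), 2L)
  expect_identical(members_in_topk(tk, c("x", "y")), 0L)
  expect_identical(members_in_topk(as_topk(sprintf("g%d", 1:20)),
                                   sprintf("g%d", 3:9)), 7L)
  expect_error(members_in_topk(tk, character(0)), "empty")
  # versioned IDs on the top-K side are harmonized before intersecting
  expect_identical(
    members_in_topk(as_topk("ENSG00000000005.2"), "ENSG00000000005"), 1L)
})

test_that("representation table computes percents at full precision", {
  gs <- toy_genesets(list(P1 = sprintf("g%d", 1:4), P2 = c("z1", "z2")),
                     c(P1 = "four genes", P2 = "absent pair"))
  tk_a <- as_topk(c("g1", "g2", "g3", "q1"), k = 4, source_label = "salEV")
  tk_b <- as_topk(c("g1", "q2", "q3", "q4"), k = 4, source_label = "bEV")
  tab <- representation_table(tk_a, tk_b, gs,
                              universe_a = c(sprintf("g%d", 1:3), "q1"),
                              universe_b = c("g1", "q2", "q3", "q4"))
  r1 <- tab[tab$pathway_id == "P1", ]
  expect_identical(r1$count_a, 3L)
  expect_equal(r1$percent_a, 75)
  expect_identical(r1$count_b, 1L)
  expect_equal(r1$percent_b, 25)
  expect_identical(r1$pathway_size, 4L)
  expect_identical(r1$measured_a, 3L)   # g4 unmeasured in A
  r2 <- tab[tab$pathway_id == "P2", ]
  expect_equal(r2$percent_a, 0)         # disjoint pathway
  expect_equal(r2$percent_b, 0)
  # full pathway inside the top-K gives 100%
  tk_full <- as_topk(sprintf("g%d", 1:10), k = 10)
  gs7 <- toy_genesets(list(S = sprintf("g%d", 1:7)), c(S = "subset"))
  expect_equal(representation_table(tk_full, tk_full, gs7)$percent_a, 100)
  # mismatched K is rejected
  expect_error(representation_table(as_topk("a", k = 3),
                                    as_topk("a", k = 5), gs7),
               "different K")
})

test_that("swapping sources swaps columns and leaves p-values unchanged", {
  gs <- toy_genesets(list(P = sprintf("g%d", 1:6)), c(P = "p"))
  tk_a <- as_topk(sprintf("g%d", 1:5), k = 5, source_label = "A")
  tk_b <- as_topk(c("g1", "x1", "x2", "x3", "x4"), k = 5,
                  source_label = "B")
  ab <- representation_table(tk_a, tk_b, gs)
  ba <- representation_table(tk_b, tk_a, gs)
  expect_identical(ab$count_a, ba$count_b)
  expect_identical(ab$count_b, ba$count_a)
  expect_equal(proportion_test(5, 1, 6)$p_value,
               proportion_test(1, 5, 6)$p_value)
})

test_that("exact proportion test matches the enumeration oracle", {
  expect_equal(proportion_test(10, 10, 40)$p_value, 1)
  expect_equal(proportion_test(10, 10, 40)$difference, 0)
  expect_equal(proportion_test(5, 0, 5)$difference, 1)
  cases <- list(c(128, 62, 390), c(124, 60, 270), c(5, 0, 5),
                c(3, 17, 30), c(0, 0, 12))
  for (cs in cases) {
    got <- proportion_test(cs[1], cs[2], cs[3])$p_value
    expect_equal(got, fisher_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-8, info = paste(cs, collapse = "/"))
  }
  expect_error(proportion_test(1, 1, 0), "positive")
  expect_error(proportion_test(7, 1, 5), "\\[0, k\\]")
})

test_that("end-to-end comparison recovers planted pathway enrichment", {
  cfg <- simulation_config(n_genes = 600, n_samples = c(8, 20),
                           n_pathways = 2, pathway_size = 25,
                           fold_factor = 10, seed = 421L)
  cm <- generate_counts(cfg)
  tab <- compare_topk(cm$counts_a, cm$counts_b, cm$genesets,
                      cm$annotation, k = 150)
  enr <- tab[tab$pathway_id == "P1", ]
  oth <- tab[tab$pathway_id == "P2", ]
  expect_gt(enr$percent_a, enr$percent_b)
  # counts bounded by min(K, pathway size)
  expect_true(all(tab$count_a <= pmin(attr(tab, "k"), tab$pathway_size)))
  expect_true(all(tab$count_b <= pmin(attr(tab, "k"), tab$pathway_size)))
  expect_true(all(tab$percent_a >= 0 & tab$percent_a <= 100))
  # measured-members columns populated from the count universes
  expect_true(all(tab$measured_a <= tab$pathway_size))
  expect_false(anyNA(tab$measured_a))
  expect_s3_class(tab, "ev_representation")
  expect_output(print(tab), "salEV")
  expect_output(summary(tab), "gene sets")
  # the unenriched pathway shows no comparable inflation
  expect_lt(abs(oth$percent_a - oth$percent_b),
            enr$percent_a - enr$percent_b)
})
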