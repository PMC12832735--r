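test_that("duplicate-run Ct calling follows the dynamic-range rule", {
  ct <- ct_table(gene = rep(c("A", "B", "C", "D"), each = 2),
                 sample = rep("s1", 8),
                 replicate = rep(1:2, 4),
                 ct = c(25, 30,      # both in window -> present
                        17.9, 25,    # one below window -> absent
                        25, NA,      # missing replicate -> absent
                        18, 35))     # inclusive bounds -> present
  p <- qpcr_presence_call(ct)
  expect_true(p["A", "s1"])
  expect_false(p["B", "s1"])
  expect_false(p["C", "s1"])
  expect_true(p["D", "s1"])
  # a gene assayed with a single well is never present
  one <- ct_table("E", "s1", 1, 25)
  expect_false(qpcr_presence_call(one)["E", "s1"])
  expect_error(qpcr_presence_call(ct, ct_min = 30, ct_max = 20), "exceed")
})

test_that("widening the Ct window never turns present into absent", {
  set.seed(5)
  for (rep in 1:1000) {
    n <- 30
    ct <- ct_table(gene = rep(sprintf("g%d", 1:5), each = 6),
                   sample = rep(rep(c("s1", "s2", "s3"), each = 2), 5),
                   replicate = rep(1:2, 15),
                   ct = ifelse(runif(n) < 0.15, NA, runif(n, 10, 45)))
    narrow <- qpcr_presence_call(ct, 20, 33)
    wide <- qpcr_presence_call(ct, 18, 35)
    expect_true(all(wide[narrow]))
  }
})

test_that("presence summary counts and percents follow the marginals", {
  # universe of 94 genes over 15 samples: 78 present somewhere, 54 in >= 10
  m <- matrix(FALSE, 94, 15,
              dimnames = list(sprintf("g%02d", 1:94),
                              sprintf("s%02d", 1:15)))
  m[1:54, 1:10] <- TRUE   # 54 genes in exactly 10 samples
  m[55:78, 1] <- TRUE     # 24 more genes in exactly 1 sample
  sm <- presence_summary(m, thresholds = c(1, 10))
  expect_identical(sm$n_genes, c(78L, 54L))
  expect_identical(sm$percent_display, c(83, 57))
  expect_equal(sm$percent, 100 * c(78, 54) / 94)
  expect_identical(attr(sm, "universe"), 94L)

  empty <- matrix(logical(0), 0, 0)
  expect_identical(presence_summary(empty)$n_genes, c(0L, 0L))
})

test_that("presence counts are non-increasing in the sample threshold", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(runif(20 * 8) < runif(1), 20, 8)
    sm <- presence_summary(m, thresholds = 1:8)
    expect_true(all(diff(sm$n_genes) <= 0))
  }
})

test_that("miRNA background filter applies mean + 2SD and the low cutoff", {
  # controls identical across samples: mean 20, sd 5 -> background 30
  ctrl <- matrix(rep(c(15, 20, 25, 15, 20, 25), 2), ncol = 2,
                 dimnames = list(sprintf("NEG_%d", 1:6), c("s1", "s2")))
  expect_equal(mean(ctrl[, 1]), 20)
  assay <- matrix(c(150, 150,   # expressed, clears cutoff
                    25, 25,     # below background
                    100, 100,   # expressed, low-flagged (not > 100)
                    101, 101),  # expressed, clears cutoff by strict rule
                  ncol = 2, byrow = TRUE,
                  dimnames = list(c("hi", "lo", "edge", "justover"),
                                  c("s1", "s2")))
  tab <- mirna_table(rbind(assay, ctrl), c(rep(FALSE, 4), rep(TRUE, 6)))
  res <- mirna_expression_filter(tab, low_cutoff = 100)
  expect_equal(res$background, 20 + 2 * sd(c(15, 20, 25, 15, 20, 25)),
               tolerance = 1e-12)
  expect_true(res$background < 31)
  t2 <- res$table
  get <- function(id, col) t2[[col]][t2$id == id]
  expect_true(get("hi", "expressed"))
  expect_false(get("hi", "low_flag"))
  expect_false(get("lo", "expressed"))
  expect_true(get("edge", "expressed"))
  expect_true(get("edge", "low_flag"))       # mean exactly 100 stays flagged
  expect_false(get("justover", "low_flag"))  # strict > clears it
  expect_identical(res$n_expressed, 3L)
  # ranks are 1..n_expressed ordered by mean count
  expect_identical(get("hi", "rank"), 1L)
  expect_true(is.na(get("lo", "rank")))
})

test_that("miRNA filtering is invariant to sample order", {
  cfg <- simulation_config(n_genes = 100, n_mirna = 60,
                           n_mirna_expressed = 15, seed = 88L)
  tab <- generate_mirna_table(cfg)$mirna
  res <- mirna_expression_filter(tab)
  shuf <- mirna_table(tab$counts[, rev(seq_len(ncol(tab$counts)))],
                      tab$is_control)
  res2 <- mirna_expression_filter(shuf)
  expect_equal(res$table$expressed, res2$table$expressed)
  expect_equal(res$background, res2$background)
})
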