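test_that("quantile normalization maps columns onto the sorted-row-mean reference", {
  m <- toy_matrix(c(1, 2,
                    3, 4), c("g1", "g2"), c("s1", "s2"))
  qn <- quantile_normalize(m)
  # columns (1,3) and (2,4): sorted-row means are (1.5, 3.5)
  expect_equal(unname(qn[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(qn[, "s2"]), c(1.5, 3.5))

  # identical columns come back unchanged
  m2 <- toy_matrix(c(5, 5, 1, 1, 9, 9), paste0("g", 1:3), c("a", "b"))
  expect_equal(quantile_normalize(m2), m2)

  # any input: all columns share one sorted multiset, ranks preserved
  set.seed(11)
  m3 <- matrix(rexp(60, 0.2), 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  qn3 <- quantile_normalize(m3)
  ref <- unname(sort(qn3[, 1]))
  for (j in 2:6) expect_equal(unname(sort(qn3[, j])), ref)
  for (j in 1:6) expect_equal(rank(qn3[, j]), rank(m3[, j]))
})

test_that("quantile normalization is idempotent and rejects bad input", {
  set.seed(3)
  m <- matrix(runif(50, 1, 100), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  once <- quantile_normalize(m)
  expect_identical(quantile_normalize(once), once)

  m[1, 1] <- NA
  expect_error(quantile_normalize(m), "non-finite")
  one_col <- matrix(1:3, 3, dimnames = list(letters[1:3], "s1"))
  expect_warning(out <- quantile_normalize(one_col), "single sample")
  expect_equal(out, one_col)
})

test_that("quantile normalization agrees with the limma reference on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rexp(200, 0.1), 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("log ratios are log2 of cancer intensity over mean control intensity", {
  m <- toy_matrix(c(3,    6,   1,   2,
                    0.75, 3,   1.5, 1.5,
                    1.5,  3,   1,   2),
                  c("gA", "gB", "gC"), c("T1", "T2", "N1", "N2"))
  labels <- split_labels(colnames(m), 2)
  lr <- log_ratio_vs_controls(m, labels)
  expect_equal(colnames(lr), c("T1", "T2"))
  expect_equal(lr["gB", "T2"], 1)
  expect_equal(lr["gA", "T1"], log2(3 / 1.5))   # = 1
  expect_equal(lr["gB", "T1"], -1)
  expect_equal(lr["gC", "T1"], 0)               # equals control mean
})

test_that("regulation calls are inclusive at the fold-change boundary", {
  r <- matrix(c(log2(1.5), 0, -1, log2(1.4999)), 1,
              dimnames = list("g", paste0("t", 1:4)))
  calls <- call_regulation(r, 1.5)
  expect_equal(unname(calls["g", ]), c("up", "neutral", "down", "neutral"))
  expect_error(call_regulation(r, 1), "fold_cutoff")
  # relaxed validation cutoff admits the borderline sample
  expect_equal(unname(call_regulation(r, 1.4)["g", 4]), "up")
})

test_that("pattern fractions count ordered joint calls over cancer samples", {
  calls <- matrix(c("up", "up", "down", "neutral",
                    "up", "down", "up", "up"), 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), paste0("t", 1:4)))
  pf <- pattern_fractions(calls, "A", "B")
  expect_equal(pf$f_uu, 0.25)
  expect_equal(pf$f_ud, 0.25)
  expect_equal(pf$f_du, 0.25)
  expect_equal(pf$f_dd, 0)
  # neutral-involving samples absorb the remainder of the partition
  neutral_frac <- mean(calls["A", ] == "neutral" | calls["B", ] == "neutral")
  expect_equal(pf$f_uu + pf$f_ud + pf$f_du + pf$f_dd + neutral_frac, 1)

  all_neutral <- matrix(c(rep("neutral", 4), rep("up", 4)), 2, byrow = TRUE,
                        dimnames = list(c("A", "B"), paste0("t", 1:4)))
  pf2 <- pattern_fractions(all_neutral, "A", "B")
  expect_equal(unlist(pf2[, c("f_uu", "f_ud", "f_du", "f_dd")]),
               c(f_uu = 0, f_ud = 0, f_du = 0, f_dd = 0))
  expect_error(pattern_fractions(calls, "A", "Z"), "Z")
})

test_that("pattern fractions are invariant to sample and gene-row order", {
  set.seed(21)
  calls <- matrix(sample(c("up", "down", "neutral"), 40, TRUE), 4,
                  dimnames = list(LETTERS[1:4], paste0("t", 1:10)))
  ref <- pattern_fractions(calls, "A", "C")
  perm <- calls[sample(4), sample(10)]
  expect_equal(pattern_fractions(perm, "A", "C"), ref)
})

test_that("panel selection applies the 15% rule with the stricter KRAS exception", {
  rec <- data.frame(
    gene_a = c("TP53", "KRAS", "KRAS", "EGFR", "BRCA1"),
    gene_b = c("EGFR", "STK17A", "CDK6", "FEN1", "RAD54B"),
    f_uu = c(0.20, 0.05, 0.16, 0.10, 0.14),
    f_du = c(0.00, 0.20, 0.10, 0.16, 0.10),
    stringsAsFactors = FALSE)
  sel <- select_initial_panel(rec, threshold = 0.15, kras_threshold = 0.25)
  # non-KRAS pair passes via f_uu at 15%
  expect_true("TP53" %in% sel$gene_a)
  # KRAS pair with f_du = 0.20 < 0.25 fails despite passing the ordinary rule
  expect_false(any(sel$gene_a == "KRAS" & sel$gene_b == "STK17A"))
  # KRAS pair may still qualify via f_uu at the ordinary threshold
  expect_true(any(sel$gene_a == "KRAS" & sel$gene_b == "CDK6"))
  expect_true(any(sel$gene_a == "EGFR" & sel$gene_b == "FEN1"))
  expect_false(any(sel$gene_a == "BRCA1"))

  # forced inclusion with prior-knowledge flag
  sel2 <- select_initial_panel(rec, include_list = data.frame(
    gene_a = "BRCA1", gene_b = "RAD54B"))
  brca <- sel2[sel2$gene_a == "BRCA1", ]
  expect_equal(nrow(brca), 1)
  expect_equal(brca$reason, "prior-knowledge")
})

test_that("SL pair tables drop self-pairs and collapse unordered duplicates", {
  pairs <- data.frame(gene_a = c("A", "B", "A", "C"),
                      gene_b = c("B", "A", "A", "D"))
  expect_warning(out <- sl_pair_table(pairs), "self-pair")
  expect_equal(nrow(out), 2)
  expect_equal(out$gene_a[1], "A")  # first orientation kept
  expect_equal(out$gene_b[1], "B")
})
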