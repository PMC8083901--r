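test_that("core aggregation averages coded grades over available cores", {
  sc <- data.frame(patient_id = "P1", stain_id = "A(N)", core_id = 1:3,
                   intensity = c("1+", "2+", "3+"))
  expect_equal(aggregate_cores(sc)$intensity, 2)

  sc2 <- data.frame(patient_id = "P1", stain_id = "A(N)", core_id = 1,
                    intensity = "2+")
  agg2 <- aggregate_cores(sc2)
  expect_equal(agg2$intensity, 2)
  expect_equal(agg2$n_cores, 1L)

  sc3 <- data.frame(patient_id = "P1", stain_id = "A(N)", core_id = 1:3,
                    intensity = c("0", "±", "1+"))
  expect_equal(aggregate_cores(sc3)$intensity, 0.5)

  # numeric coding accepted; off-grid rejected
  expect_equal(aggregate_cores(data.frame(patient_id = "P", stain_id = "S",
                                          core_id = 1:2,
                                          intensity = c(2, 3)))$intensity, 2.5)
  expect_error(code_intensity_grade(1.7), "grade")
})

test_that("cutoff calls reproduce the published rule boundaries", {
  panel <- default_stain_panel()
  agg <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    stain_id   = c("RB1(N)", "CSNK1E(C)", "EGFR(M)", "EGFR(M)", "TP53(N)"),
    intensity  = c(1.0, 1.0, 1.5, 1.5, 0.5),
    percent    = c(NA, NA, 5, 10, 0),
    stringsAsFactors = FALSE)
  calls <- apply_cutoffs(agg, panel)
  # RB1(N): over-rule >=1+, mean exactly 1 -> over
  expect_equal(calls$call[1], "over")
  # CSNK1E(C): over-rule >1+, mean exactly 1 -> under
  expect_equal(calls$call[2], "under")
  # EGFR(M): >=1+ and >=10% conjunctive; percent 5 fails -> under
  expect_equal(calls$call[3], "under")
  expect_equal(calls$call[4], "over")
  # TP53(N): percent-only rule, >0% for over
  expect_equal(calls$call[5], "under")
})

test_that("every score maps to exactly one of over/under across the panel", {
  panel <- default_stain_panel()
  over <- attr(panel, "over_rules")
  under <- attr(panel, "under_rules")
  grid <- expand.grid(intensity = seq(0, 3, by = 0.25),
                      percent = seq(0, 100, by = 5))
  for (s in panel$stain_id) {
    o <- mapply(over[[s]], grid$intensity, grid$percent)
    u <- mapply(under[[s]], grid$intensity, grid$percent)
    expect_true(all(xor(o, u)), label = paste("rule partition for", s))
  }
})

test_that("unparseable rules fail at panel load time", {
  df <- data.frame(stain_id = "X(N)", protein = "X", compartment = "N",
                   under_rule = "sometimes low", over_rule = ">=1+")
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_stain_panel(path), "unparseable")
})

test_that("stain-pair enumeration excludes same-protein pairs (closed form)", {
  # two stains of one protein -> no pairs
  p1 <- make_panel(data.frame(stain_id = c("CDH3(C)", "CDH3(N)"),
                              protein = "CDH3", compartment = c("C", "N"),
                              under_rule = "<1+", over_rule = ">=1+"))
  expect_equal(nrow(enumerate_stain_pairs(p1)), 0)
  # three distinct proteins -> C(3,2) = 3
  expect_equal(nrow(enumerate_stain_pairs(tiny_panel())), 3)

  # randomized panels against the closed form and a brute-force double loop
  set.seed(31)
  for (rep in 1:10) {
    n_prot <- sample(3:8, 1)
    k <- sample(1:3, n_prot, replace = TRUE)
    df <- do.call(rbind, lapply(seq_len(n_prot), function(i)
      data.frame(stain_id = paste0("P", i, "_", seq_len(k[i])),
                 protein = paste0("P", i),
                 compartment = "N", under_rule = "<1+", over_rule = ">=1+")))
    pairs <- enumerate_stain_pairs(make_panel(df))
    n <- sum(k)
    expect_equal(nrow(pairs), choose(n, 2) - sum(choose(k, 2)))
    brute <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (df$protein[i] != df$protein[j]) brute <- brute + 1L
    expect_equal(nrow(pairs), brute)
  }
})

test_that("marker membership is the AND of single-stain memberships", {
  calls <- data.frame(
    patient_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
    stain_id = rep(c("A(N)", "B(C)"), 4),
    call = c("under", "under",  "under", "over",
             "over", "under",   "over", "over"))
  mk_dd <- marker(c("A(N)", "B(C)"), c("down", "down"))
  expect_equal(unname(marker_membership(calls, mk_dd)), c(1L, 0L, 0L, 0L))
  mk_uu <- marker(c("A(N)", "B(C)"), c("up", "up"))
  expect_equal(unname(marker_membership(calls, mk_uu)), c(0L, 0L, 0L, 1L))
  # paired membership == AND of the two singles
  ma <- marker_membership(calls, marker("A(N)", "down"))
  mb <- marker_membership(calls, marker("B(C)", "down"))
  expect_equal(marker_membership(calls, mk_dd), ma * mb)
})

test_that("patients with missing component calls are dropped marker-wise", {
  calls <- data.frame(
    patient_id = c("P1", "P1", "P2"),       # P2 lacks the B(C) call
    stain_id = c("A(N)", "B(C)", "A(N)"),
    call = c("under", "under", "under"))
  mm <- marker_membership(calls, marker(c("A(N)", "B(C)"), c("down", "down")))
  expect_equal(names(mm), "P1")
  # but P2 still counts for the single-stain marker
  expect_equal(names(marker_membership(calls, marker("A(N)", "down"))),
               c("P1", "P2"))
  expect_error(marker_membership(calls, marker("Z(C)", "down")), "Z\\(C\\)")
})

test_that("the standard marker set has one single per stain and four patterns per pair", {
  panel <- tiny_panel()
  mks <- enumerate_markers(panel)
  expect_length(mks, 3 + 3 * 4)
  arities <- vapply(mks, function(m) length(m$stains), integer(1))
  expect_equal(sum(arities == 1), 3)
  expect_equal(sum(arities == 2), 12)
})
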