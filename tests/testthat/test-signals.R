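test_that("fourfold tables count AE records with the background comparator", {
  # group X: PT "q" x4 plus 6 other AEs; rest of background: "q" x10, 180 other
  assignments <- tibble::tibble(
    primaryid = as.character(1:200),
    caseid = as.character(1:200),
    group = c(rep("IPI", 10), rep("NIVO", 190)),
    is_background = TRUE
  )
  reac <- tibble::tibble(
    primaryid = c(rep(as.character(1:10), 1), as.character(sample(11:200, 190, TRUE))),
    pt = c(rep("q", 4), rep("other_a", 6), rep("q", 10), rep("other_b", 180))
  )
  tabs <- build_contingency(reac, assignments, "IPI")
  row <- tabs[tabs$pt == "q", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(4L, 6L, 10L, 180L))
  # a + c equals the PT's total AE records in the background
  expect_equal(row$a + row$c, sum(reac$pt == "q"))
  # PT absent from the target group gets no table
  expect_false("other_b" %in% tabs$pt)
  # per-group totals: a + b constant over PTs of the group
  expect_true(all(tabs$a + tabs$b == 10L))
})

test_that("ROR and Wald CI match the closed form, with Haldane correction on zeros", {
  r <- ror_stats(100, 900, 1000, 9000)
  expect_equal(r$ror, 1)
  expect_true(r$ror_025 < 1 && r$ror_975 > 1)
  r2 <- ror_stats(10, 90, 100, 9900)
  expect_equal(r2$ror, 11)
  expect_equal(r2$ror_025, 5.559515, tolerance = 1e-6)
  expect_false(r2$haldane)
  # zero cell: +0.5 to all cells, flagged
  r3 <- ror_stats(0, 10, 5, 100)
  expect_true(r3$haldane)
  expect_equal(r3$ror, (0.5 * 100.5) / (10.5 * 5.5))
  # all-zero table: not computable
  r4 <- ror_stats(0, 0, 0, 0)
  expect_true(is.na(r4$ror))
})

test_that("ROR/CI and chi-square match brute-force evaluations on random tables", {
  withr::local_seed(13)
  for (i in 1:200) {
    m <- random_2x2()
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    got <- ror_stats(a, b, c, d)
    want <- brute_ror(a, b, c, d)
    expect_equal(got$ror, unname(want["ror"]), tolerance = 1e-9)
    expect_equal(got$ror_025, unname(want["lo"]), tolerance = 1e-9)
    expect_equal(got$ror_975, unname(want["hi"]), tolerance = 1e-9)
    p <- pt_p_value(a, b, c, d)
    if (p$p_method == "chisq") {
      chi2 <- brute_chisq(matrix(c(a, b, c, d), 2, byrow = TRUE))
      expect_equal(p$p, pchisq(chi2, 1, lower.tail = FALSE), tolerance = 1e-9)
    }
  }
})

test_that("reciprocity: swapping target and comparator inverts the ROR and its CI", {
  withr::local_seed(17)
  for (i in 1:25) {
    m <- random_2x2()
    fwd <- ror_stats(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    rev <- ror_stats(m[2, 1], m[2, 2], m[1, 1], m[1, 2])
    expect_equal(rev$ror, 1 / fwd$ror, tolerance = 1e-12)
    expect_equal(rev$ror_025, 1 / fwd$ror_975, tolerance = 1e-12)
    expect_equal(rev$ror_975, 1 / fwd$ror_025, tolerance = 1e-12)
  }
})

test_that("IC is the shrunken log2 observed-to-expected with a gamma lower bound", {
  # exact independence: E = a, IC = 0 exactly, lower bound negative
  r <- ic_stats(100, 900, 1000, 9000)
  expect_equal(r$ic, 0)
  expect_lt(r$ic_025, 0)
  r2 <- ic_stats(10, 90, 100, 9900)
  expect_equal(r2$ic, log2(10.5 / ((100 * 110 / 10100) + 0.5)), tolerance = 1e-12)
  expect_equal(r2$ic, 2.724099, tolerance = 1e-6)
  expect_equal(r2$ic_025, 1.693957, tolerance = 1e-6)
  expect_true(all(r2$ic_025 < r2$ic))
})

test_that("IC_025 matches a Monte-Carlo gamma-posterior quantile", {
  withr::local_seed(19)
  cases <- list(c(10, 90, 100, 9900), c(5, 45, 20, 2000), c(50, 500, 80, 8000))
  for (x in cases) {
    n <- sum(x); e <- (x[1] + x[2]) * (x[1] + x[3]) / n
    draws <- log2(rgamma(2e5, shape = x[1] + 0.5, rate = e + 0.5))
    got <- ic_stats(x[1], x[2], x[3], x[4])$ic_025
    expect_equal(got, unname(quantile(draws, 0.025)), tolerance = 0.05)
  }
})

test_that("IC shrinkage and large-count consistency hold", {
  a <- 12; b <- 88; c <- 40; d <- 9860
  e <- (a + b) * (a + c) / (a + b + c + d)
  base <- ic_stats(a, b, c, d)
  expect_lt(base$ic, log2(a / e))           # shrinkage toward the null
  expect_lt(base$ic_025, base$ic)
  # scaling all cells up drives ic_025 toward log2(a/E) from below
  prev <- -Inf
  for (k in c(10, 100, 1000)) {
    r <- ic_stats(a * k, b * k, c * k, d * k)
    expect_gt(r$ic_025, prev)
    expect_lt(r$ic_025, log2(a / e))
    prev <- r$ic_025
  }
  expect_equal(prev, log2(a / e), tolerance = 0.01)
})

test_that("scale monotonicity: inflating a disproportionate table tightens both lower bounds", {
  a <- 10; b <- 90; c <- 100; d <- 9900
  for (k in c(2, 5, 10)) {
    expect_gt(ror_stats(a * k, b * k, c * k, d * k)$ror_025,
              ror_stats(a, b, c, d)$ror_025)
    expect_gt(ic_stats(a * k, b * k, c * k, d * k)$ic_025,
              ic_stats(a, b, c, d)$ic_025)
  }
})

test_that("the Bate closed-form variant is near the gamma formulation at large counts", {
  g <- ic_stats(200, 1800, 2000, 180000, method = "gamma")
  b <- ic_stats(200, 1800, 2000, 180000, method = "bate")
  expect_equal(b$ic, g$ic, tolerance = 0.05)
  expect_equal(b$ic_025, g$ic_025, tolerance = 0.1)
})

test_that("the joint dual-criteria flag requires all three conditions", {
  expect_true(signal_flag(3, 1.001, 0.001))
  expect_false(signal_flag(2, 5.0, 1.0))      # a < 3
  expect_false(signal_flag(100, 0.99, 0.5))   # ROR criterion fails
  expect_false(signal_flag(100, 1.5, -0.01))  # IC criterion fails
  expect_false(signal_flag(10, NA, 0.5))      # not computable -> negative
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(50)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher's exact path is taken for small expected counts", {
  res <- pt_p_value(1, 2, 3, 4)
  expect_equal(res$p_method, "fisher")
  expect_equal(res$p, fisher.test(matrix(c(1, 2, 3, 4), 2, byrow = TRUE))$p.value)
  degen <- pt_p_value(0, 0, 5, 10)
  expect_equal(degen$p_method, "degenerate")
  expect_equal(degen$p, 1)
})

test_that("detect_signals assembles per-group families with FDR and accessors", {
  cfg <- synthetic_config(
    seed = 23, n_cases = 3000,
    signal_spec = tibble::tibble(group = "IPI_NIVO", pt = "Cytokine release syndrome",
                                 multiplier = 6))
  sim <- generate_faers_sim(cfg)
  cleaned <- clean_faers(sim$tables, quiet = TRUE)
  asg <- assign_groups(cleaned$drug, cleaned$demo)
  sig <- detect_signals(cleaned$reac, asg, groups = c("IPI_NIVO", "NIVO"))
  expect_s3_class(sig, "faers_signals")
  # FDR is applied within each group family
  for (g in c("IPI_NIVO", "NIVO")) {
    sub <- sig[sig$group == g, ]
    expect_equal(sub$p_fdr, p.adjust(sub$p_raw, "BH"))
  }
  planted <- sig[sig$group == "IPI_NIVO" & sig$pt == "Cytokine release syndrome", ]
  expect_true(planted$positive)
  td <- tidy(sig)
  expect_true(all(c("group", "pt", "ror", "ic_025", "positive") %in% names(td)))
  gl <- glance(sig)
  expect_equal(sort(gl$group), sort(c("IPI_NIVO", "NIVO")))
  m <- ic_matrix(sig)
  expect_true(all(c("pt", "IPI_NIVO", "NIVO") %in% names(m)))
  p <- ggplot2::autoplot(sig)
  expect_s3_class(p, "ggplot")
})
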