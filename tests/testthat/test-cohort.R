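test_that("drug-name normalization matches brands, suffixes, and active ingredient", {
  expect_equal(normalize_drug("OPDIVO."), "nivolumab")
  expect_equal(normalize_drug("Nivolumab 240 MG"), "nivolumab")
  expect_equal(normalize_drug("  yervoy  "), "ipilimumab")
  expect_equal(normalize_drug("IMJUDO"), "tremelimumab")
  expect_true(is.na(normalize_drug("PEMBROLIZUMAB")))
  # prod_ai consulted when the verbatim name fails
  expect_equal(normalize_drug("UNKNOWN BRAND", "DURVALUMAB"), "durvalumab")
  expect_true(is.na(normalize_drug(NA_character_)))
})

test_that("case group assignment follows the PS/SS suspect rules", {
  demo <- tibble::tibble(primaryid = as.character(1:6),
                         caseid = as.character(901:906))
  drug <- tibble::tribble(
    ~primaryid, ~drug_seq, ~role_cod, ~drugname, ~prod_ai,
    "1", 1L, "PS", "OPDIVO", NA,                      # NIVO mono
    "2", 1L, "PS", "YERVOY", NA,                      # IPI_NIVO (partner SS)
    "2", 2L, "SS", "NIVOLUMAB", NA,
    "3", 1L, "PS", "PEMBROLIZUMAB", NA,               # OTHER (non-study PS)
    "4", 1L, "PS", "IMFINZI", NA,                     # DURVA_TREME (both PS)
    "4", 2L, "PS", "IMJUDO", NA,
    "5", 1L, "PS", "OPDIVO", NA,                      # OTHER: 3 study suspects
    "5", 2L, "SS", "YERVOY", NA,
    "5", 3L, "SS", "IMFINZI", NA,
    "6", 1L, "C",  "OPDIVO", NA                       # no PS record
  )
  expect_warning(asg <- assign_groups(drug, demo), "Primary Suspect")
  got <- setNames(asg$group, asg$primaryid)
  expect_equal(unname(got[c("1", "2", "3", "4", "5", "6")]),
               c("NIVO", "IPI_NIVO", "OTHER", "DURVA_TREME", "OTHER", "OTHER"))
  # partition: one group per case, background flag consistent
  expect_equal(nrow(asg), 6L)
  expect_equal(asg$is_background, asg$group != "OTHER")
  # concomitant-only partner does not make a combination
  drug2 <- tibble::tribble(
    ~primaryid, ~drug_seq, ~role_cod, ~drugname, ~prod_ai,
    "1", 1L, "PS", "OPDIVO", NA,
    "1", 2L, "C", "YERVOY", NA
  )
  asg2 <- assign_groups(drug2, demo[1, ])
  expect_equal(asg2$group, "NIVO")
})

test_that("Cramér's V reproduces the published baseline statistics from printed counts", {
  counts <- ici_baseline_counts()
  expected <- c(gender = 0.036, age = 0.114, serious = 0.079,
                hospitalization = 0.132, death = 0.051, disability = 0.004)
  for (nm in names(expected)) {
    res <- cramers_v(counts[[nm]])
    expect_equal(round(res$v, 3), unname(expected[[nm]]), info = nm)
  }
  expect_equal(round(cramers_v(counts$disability)$p, 3), 0.411)
  expect_lt(cramers_v(counts$gender)$p, 0.001)
})

test_that("Cramér's V equals a brute-force chi-square oracle and is symmetric", {
  withr::local_seed(7)
  for (rep in 1:50) {
    r <- sample(2:5, 1); k <- sample(2:5, 1)
    tab <- matrix(sample(1:200, r * k, replace = TRUE), nrow = r)
    res <- cramers_v(tab)
    chi2 <- brute_chisq(tab)
    expect_equal(res$chi2, chi2, tolerance = 1e-10)
    expect_equal(res$v, sqrt(chi2 / (sum(tab) * (min(r, k) - 1))),
                 tolerance = 1e-10)
    expect_true(res$v >= 0 && res$v <= 1 + 1e-12)
    # invariance to row/column permutations
    expect_equal(cramers_v(tab[sample(r), sample(k)])$v, res$v,
                 tolerance = 1e-10)
    # chi2 scales linearly with counts (V asymptotically unchanged)
    expect_equal(cramers_v(tab * 3)$chi2, 3 * chi2, tolerance = 1e-8)
    expect_equal(cramers_v(tab * 3)$v, res$v, tolerance = 1e-10)
  }
})

test_that("proportional tables give exact independence", {
  res <- cramers_v(cbind(c(10, 20), c(30, 60)))
  expect_equal(res$chi2, 0)
  expect_equal(res$v, 0)
  expect_equal(res$p, 1)
})

test_that("degenerate rows are dropped with a warning", {
  tab <- rbind(c(10, 20), c(0, 0), c(5, 8))
  expect_warning(res <- cramers_v(tab), "all-zero")
  expect_equal(res$dof, 1)
  expect_error(suppressWarnings(cramers_v(rbind(c(0, 0), c(1, 2)))),
               "at least 2")
})

test_that("seriousness is report-level presence of any outcome code", {
  demo <- tibble::tibble(primaryid = as.character(1:3))
  outc <- tibble::tibble(primaryid = c("1", "1", "3"),
                         outc_cod = c("HO", "OT", "DE"))
  s <- case_seriousness(demo, outc)
  expect_equal(s$serious, c(TRUE, FALSE, TRUE))
  expect_equal(s$HO, c(TRUE, FALSE, FALSE))
  expect_equal(s$OT, c(TRUE, FALSE, FALSE))
  expect_equal(s$DE, c(FALSE, FALSE, TRUE))
})

test_that("onset time is event minus earliest PS therapy start", {
  demo <- tibble::tibble(primaryid = c("1", "2", "3"),
                         event_dt = c("20230206", "", "20230301"))
  drug <- tibble::tibble(primaryid = c("1", "2", "3"), drug_seq = 1L,
                         role_cod = "PS", drugname = "OPDIVO", prod_ai = NA)
  ther <- tibble::tibble(primaryid = c("1", "2", "3"), dsg_drug_seq = 1L,
                         start_dt = c("20230101", "20230101", "20230310"),
                         end_dt = NA_character_)
  res <- onset_days(demo, drug, ther)
  expect_equal(res$onset_days, c(36, NA, -9))
  expect_equal(res$negative_onset, c(FALSE, FALSE, TRUE))
  # partial event date yields missing
  demo$event_dt[1] <- "202302"
  expect_true(is.na(onset_days(demo, drug, ther)$onset_days[1]))
})

test_that("country counts use occurrence country with reporter fallback", {
  demo <- tibble::tibble(primaryid = as.character(1:4),
                         occr_country = c("US", "US", "US", NA),
                         reporter_country = c("US", "JP", "US", "FR"))
  cc <- country_counts(demo)
  expect_equal(cc$n[cc$country == "US"], 3L)
  expect_equal(cc$n[cc$country == "FR"], 1L)
  expect_equal(nrow(country_counts(demo[0, ])), 0L)
})

test_that("baseline summary recovers known category counts on a synthetic cohort", {
  cfg <- synthetic_config(seed = 11, n_cases = 1500)
  sim <- generate_faers_sim(cfg)
  cleaned <- clean_faers(sim$tables, quiet = TRUE)
  asg <- assign_groups(cleaned$drug, cleaned$demo)
  onset <- onset_days(cleaned$demo, cleaned$drug, cleaned$ther)
  bl <- baseline_summary(asg, cleaned$demo, cleaned$outc, onset)
  # cell counts sum to the background total per variable
  tot <- sum(bl$n)
  for (v in unique(bl$table$variable)) {
    sub <- bl$table[bl$table$variable == v, ]
    expect_equal(sum(sub$n_total), tot, info = v)
    expect_equal(sum(sub$pct_sici), 100, tolerance = 1e-6, info = v)
    expect_equal(sum(sub$pct_dig), 100, tolerance = 1e-6, info = v)
  }
  # sex counts match a direct tabulation of the generator's truth
  truth <- sim$truth$assignments
  bg_cases <- truth$caseid[truth$group != "OTHER" &
                             !truth$caseid %in% sim$truth$deleted_caseids]
  demo_bg <- cleaned$demo[cleaned$demo$caseid %in% bg_cases, ]
  n_male <- sum(demo_bg$sex == "M", na.rm = TRUE)
  sexrow <- bl$table[bl$table$variable == "sex" & bl$table$level == "Male", ]
  expect_equal(sexrow$n_total, n_male)
  expect_s3_class(bl, "faers_baseline")
  expect_true(all(c("chi2", "v", "p") %in% names(bl$stats)))
})
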