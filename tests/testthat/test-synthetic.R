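test_that("configs validate their probability structure", {
  expect_s3_class(synthetic_config(), "faers_sim_config")
  expect_error(synthetic_config(group_weights = c(IPI = 1)), "group_weights")
  w <- default_group_weights(); w[1] <- w[1] + 0.1
  expect_error(synthetic_config(group_weights = w), "sum to 1")
  expect_error(synthetic_config(signal_spec = tibble::tibble(
    group = "IPI", pt = "No such PT", multiplier = 2)), "pt")
  expect_error(synthetic_config(signal_spec = tibble::tibble(
    group = "IPI", pt = "Colitis", multiplier = -1)), "multiplier")
})

test_that("generation is deterministic in the seed and writes byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 5, n_cases = 300)
  generate_faers_sim(cfg, d1)
  generate_faers_sim(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  cfg2 <- synthetic_config(seed = 6, n_cases = 300)
  generate_faers_sim(cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d3, "DEMO.txt"))))
})

test_that("zero cases yield a valid header-only package and empty truth", {
  d <- withr::local_tempdir()
  sim <- generate_faers_sim(synthetic_config(n_cases = 0), d)
  pkg <- suppressWarnings(read_faers_package(d))
  expect_equal(nrow(pkg$demo), 0L)
  expect_equal(nrow(pkg$reac), 0L)
  expect_equal(nrow(sim$truth$assignments), 0L)
})

test_that("cleaning removes exactly the injected duplicates and deleted cases", {
  cfg <- synthetic_config(seed = 9, n_cases = 2000)
  sim <- generate_faers_sim(cfg)
  cleaned <- clean_faers(sim$tables, quiet = TRUE)
  truth <- sim$truth
  expect_setequal(cleaned$demo$caseid, truth$surviving_caseids)
  # the kept version is always the current (larger) primaryid
  expect_setequal(cleaned$demo$primaryid,
                  truth$assignments$primaryid[truth$assignments$caseid %in%
                                                truth$surviving_caseids])
  # funnel: raw = cases + injected versions
  expect_equal(cleaned$funnel$n[1],
               cfg$n_cases + length(truth$duplicate_caseids))
  expect_equal(cleaned$funnel$n[2], cfg$n_cases)
  expect_equal(cleaned$funnel$n[3],
               cfg$n_cases - length(truth$deleted_caseids))
})

test_that("cohort assignment recovers the generator's true groups", {
  cfg <- synthetic_config(seed = 27, n_cases = 2000)
  sim <- generate_faers_sim(cfg)
  cleaned <- clean_faers(sim$tables, quiet = TRUE)
  asg <- assign_groups(cleaned$drug, cleaned$demo)
  m <- dplyr::inner_join(asg, sim$truth$assignments, by = "caseid",
                         suffix = c("", "_true"))
  expect_equal(m$group, m$group_true)
})

test_that("observed contingency cells sit within 4 SD of the analytic expectation", {
  cfg <- synthetic_config(
    seed = 41, n_cases = 8000,
    signal_spec = tibble::tibble(group = "IPI_NIVO", pt = "Colitis",
                                 multiplier = 3))
  sim <- generate_faers_sim(cfg)
  cleaned <- clean_faers(sim$tables, quiet = TRUE)
  asg <- assign_groups(cleaned$drug, cleaned$demo)
  tabs <- build_contingency(cleaned$reac, asg, "IPI_NIVO")
  for (pt in c("Colitis", "Rash", "Diarrhoea")) {
    want <- expected_table(cfg, "IPI_NIVO", pt)
    got <- tabs[tabs$pt == pt, ]
    # Poisson-scale bound on the target cell
    expect_lt(abs(got$a - want$a), 4 * sqrt(want$a) + 1, label = pt)
    expect_lt(abs(got$c - want$c), 4 * sqrt(want$c) + 1, label = pt)
  }
  expect_error(expected_table(cfg, "IPI_NIVO", "No such PT"), "unknown PT")
  expect_error(expected_table(cfg, "NOPE", "Colitis"), "unknown background group")
})

test_that("a null config implies unit expected ROR for every pair", {
  cfg <- synthetic_config(n_cases = 1000)
  for (g in c("IPI", "IPI_NIVO")) {
    e <- expected_table(cfg, g, "Colitis")
    expect_equal((e$a * e$d) / (e$b * e$c), 1, tolerance = 1e-12)
  }
})

test_that("generated onset times recover the configured log-normal median", {
  cfg <- synthetic_config(seed = 15, n_cases = 12000, missing_onset_rate = 0.3)
  sim <- generate_faers_sim(cfg)
  cleaned <- clean_faers(sim$tables, quiet = TRUE)
  asg <- assign_groups(cleaned$drug, cleaned$demo)
  ons <- onset_days(cleaned$demo, cleaned$drug, cleaned$ther)
  arm <- dplyr::inner_join(ons, asg, by = "primaryid")
  med_mono <- median(arm$onset_days[!arm$group %in% c("IPI_NIVO", "DURVA_TREME") &
                                      arm$is_background], na.rm = TRUE)
  med_combo <- median(arm$onset_days[arm$group %in% c("IPI_NIVO", "DURVA_TREME")],
                      na.rm = TRUE)
  expect_gt(sum(!is.na(arm$onset_days)), 5000)
  expect_lt(abs(med_mono - 50) / 50, 0.10)
  expect_lt(abs(med_combo - 36) / 36, 0.10)
})
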