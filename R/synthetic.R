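# Synthetic spontaneous-reporting generator.
#
# Emits FAERS-dialect quarterly packages with known statistical structure:
# demographics drawn from the marginals of a large published ICI cohort,
# AE counts per case of 1 + Poisson, per-group PT multinomials with planted
# reporting-rate multipliers, injected superseded case versions and a
# deleted-case list. Every draw is governed by one seed, so a config is a
# complete description of a dataset.

default_pt_vocab <- function() {
  tibble::tribble(
    ~pt_name,                       ~soc_name,                                        ~baseline_prob,
    "Death",                        "General disorders",                              0.080,
    "Fatigue",                      "General disorders",                              0.060,
    "Pyrexia",                      "General disorders",                              0.050,
    "Malignant neoplasm progression", "Neoplasms",                                    0.070,
    "Off label use",                "Injury and procedural complications",            0.050,
    "Diarrhoea",                    "Gastrointestinal disorders",                     0.070,
    "Colitis",                      "Gastrointestinal disorders",                     0.040,
    "Nausea",                       "Gastrointestinal disorders",                     0.050,
    "Immune-mediated enterocolitis", "Gastrointestinal disorders",                    0.015,
    "Hepatitis",                    "Hepatobiliary disorders",                        0.030,
    "Hepatic function abnormal",    "Hepatobiliary disorders",                        0.030,
    "Immune-mediated hepatitis",    "Hepatobiliary disorders",                        0.010,
    "Myocarditis",                  "Cardiac disorders",                              0.020,
    "Immune-mediated myocarditis",  "Cardiac disorders",                              0.008,
    "Hypothyroidism",               "Endocrine disorders",                            0.040,
    "Hyperthyroidism",              "Endocrine disorders",                            0.025,
    "Adrenal insufficiency",        "Endocrine disorders",                            0.020,
    "Hypophysitis",                 "Endocrine disorders",                            0.012,
    "Thyroiditis",                  "Endocrine disorders",                            0.010,
    "Rash",                         "Skin and subcutaneous tissue disorders",         0.060,
    "Pruritus",                     "Skin and subcutaneous tissue disorders",         0.040,
    "Pneumonitis",                  "Respiratory disorders",                          0.045,
    "Acute kidney injury",          "Renal and urinary disorders",                    0.030,
    "Cytokine release syndrome",    "Immune system disorders",                        0.010,
    "Type 1 diabetes mellitus",     "Metabolism and nutrition disorders",             0.015,
    "Diabetic ketoacidosis",        "Metabolism and nutrition disorders",             0.010,
    "Arthralgia",                   "Musculoskeletal disorders",                      0.040,
    "Myositis",                     "Musculoskeletal disorders",                      0.015,
    "Headache",                     "Nervous system disorders",                       0.045,
    "Sepsis",                       "Infections and infestations",                    0.050
  )
}

# Group weights follow the published subgroup sizes (7,386 / 29,544 / 5,278 /
# 25 / 12,256 / 563 of 55,052 background cases), scaled so that a fifth of
# generated cases fall outside the study background.
default_group_weights <- function(other_weight = 0.2) {
  bg <- c(IPI = 7386, NIVO = 29544, DURVA = 5278, TREME = 25,
          IPI_NIVO = 12256, DURVA_TREME = 563)
  c(bg / sum(bg) * (1 - other_weight), OTHER = other_weight)
}

default_year_probs <- function() {
  counts <- c(263, 839, 652, 981, 1915, 5029, 6529, 6038, 7039, 6183, 6010,
              5801, 4690, 3083)
  stats::setNames(counts / sum(counts), as.character(2011:2024))
}

#' Build a synthetic reporting-system configuration
#'
#' Defaults emulate the marginals of the published ICI cohort: sex, age-band,
#' reporter-occupation, country and reporting-year distributions; seriousness
#' 86% with per-outcome flag rates; AEs per case 1 + Poisson(1.14) (about
#' 2.14 AE records per patient); log-normal onset with median 50 days for
#' monotherapy arms and 36 days for combination arms and 76% missingness;
#' 15% of cases re-emitted as a superseded earlier version and 1% withdrawn
#' via the deletion list.
#'
#' @param seed Integer seed governing every draw.
#' @param n_cases Number of distinct cases (before duplicate versions).
#' @param group_weights Named probability vector over the six study groups
#'   plus `OTHER`.
#' @param pt_vocab Tibble `pt_name`, `soc_name`, `baseline_prob`.
#' @param signal_spec Tibble `group`, `pt`, `multiplier` of planted
#'   reporting-rate multipliers (lambda; 1 = null).
#' @param mean_extra_aes Mean of the Poisson count added to the mandatory
#'   first AE record.
#' @param sex_probs,occupation_probs,country_probs,year_probs Named
#'   probability vectors.
#' @param age_band_probs Probabilities for the bands `<18`, `18-44`,
#'   `45-64`, `65-74`, `>=75`, `Unspecified`.
#' @param serious_prob Probability a case carries at least one outcome code.
#' @param outcome_probs Per-code flag probabilities conditional on serious.
#' @param onset_meanlog,onset_sdlog Named (`mono`, `combo`) log-normal onset
#'   parameters, days.
#' @param missing_onset_rate Fraction of cases without a usable therapy
#'   start date.
#' @param partial_date_rate Fraction of event dates demoted to year-month.
#' @param duplicate_rate Fraction of cases with an injected superseded
#'   version (earlier FDA date, smaller primaryid).
#' @param deleted_rate Fraction of cases placed on the deletion list.
#' @return Validated list of class `"faers_sim_config"`.
#' @export
synthetic_config <- function(
    seed = 20240101L,
    n_cases = 5000L,
    group_weights = default_group_weights(),
    pt_vocab = default_pt_vocab(),
    signal_spec = tibble::tibble(group = character(), pt = character(),
                                 multiplier = numeric()),
    mean_extra_aes = 1.14,
    sex_probs = c(F = 0.2800, M = 0.5173, U = 0.2027),
    age_band_probs = c(0.0020, 0.0446, 0.2198, 0.1893, 0.1183, 0.4260),
    occupation_probs = c(MD = 0.3492, PH = 0.1950, CN = 0.2836, OT = 0.1564,
                         LW = 0.0005, U = 0.0153),
    country_probs = c(US = 0.47, JP = 0.16, FR = 0.07, CN = 0.05, DE = 0.05,
                      GB = 0.05, CA = 0.05, AU = 0.05, IT = 0.05),
    year_probs = default_year_probs(),
    serious_prob = 0.8601,
    outcome_probs = c(DE = 0.3427, LT = 0.0502, HO = 0.3154, DS = 0.0137,
                      CA = 0.0004, RI = 0.0011, OT = 0.8455),
    onset_meanlog = c(mono = log(50), combo = log(36)),
    onset_sdlog = c(mono = 1.558, combo = 1.310),
    missing_onset_rate = 0.76,
    partial_date_rate = 0.05,
    duplicate_rate = 0.15,
    deleted_rate = 0.01) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              group_weights = group_weights, pt_vocab = tibble::as_tibble(pt_vocab),
              signal_spec = tibble::as_tibble(signal_spec),
              mean_extra_aes = mean_extra_aes, sex_probs = sex_probs,
              age_band_probs = age_band_probs,
              occupation_probs = occupation_probs,
              country_probs = country_probs, year_probs = year_probs,
              serious_prob = serious_prob, outcome_probs = outcome_probs,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              missing_onset_rate = missing_onset_rate,
              partial_date_rate = partial_date_rate,
              duplicate_rate = duplicate_rate, deleted_rate = deleted_rate)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 0L)
  check_probs <- function(p, what, sum_to_one = TRUE) {
    if (any(p < 0 | p > 1)) stop(what, " must lie in [0, 1]")
    if (sum_to_one && abs(sum(p) - 1) > 1e-9) {
      stop(what, " must sum to 1 (got ", sum(p), ")")
    }
  }
  need <- c(ici_groups, "OTHER")
  if (!setequal(names(cfg$group_weights), need)) {
    stop("group_weights must name exactly: ", paste(need, collapse = ", "))
  }
  check_probs(cfg$group_weights, "group_weights")
  check_probs(cfg$sex_probs, "sex_probs")
  check_probs(cfg$age_band_probs, "age_band_probs")
  check_probs(cfg$occupation_probs, "occupation_probs")
  check_probs(cfg$country_probs, "country_probs")
  check_probs(cfg$year_probs, "year_probs")
  check_probs(cfg$outcome_probs, "outcome_probs", sum_to_one = FALSE)
  stopifnot(cfg$serious_prob >= 0, cfg$serious_prob <= 1,
            cfg$mean_extra_aes >= 0,
            all(cfg$pt_vocab$baseline_prob > 0),
            cfg$missing_onset_rate >= 0, cfg$missing_onset_rate <= 1,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate <= 1,
            cfg$deleted_rate >= 0, cfg$deleted_rate <= 1)
  if (nrow(cfg$signal_spec) > 0L) {
    stopifnot(all(cfg$signal_spec$multiplier >= 0),
              all(cfg$signal_spec$group %in% need),
              all(cfg$signal_spec$pt %in% cfg$pt_vocab$pt_name))
  }
  structure(cfg, class = "faers_sim_config")
}

# Per-case PT sampling probabilities for one group: baseline * multiplier,
# renormalized.
group_pt_probs <- function(cfg, group) {
  p <- cfg$pt_vocab$baseline_prob
  names(p) <- cfg$pt_vocab$pt_name
  spec <- dplyr::filter(cfg$signal_spec, .data$group == !!group)
  if (nrow(spec) > 0L) {
    p[spec$pt] <- p[spec$pt] * spec$multiplier
  }
  p / sum(p)
}

drug_name_variants <- list(
  ipilimumab = c("IPILIMUMAB", "Ipilimumab", "YERVOY", "IPILIMUMAB 50 MG"),
  nivolumab = c("NIVOLUMAB", "Nivolumab", "OPDIVO", "OPDIVO (NIVOLUMAB)",
                "Nivolumab 240 MG"),
  durvalumab = c("DURVALUMAB", "IMFINZI", "Durvalumab 500 MG"),
  tremelimumab = c("TREMELIMUMAB", "IMJUDO", "Tremelimumab."),
  other = c("PEMBROLIZUMAB", "ATEZOLIZUMAB", "CARBOPLATIN", "PACLITAXEL",
            "KEYTRUDA", "DOCETAXEL")
)

rand_date_in_year <- function(year) {
  sprintf("%04d%02d%02d", year, sample(1:12, length(year), replace = TRUE),
          sample(1:28, length(year), replace = TRUE))
}

#' Generate a synthetic FAERS package
#'
#' Deterministic given the config seed. Combination cases carry both partner
#' drugs with suspect roles (the partner is SS in 80% of combos and PS in
#' the rest); monotherapy cases carry one study drug as PS plus an optional
#' non-study concomitant; `OTHER` cases have a non-study PS drug. A fraction
#' of cases is re-emitted as a superseded earlier version (same caseid,
#' smaller primaryid, earlier FDA date) and a fraction is put on the
#' deletion list.
#'
#' @param cfg A `"faers_sim_config"`.
#' @param dir Output directory for the package files (`NULL` keeps the
#'   tables in memory only).
#' @return List with `tables` (the emitted tibbles, superseded versions
#'   included), `dir`, and `truth`: per-case `assignments` (caseid, primaryid
#'   of the current version, group), the planted `signal_spec`,
#'   `duplicate_caseids`, `deleted_caseids`, and `surviving_caseids`.
#' @export
generate_faers_sim <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "faers_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases
  empty_chr <- character(0)
  if (n == 0L) {
    tables <- list(
      demo = tibble::tibble(primaryid = empty_chr, caseid = empty_chr,
                            fda_dt = empty_chr, event_dt = empty_chr,
                            age = numeric(0), age_cod = empty_chr,
                            sex = empty_chr, occp_cod = empty_chr,
                            reporter_country = empty_chr, occr_country = empty_chr),
      drug = tibble::tibble(primaryid = empty_chr, drug_seq = integer(0),
                            role_cod = empty_chr, drugname = empty_chr,
                            prod_ai = empty_chr),
      reac = tibble::tibble(primaryid = empty_chr, pt = empty_chr),
      outc = tibble::tibble(primaryid = empty_chr, outc_cod = empty_chr),
      ther = tibble::tibble(primaryid = empty_chr, dsg_drug_seq = integer(0),
                            start_dt = empty_chr, end_dt = empty_chr),
      deleted = empty_chr
    )
    if (!is.null(dir)) write_faers_package(tables, dir)
    return(list(tables = tables, dir = dir, truth = list(
      assignments = tibble::tibble(caseid = empty_chr, primaryid = empty_chr,
                                   group = empty_chr),
      signal_spec = cfg$signal_spec, duplicate_caseids = empty_chr,
      deleted_caseids = empty_chr, surviving_caseids = empty_chr)))
  }

  caseid <- sprintf("9%07d", seq_len(n))
  primaryid <- paste0(caseid, "2")     # current version
  group <- sample(names(cfg$group_weights), n, replace = TRUE,
                  prob = cfg$group_weights)
  sex <- sample(names(cfg$sex_probs), n, replace = TRUE, prob = cfg$sex_probs)
  sex[sex == "U"] <- NA_character_
  band <- sample(seq_along(cfg$age_band_probs), n, replace = TRUE,
                 prob = cfg$age_band_probs)
  lo <- c(0, 18, 45, 65, 75, NA)[band]
  hi <- c(17, 44, 64, 74, 95, NA)[band]
  age <- rep(NA_real_, n)
  known <- !is.na(lo)
  age[known] <- floor(runif(sum(known), lo[known], hi[known] + 1))
  occp <- sample(names(cfg$occupation_probs), n, replace = TRUE,
                 prob = cfg$occupation_probs)
  occp[occp == "U"] <- NA_character_
  country <- sample(names(cfg$country_probs), n, replace = TRUE,
                    prob = cfg$country_probs)
  year <- as.integer(sample(names(cfg$year_probs), n, replace = TRUE,
                            prob = cfg$year_probs))
  fda_dt <- rand_date_in_year(year)

  # therapy start + onset -> event date
  is_combo <- group %in% ici_combo_groups
  arm <- ifelse(is_combo, "combo", "mono")
  onset <- round(rlnorm(n, cfg$onset_meanlog[arm], cfg$onset_sdlog[arm]))
  start_date <- as.Date(sprintf("%04d-%02d-%02d", year,
                                sample(1:12, n, TRUE), sample(1:28, n, TRUE))) -
    sample(0:60, n, TRUE)
  event_date <- start_date + onset
  has_onset <- runif(n) >= cfg$missing_onset_rate
  start_dt <- ifelse(has_onset, format(start_date, "%Y%m%d"), "")
  event_dt <- ifelse(has_onset, format(event_date, "%Y%m%d"), "")
  partial <- has_onset & runif(n) < cfg$partial_date_rate
  event_dt[partial] <- substr(event_dt[partial], 1, 6)

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = age,
    age_cod = ifelse(is.na(age), NA_character_, "YR"), sex = sex,
    occp_cod = occp, reporter_country = country, occr_country = country
  )

  # drug records
  pick_name <- function(drug) sample(drug_name_variants[[drug]], 1L)
  drug_rows <- purrr::map(seq_len(n), function(i) {
    g <- group[[i]]
    if (g == "OTHER") {
      rows <- tibble::tibble(drug_seq = 1L, role_cod = "PS",
                             drugname = pick_name("other"),
                             prod_ai = NA_character_)
    } else if (g %in% ici_combo_groups) {
      pair <- if (g == "IPI_NIVO") c("ipilimumab", "nivolumab") else
        c("durvalumab", "tremelimumab")
      pair <- sample(pair)
      partner_role <- if (runif(1) < 0.8) "SS" else "PS"
      rows <- tibble::tibble(
        drug_seq = 1:2, role_cod = c("PS", partner_role),
        drugname = c(pick_name(pair[[1]]), pick_name(pair[[2]])),
        prod_ai = toupper(pair))
    } else {
      drug <- canonical_of_group[[g]]
      rows <- tibble::tibble(drug_seq = 1L, role_cod = "PS",
                             drugname = pick_name(drug),
                             prod_ai = toupper(drug))
    }
    if (runif(1) < 0.3) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        drug_seq = max(rows$drug_seq) + 1L, role_cod = "C",
        drugname = pick_name("other"), prod_ai = NA_character_))
    }
    rows$primaryid <- primaryid[[i]]
    rows
  }) |> purrr::list_rbind() |>
    dplyr::select("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai")

  # reactions: 1 + Poisson AE records from the group multinomial
  n_aes <- 1L + rpois(n, cfg$mean_extra_aes)
  probs_by_group <- purrr::map(setNames(names(cfg$group_weights),
                                        names(cfg$group_weights)),
                               \(g) group_pt_probs(cfg, g))
  reac <- tibble::tibble(
    primaryid = rep(primaryid, n_aes),
    group = rep(group, n_aes)
  )
  reac$pt <- NA_character_
  for (g in names(probs_by_group)) {
    idx <- which(reac$group == g)
    if (length(idx) == 0L) next
    p <- probs_by_group[[g]]
    reac$pt[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  reac <- dplyr::select(reac, "primaryid", "pt")

  # outcomes
  serious <- runif(n) < cfg$serious_prob
  outc <- purrr::map(which(serious), function(i) {
    codes <- names(cfg$outcome_probs)[runif(length(cfg$outcome_probs)) <
                                        cfg$outcome_probs]
    if (length(codes) == 0L) codes <- "OT"
    tibble::tibble(primaryid = primaryid[[i]], outc_cod = codes)
  }) |> purrr::list_rbind()
  if (is.null(outc) || nrow(outc) == 0L) {
    outc <- tibble::tibble(primaryid = character(), outc_cod = character())
  }

  ther <- tibble::tibble(
    primaryid = primaryid, dsg_drug_seq = 1L,
    start_dt = start_dt, end_dt = ""
  ) |> dplyr::filter(nzchar(.data$start_dt))

  # injected superseded versions: same caseid, smaller primaryid, earlier
  # FDA date, same satellite rows under the old primaryid
  dup_idx <- which(runif(n) < cfg$duplicate_rate)
  dup_caseids <- caseid[dup_idx]
  if (length(dup_idx) > 0L) {
    old_pid <- paste0(caseid[dup_idx], "1")
    old_demo <- demo[dup_idx, ] |>
      dplyr::mutate(
        primaryid = old_pid,
        fda_dt = format(as.Date(paste0(substr(.data$fda_dt, 1, 4), "-",
                                       substr(.data$fda_dt, 5, 6), "-",
                                       substr(.data$fda_dt, 7, 8))) -
                          sample(30:400, length(dup_idx), TRUE), "%Y%m%d"))
    remap <- function(df, keep_pid) {
      df |> dplyr::filter(.data$primaryid %in% keep_pid) |>
        dplyr::mutate(primaryid = paste0(substr(.data$primaryid, 1,
                                                nchar(.data$primaryid) - 1L), "1"))
    }
    demo <- dplyr::bind_rows(demo, old_demo)
    drug_rows <- dplyr::bind_rows(drug_rows, remap(drug_rows, primaryid[dup_idx]))
    reac <- dplyr::bind_rows(reac, remap(reac, primaryid[dup_idx]))
    outc <- dplyr::bind_rows(outc, remap(outc, primaryid[dup_idx]))
    ther <- dplyr::bind_rows(ther, remap(ther, primaryid[dup_idx]))
  }

  deleted_caseids <- caseid[runif(n) < cfg$deleted_rate]

  tables <- list(demo = demo, drug = drug_rows, reac = reac, outc = outc,
                 ther = ther, deleted = deleted_caseids)
  if (!is.null(dir)) write_faers_package(tables, dir)
  list(
    tables = tables, dir = dir,
    truth = list(
      assignments = tibble::tibble(caseid = caseid, primaryid = primaryid,
                                   group = group),
      signal_spec = cfg$signal_spec,
      duplicate_caseids = dup_caseids,
      deleted_caseids = deleted_caseids,
      surviving_caseids = setdiff(caseid, deleted_caseids)
    )
  )
}

#' PT-to-SOC map implied by a synthetic config
#'
#' @param cfg A `"faers_sim_config"`.
#' @return A validated `"pt_soc_map"` covering the config's PT vocabulary.
#' @export
sim_pt_soc_map <- function(cfg) {
  validate_pt_soc_map(tibble::tibble(
    pt_name = cfg$pt_vocab$pt_name,
    soc_name = cfg$pt_vocab$soc_name,
    is_primary_soc = TRUE
  ))
}

#' Expected fourfold cell counts under a synthetic config
#'
#' Closed-form expectation of the AE-record contingency cells implied by the
#' group weights, the per-group PT multinomials and the AE-count model,
#' after deletion-list attrition (superseded versions are removed by
#' cleaning and do not enter). Used as the analytic oracle when checking
#' the generator and the pipeline jointly.
#'
#' @param cfg A `"faers_sim_config"`.
#' @param group Target background group.
#' @param pt A PT name from the config vocabulary.
#' @return One-row tibble `a`, `b`, `c`, `d` of expected counts.
#' @export
expected_table <- function(cfg, group, pt) {
  stopifnot(inherits(cfg, "faers_sim_config"))
  if (!group %in% ici_groups) stop("unknown background group: ", group)
  if (!pt %in% cfg$pt_vocab$pt_name) stop("unknown PT: ", pt)
  m <- 1 + cfg$mean_extra_aes
  n_surv <- cfg$n_cases * (1 - cfg$deleted_rate)
  w <- cfg$group_weights[ici_groups]
  recs <- n_surv * w * m
  p_pt <- vapply(ici_groups, \(g) group_pt_probs(cfg, g)[[pt]], numeric(1))
  a <- recs[[group]] * p_pt[[group]]
  b <- recs[[group]] - a
  other <- setdiff(ici_groups, group)
  c_ <- sum(recs[other] * p_pt[other])
  d <- sum(recs[other]) - c_
  tibble::tibble(a = a, b = b, c = c_, d = d)
}
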