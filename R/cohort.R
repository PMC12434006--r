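# Cohort construction for the six-group checkpoint-inhibitor background and
# the baseline description of single-agent (sICI) versus dual-therapy (DIG)
# cases.

ici_groups <- c("IPI", "NIVO", "DURVA", "TREME", "IPI_NIVO", "DURVA_TREME")
ici_mono_groups <- c("IPI", "NIVO", "DURVA", "TREME")
ici_combo_groups <- c("IPI_NIVO", "DURVA_TREME")
canonical_of_group <- c(IPI = "ipilimumab", NIVO = "nivolumab",
                        DURVA = "durvalumab", TREME = "tremelimumab")

#' Default drug-synonym table for the four study drugs
#'
#' Maps generic and US brand names (Yervoy, Opdivo, Imfinzi, Imjudo) to the
#' canonical drug; matching in [normalize_drug()] is by case-insensitive
#' substring on the trimmed name, so dosage suffixes match too.
#'
#' @return Tibble with columns `pattern`, `canonical`.
#' @export
default_drug_synonyms <- function() {
  tibble::tribble(
    ~pattern,        ~canonical,
    "IPILIMUMAB",    "ipilimumab",
    "YERVOY",        "ipilimumab",
    "NIVOLUMAB",     "nivolumab",
    "OPDIVO",        "nivolumab",
    "DURVALUMAB",    "durvalumab",
    "IMFINZI",       "durvalumab",
    "TREMELIMUMAB",  "tremelimumab",
    "IMJUDO",        "tremelimumab"
  )
}

#' Read a drug-synonym table
#'
#' @param path Two-column TSV (`pattern`, `canonical`).
#' @return Tibble with the validated synonym entries.
#' @export
read_drug_synonyms <- function(path) {
  syn <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  stopifnot(all(c("pattern", "canonical") %in% names(syn)))
  bad <- setdiff(unique(syn$canonical), unname(canonical_of_group))
  if (length(bad) > 0L) {
    stop("synonym table maps to non-study drug(s): ", paste(bad, collapse = ", "))
  }
  tibble::as_tibble(syn)
}

#' Map raw drug names to a canonical study drug
#'
#' Uppercases and trims the verbatim drug name and looks for any synonym
#' pattern as a substring; when the drug name does not match, the active
#' ingredient field is consulted. Non-study drugs map to `NA`.
#'
#' @param drugname Character vector of verbatim drug names.
#' @param prod_ai Character vector of active-ingredient strings (or `NA`).
#' @param synonyms Synonym tibble (default [default_drug_synonyms()]).
#' @return Character vector of canonical names or `NA`.
#' @examples
#' normalize_drug(c("OPDIVO.", "Nivolumab 240 MG", "PEMBROLIZUMAB"))
#' @export
normalize_drug <- function(drugname, prod_ai = NA_character_,
                           synonyms = default_drug_synonyms()) {
  prod_ai <- rep_len(prod_ai, length(drugname))
  match_one <- function(x) {
    if (is.na(x)) return(NA_character_)
    x <- toupper(trimws(x))
    hit <- which(stringr::str_detect(x, stringr::fixed(toupper(synonyms$pattern))))
    if (length(hit) == 0L) NA_character_ else synonyms$canonical[[hit[[1L]]]]
  }
  out <- vapply(drugname, match_one, character(1), USE.NAMES = FALSE)
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- vapply(prod_ai[miss], match_one, character(1), USE.NAMES = FALSE)
  }
  out
}

#' Assign cleaned cases to study groups
#'
#' The group is decided by suspect roles only. With P the set of canonical
#' study drugs among a case's Primary Suspect (PS) records and S the set
#' with role PS or SS: a monotherapy group requires P to name that drug and
#' S to contain no other study drug; a combination group (`IPI_NIVO`,
#' `DURVA_TREME`) requires the PS drug to be one partner and S to be exactly
#' the partner pair. Everything else — PS not a study drug, three or more
#' study drugs, no PS record — is `OTHER`.
#'
#' @param drug Cleaned DRUG tibble (`primaryid`, `role_cod`, `drugname`,
#'   `prod_ai`).
#' @param demo Cleaned DEMO tibble (supplies `caseid` per `primaryid`).
#' @param synonyms Synonym tibble.
#' @return Tibble with `primaryid`, `caseid`, `group`, `is_background`
#'   (group != "OTHER"); one row per case.
#' @export
assign_groups <- function(drug, demo, synonyms = default_drug_synonyms()) {
  drug <- drug |>
    dplyr::mutate(canonical = normalize_drug(.data$drugname, .data$prod_ai,
                                             synonyms))
  no_ps <- drug |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(has_ps = any(.data$role_cod == "PS", na.rm = TRUE))
  if (any(!no_ps$has_ps)) {
    warning(sum(!no_ps$has_ps),
            " case(s) without a Primary Suspect record assigned to OTHER",
            call. = FALSE)
  }
  per_case <- drug |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      ps_drugs = list(unique(stats::na.omit(.data$canonical[.data$role_cod == "PS"]))),
      suspect_drugs = list(unique(stats::na.omit(
        .data$canonical[.data$role_cod %in% c("PS", "SS")])))
    ) |>
    dplyr::mutate(group = purrr::map2_chr(.data$ps_drugs, .data$suspect_drugs,
                                          classify_case))
  demo |>
    dplyr::select("primaryid", "caseid") |>
    dplyr::left_join(per_case, by = "primaryid") |>
    dplyr::mutate(group = dplyr::coalesce(.data$group, "OTHER"),
                  is_background = .data$group != "OTHER") |>
    dplyr::select("primaryid", "caseid", "group", "is_background")
}

classify_case <- function(ps, suspects) {
  if (length(ps) == 0L) return("OTHER")
  combos <- list(IPI_NIVO = c("ipilimumab", "nivolumab"),
                 DURVA_TREME = c("durvalumab", "tremelimumab"))
  # both partners may carry the PS role; the case is still the combination
  for (g in names(combos)) {
    if (all(ps %in% combos[[g]]) && setequal(suspects, combos[[g]])) return(g)
  }
  if (length(ps) == 1L && identical(suspects, ps)) {
    return(names(canonical_of_group)[match(ps, canonical_of_group)])
  }
  "OTHER"
}

#' Cramér's V association strength with chi-square p-value
#'
#' Pearson chi-square without continuity correction on an r x c count table;
#' V = sqrt(chi2 / (N * (min(r, c) - 1))). All-zero rows or columns are
#' dropped (with a warning) before computing.
#'
#' @param tab Matrix or table of non-negative counts (>= 2 non-degenerate
#'   rows and columns).
#' @return One-row tibble with `chi2`, `v`, `p`, `dof`, `n`.
#' @examples
#' cramers_v(cbind(a = c(10, 20), b = c(30, 60)))  # exact independence
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(is.finite(tab)))
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s) before Cramér's V", call. = FALSE)
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("Cramér's V needs at least 2 non-degenerate rows and columns")
  }
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  tibble::tibble(
    chi2 = unname(ch$statistic),
    v = sqrt(unname(ch$statistic) / (n * (min(dim(tab)) - 1L))),
    p = unname(ch$p.value),
    dof = unname(ch$parameter),
    n = n
  )
}

#' Per-case seriousness and outcome flags
#'
#' FAERS classifies seriousness at the report level: a case with at least
#' one OUTC record is serious, one with none is non-serious.
#'
#' @param demo Cleaned DEMO tibble.
#' @param outc Cleaned OUTC tibble.
#' @return Tibble with `primaryid`, `serious`, and one logical column per
#'   outcome code (`DE`, `LT`, `HO`, `DS`, `CA`, `RI`, `OT`).
#' @export
case_seriousness <- function(demo, outc) {
  base <- tibble::tibble(primaryid = demo$primaryid)
  flags <- outc |>
    dplyr::filter(.data$outc_cod %in% faers_outcome_codes) |>
    dplyr::distinct(.data$primaryid, .data$outc_cod) |>
    dplyr::mutate(value = TRUE) |>
    tidyr::pivot_wider(names_from = "outc_cod", values_from = "value",
                       values_fill = FALSE)
  out <- dplyr::left_join(base, flags, by = "primaryid")
  for (code in faers_outcome_codes) {
    out[[code]] <- if (code %in% names(out)) dplyr::coalesce(out[[code]], FALSE) else FALSE
  }
  any_serious <- outc |>
    dplyr::distinct(.data$primaryid) |>
    dplyr::mutate(serious = TRUE)
  out <- dplyr::left_join(out, any_serious, by = "primaryid") |>
    dplyr::mutate(serious = dplyr::coalesce(.data$serious, FALSE))
  out[, c("primaryid", "serious", faers_outcome_codes)]
}

#' Time to onset in days
#'
#' Days from the earliest full therapy start date among a case's
#' Primary-Suspect drug records to the case's event date. Partial or absent
#' dates yield `NA`; negative deltas (event before recorded start) are kept
#' and flagged.
#'
#' @param demo Cleaned DEMO tibble (`event_dt`).
#' @param drug Cleaned DRUG tibble (identifies PS `drug_seq`).
#' @param ther Cleaned THER tibble (`dsg_drug_seq`, `start_dt`).
#' @return Tibble with `primaryid`, `onset_days`, `negative_onset`.
#' @export
onset_days <- function(demo, drug, ther) {
  ps_seq <- drug |>
    dplyr::filter(.data$role_cod == "PS") |>
    dplyr::select("primaryid", "drug_seq")
  starts <- ther |>
    dplyr::inner_join(ps_seq, by = c("primaryid", dsg_drug_seq = "drug_seq")) |>
    dplyr::mutate(start_date = faers_date_parts(.data$start_dt)$date) |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_date = min(.data$start_date))
  demo |>
    dplyr::select("primaryid", "event_dt") |>
    dplyr::mutate(event_date = faers_date_parts(.data$event_dt)$date) |>
    dplyr::left_join(starts, by = "primaryid") |>
    dplyr::mutate(
      onset_days = as.numeric(.data$event_date - .data$start_date),
      negative_onset = !is.na(.data$onset_days) & .data$onset_days < 0
    ) |>
    dplyr::select("primaryid", "onset_days", "negative_onset")
}

age_band_breaks <- c(0, 18, 45, 65, 75, Inf)
age_band_labels <- c("<18", "18-44", "45-64", "65-74", ">=75")

onset_band_breaks <- c(-Inf, 30, 60, 90, 120, 150, 180, 360, Inf)
onset_band_labels <- c("<30", "31-60", "61-90", "91-120", "121-150",
                       "151-180", "181-360", ">360")

band_ages <- function(age_years) {
  cut(age_years, breaks = age_band_breaks, labels = age_band_labels,
      right = FALSE)
}

#' Baseline description of sICI versus dual-therapy cases
#'
#' Tabulates the background cases — four monotherapy groups pooled as sICI,
#' the two combination groups pooled as DIG — over sex, age band, reporting
#' year, reporter occupation, seriousness, each outcome flag, and banded
#' onset time, attaching Cramér's V and the chi-square p per variable, plus
#' quantitative summaries of age and onset time. Counting is at patient
#' (case) level.
#'
#' @param assignments Output of [assign_groups()].
#' @param demo,outc Cleaned tables.
#' @param onset Output of [onset_days()] (optional; onset blocks are skipped
#'   when absent).
#' @param include_negative_onset Keep negative onset deltas in the
#'   quantitative block (banded tables always exclude them).
#' @return A list of class `"faers_baseline"`: `table` (long tibble with
#'   variable, level, counts and column percentages for sICI/DIG/total),
#'   `stats` (per-variable chi2, V, p), `quantitative` (age and onset
#'   summaries), `n` (cases per arm).
#' @export
baseline_summary <- function(assignments, demo, outc, onset = NULL,
                             include_negative_onset = TRUE) {
  bg <- assignments |>
    dplyr::filter(.data$is_background) |>
    dplyr::mutate(arm = ifelse(.data$group %in% ici_combo_groups, "DIG", "sICI"))
  cases <- bg |>
    dplyr::left_join(demo, by = c("primaryid", "caseid")) |>
    dplyr::left_join(case_seriousness(demo, outc), by = "primaryid")
  if (!is.null(onset)) {
    cases <- dplyr::left_join(cases, onset, by = "primaryid")
  }
  cases <- cases |>
    dplyr::mutate(
      sex_lvl = dplyr::case_when(.data$sex == "F" ~ "Female",
                                 .data$sex == "M" ~ "Male",
                                 TRUE ~ "Unspecified"),
      age_years = normalize_age(.data$age, .data$age_cod),
      age_lvl = as.character(band_ages(.data$age_years)),
      age_lvl = dplyr::coalesce(.data$age_lvl, "Unspecified"),
      year_lvl = as.character(faers_date_parts(.data$fda_dt)$year),
      occp_lvl = dplyr::case_when(
        .data$occp_cod == "MD" ~ "Physician",
        .data$occp_cod == "PH" ~ "Pharmacist",
        .data$occp_cod == "CN" ~ "Consumer",
        .data$occp_cod == "OT" ~ "Other health-professional",
        .data$occp_cod == "LW" ~ "Lawyer",
        TRUE ~ "Unspecified"),
      serious_lvl = ifelse(.data$serious, "Serious", "Non-Serious")
    )
  variables <- list(
    sex = "sex_lvl", age = "age_lvl", reporting_year = "year_lvl",
    reporter = "occp_lvl", serious = "serious_lvl"
  )
  for (code in faers_outcome_codes) {
    cases[[paste0("outc_", code)]] <- ifelse(cases[[code]], "Yes", "No")
    variables[[paste0("outcome_", code)]] <- paste0("outc_", code)
  }
  if (!is.null(onset)) {
    cases$onset_lvl <- ifelse(
      is.na(cases$onset_days) | cases$onset_days < 0, NA_character_,
      as.character(cut(cases$onset_days, onset_band_breaks, onset_band_labels)))
    cases$onset_lvl <- dplyr::coalesce(cases$onset_lvl, "Missing")
    variables$onset_band <- "onset_lvl"
  }
  one_var <- function(col, var) {
    tab <- table(cases[[col]], cases$arm)
    long <- tibble::as_tibble(tab, .name_repair = "minimal") |>
      setNames(c("level", "arm", "n")) |>
      tidyr::pivot_wider(names_from = "arm", values_from = "n",
                         values_fill = 0L)
    for (a in c("sICI", "DIG")) if (!a %in% names(long)) long[[a]] <- 0L
    long |>
      dplyr::mutate(
        variable = var,
        n_sici = .data$sICI, n_dig = .data$DIG,
        n_total = .data$n_sici + .data$n_dig,
        pct_sici = 100 * .data$n_sici / sum(.data$n_sici),
        pct_dig = 100 * .data$n_dig / sum(.data$n_dig),
        pct_total = 100 * .data$n_total / sum(.data$n_total)
      ) |>
      dplyr::select("variable", "level", "n_sici", "pct_sici", "n_dig",
                    "pct_dig", "n_total", "pct_total")
  }
  var_stats <- function(col, var) {
    tab <- table(cases[[col]], cases$arm)
    ok <- nrow(tab) >= 2L && ncol(tab) >= 2L &&
      sum(rowSums(tab) > 0) >= 2L && sum(colSums(tab) > 0) >= 2L
    if (!ok) {
      return(tibble::tibble(variable = var, chi2 = NA_real_, v = NA_real_,
                            p = NA_real_, dof = NA_real_))
    }
    dplyr::mutate(cramers_v(tab), variable = var) |>
      dplyr::select("variable", "chi2", "v", "p", "dof")
  }
  table_long <- purrr::imap(variables, \(col, var) one_var(col, var)) |>
    purrr::list_rbind()
  stats_tbl <- purrr::imap(variables, \(col, var) var_stats(col, var)) |>
    purrr::list_rbind()
  quant <- function(x, arm) {
    x_arm <- x[cases$arm == arm]
    tibble::tibble(
      arm = arm, n = sum(!is.na(x_arm)), missing = sum(is.na(x_arm)),
      mean = mean(x_arm, na.rm = TRUE), sd = stats::sd(x_arm, na.rm = TRUE),
      median = stats::median(x_arm, na.rm = TRUE),
      q1 = unname(stats::quantile(x_arm, 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(x_arm, 0.75, na.rm = TRUE)),
      min = suppressWarnings(min(x_arm, na.rm = TRUE)),
      max = suppressWarnings(max(x_arm, na.rm = TRUE))
    )
  }
  quantitative <- list(
    age = purrr::map(c("sICI", "DIG"), \(a) quant(cases$age_years, a)) |>
      purrr::list_rbind()
  )
  if (!is.null(onset)) {
    ons <- cases$onset_days
    if (!include_negative_onset) ons[!is.na(ons) & ons < 0] <- NA_real_
    quantitative$onset <- purrr::map(c("sICI", "DIG"), \(a) quant(ons, a)) |>
      purrr::list_rbind()
  }
  structure(
    list(table = table_long, stats = stats_tbl, quantitative = quantitative,
         n = c(sICI = sum(cases$arm == "sICI"), DIG = sum(cases$arm == "DIG"))),
    class = "faers_baseline"
  )
}

#' Case counts per reporting country
#'
#' Counts background cases by occurrence country, falling back to the
#' reporter country when the occurrence country is missing.
#'
#' @param demo Cleaned DEMO tibble restricted to the cases of interest.
#' @return Tibble `country`, `n`, sorted descending.
#' @export
country_counts <- function(demo) {
  if (nrow(demo) == 0L) return(tibble::tibble(country = character(), n = integer()))
  demo |>
    dplyr::mutate(country = dplyr::coalesce(.data$occr_country,
                                            .data$reporter_country,
                                            "Unknown")) |>
    dplyr::count(.data$country, sort = TRUE)
}

#' @export
print.faers_baseline <- function(x, ...) {
  cat("FAERS baseline summary:", x$n[["sICI"]], "sICI cases,",
      x$n[["DIG"]], "DIG cases\n")
  print(x$stats)
  invisible(x)
}
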