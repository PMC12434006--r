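# End-to-end orchestration: clean -> cohort -> baseline -> signals -> SOC
# aggregation, with CSV exports mirroring the analysis tables and a
# machine-readable run manifest.

#' Assemble a pipeline run configuration
#'
#' @param input Either a directory containing a FAERS-dialect package (see
#'   [read_faers_package()]) or a `"faers_sim_config"` to generate one.
#' @param out_dir Output directory for the CSV exports.
#' @param synonyms Drug synonym tibble.
#' @param pt_soc_map Optional validated `"pt_soc_map"` (derived from the
#'   simulation config when `input` is synthetic and none is given).
#' @param groups Target groups for signal detection.
#' @param ic_method BCPNN variant, `"gamma"` or `"bate"`.
#' @param include_negative_onset Onset handling mode for the quantitative
#'   baseline block.
#' @param display_min_a Display threshold on the a cell for the report
#'   tables (the full-precision CSVs always retain every row).
#' @return List of class `"faers_run_config"`.
#' @export
run_config <- function(input, out_dir,
                       synonyms = default_drug_synonyms(),
                       pt_soc_map = NULL,
                       groups = ici_groups,
                       ic_method = c("gamma", "bate"),
                       include_negative_onset = TRUE,
                       display_min_a = 0) {
  ic_method <- match.arg(ic_method)
  stopifnot(inherits(input, "faers_sim_config") ||
              (is.character(input) && length(input) == 1L))
  if (is.character(input) && !dir.exists(input)) {
    stop("input package directory does not exist: ", input)
  }
  if (inherits(input, "faers_sim_config") && is.null(pt_soc_map)) {
    pt_soc_map <- sim_pt_soc_map(input)
  }
  structure(list(input = input, out_dir = out_dir, synonyms = synonyms,
                 pt_soc_map = pt_soc_map, groups = groups,
                 ic_method = ic_method,
                 include_negative_onset = include_negative_onset,
                 display_min_a = display_min_a),
            class = "faers_run_config")
}

config_hash <- function(cfg) {
  rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
}

#' Run the full signal-detection pipeline
#'
#' Stages, in order: ingest (or simulate), clean (dedup + deletion, funnel
#' logged), cohort assignment, baseline description, country counts, onset
#' summaries, per-group disproportionality signals with FDR, SOC
#' aggregation, IC_025 matrix. Every stage's output is written as CSV under
#' the configured directory along with `manifest.json` (config hash, stage
#' row counts, package version). Any stage failure aborts the run and
#' removes the partial outputs.
#'
#' @param cfg A `"faers_run_config"`.
#' @param quiet Suppress funnel log messages.
#' @return (Invisibly) a list with the in-memory results: `clean`,
#'   `assignments`, `baseline`, `countries`, `signals`, `soc`, `ic_matrix`,
#'   `funnel`, `manifest`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "faers_run_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  created <- character()
  fail <- function(stage, e) {
    unlink(file.path(out, created))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(df, name) {
    readr::write_csv(df, file.path(out, name))
    created <<- c(created, name)
  }

  pkg <- tryCatch({
    if (inherits(cfg$input, "faers_sim_config")) {
      generate_faers_sim(cfg$input)$tables
    } else {
      read_faers_package(cfg$input)
    }
  }, error = function(e) fail("ingest", e))

  cleaned <- tryCatch(clean_faers(pkg, quiet = quiet),
                      error = function(e) fail("clean", e))
  assignments <- tryCatch(
    assign_groups(cleaned$drug, cleaned$demo, cfg$synonyms),
    error = function(e) fail("cohort", e))
  bg_demo <- dplyr::semi_join(cleaned$demo,
                              dplyr::filter(assignments, .data$is_background),
                              by = "primaryid")
  onset <- tryCatch(onset_days(bg_demo, cleaned$drug, cleaned$ther),
                    error = function(e) fail("onset", e))
  baseline <- tryCatch(
    baseline_summary(assignments, cleaned$demo, cleaned$outc, onset,
                     include_negative_onset = cfg$include_negative_onset),
    error = function(e) fail("baseline", e))
  countries <- tryCatch(country_counts(bg_demo),
                        error = function(e) fail("countries", e))
  signals <- tryCatch(
    detect_signals(cleaned$reac, assignments, cfg$groups,
                   ic_method = cfg$ic_method),
    error = function(e) fail("signals", e))
  soc <- if (!is.null(cfg$pt_soc_map)) {
    tryCatch(soc_counts(signals, cfg$pt_soc_map),
             error = function(e) fail("soc", e))
  } else NULL
  icm <- ic_matrix(signals)

  group_sizes <- dplyr::count(assignments, .data$group, name = "n_cases")
  emit(cleaned$funnel, "funnel.csv")
  emit(group_sizes, "group_sizes.csv")
  emit(baseline$table, "baseline.csv")
  emit(baseline$stats, "baseline_stats.csv")
  emit(countries, "countries.csv")
  onset_tbl <- baseline$quantitative$onset
  if (!is.null(onset_tbl)) emit(onset_tbl, "onset_summary.csv")
  emit(tibble::as_tibble(signals), "signals.csv")
  report <- dplyr::filter(tibble::as_tibble(signals), .data$a > cfg$display_min_a)
  num_cols <- names(report)[vapply(report, is.numeric, logical(1))]
  report <- dplyr::mutate(report, dplyr::across(dplyr::all_of(num_cols),
                                                \(x) signif(x, 4)))
  emit(report, "signals_report.csv")
  if (!is.null(soc)) emit(soc, "soc_counts.csv")
  emit(icm, "ic025_matrix.csv")

  manifest <- list(
    package = "faersdispro",
    version = as.character(utils::packageVersion("faersdispro")),
    config_hash = config_hash(cfg),
    n_raw = cleaned$funnel$n[[1]],
    n_clean = cleaned$funnel$n[[nrow(cleaned$funnel)]],
    n_background = sum(assignments$is_background),
    n_signal_pairs = nrow(signals),
    n_positive = sum(signals$positive),
    outputs = created
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(clean = cleaned, assignments = assignments,
                 baseline = baseline, countries = countries,
                 signals = signals, soc = soc, ic_matrix = icm,
                 funnel = cleaned$funnel, manifest = manifest))
}

#' Side-by-side signal comparison of two or more groups
#'
#' One row per PT observed in any of the requested groups; a PT absent from
#' a group keeps explicit `NA` markers in that group's columns.
#'
#' @param signals A `"faers_signals"` tibble.
#' @param groups Two or more group labels present in `signals`.
#' @return Wide tibble keyed by `pt` with per-group `a`, `ror`, `ror_025`,
#'   `ic`, `ic_025`, `positive` columns.
#' @export
compare_groups <- function(signals, groups) {
  missing_g <- setdiff(groups, unique(signals$group))
  if (length(missing_g) > 0L) {
    stop("group(s) not present in signal results: ",
         paste(missing_g, collapse = ", "))
  }
  tibble::as_tibble(signals) |>
    dplyr::filter(.data$group %in% groups) |>
    dplyr::select("pt", "group", "a", "ror", "ror_025", "ic", "ic_025",
                  "positive") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("a", "ror", "ror_025", "ic", "ic_025",
                                       "positive")) |>
    dplyr::arrange(.data$pt)
}

#' Bar plot of positive PT types per SOC
#'
#' @param soc Output of [soc_counts()].
#' @return A ggplot.
#' @export
plot_soc_counts <- function(soc) {
  ggplot2::ggplot(soc, ggplot2::aes(x = .data$n_positive_pt,
                                    y = stats::reorder(.data$soc_name,
                                                       .data$n_positive_pt),
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "positive PT types", y = NULL, fill = "group") +
    ggplot2::theme_minimal()
}
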