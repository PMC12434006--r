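# Disproportionality statistics on the case/non-case fourfold table.
#
# For one (drug group, preferred term) pair within the study background:
#   a = target-PT AE records in the target group
#   b = other AE records in the target group
#   c = target-PT AE records in the other background groups
#   d = other AE records in the other background groups
# Counts are AE records, not patients. The joint signal rule flags a pair
# positive when a >= 3, ROR_025 > 1 and IC_025 > 0.

#' Build fourfold tables for every PT of a target group
#'
#' The comparator is the rest of the six-group study background (case versus
#' non-case within the background), not the full database. One table is
#' emitted per distinct PT observed in the target group.
#'
#' @param reac Cleaned REAC tibble (AE records).
#' @param assignments Output of [assign_groups()].
#' @param target_group One of the background group labels.
#' @return Tibble with `group`, `pt`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(reac, assignments, target_group) {
  stopifnot(target_group %in% ici_groups)
  bg <- dplyr::filter(assignments, .data$is_background)
  ae <- reac |>
    dplyr::inner_join(dplyr::select(bg, "primaryid", "group"), by = "primaryid") |>
    dplyr::filter(!is.na(.data$pt), nzchar(trimws(.data$pt))) |>
    dplyr::mutate(pt = trimws(.data$pt))
  n_target_total <- sum(ae$group == target_group)
  n_other_total <- sum(ae$group != target_group)
  if (n_target_total == 0L) {
    warning("no AE records for group ", target_group, call. = FALSE)
    return(tibble::tibble(group = character(), pt = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), n = integer()))
  }
  if (n_other_total == 0L) {
    warning("single-group background: comparator cells are empty for ",
            target_group, call. = FALSE)
  }
  ae |>
    dplyr::count(.data$pt, in_target = .data$group == target_group) |>
    tidyr::pivot_wider(names_from = "in_target", values_from = "n",
                       values_fill = 0L, names_prefix = "t_") |>
    (\(df) {
      if (!"t_TRUE" %in% names(df)) df$t_TRUE <- 0L
      if (!"t_FALSE" %in% names(df)) df$t_FALSE <- 0L
      df
    })() |>
    dplyr::filter(.data$t_TRUE > 0L) |>
    dplyr::transmute(
      group = target_group,
      pt = .data$pt,
      a = .data$t_TRUE,
      b = n_target_total - .data$t_TRUE,
      c = .data$t_FALSE,
      d = n_other_total - .data$t_FALSE,
      n = .data$a + .data$b + .data$c + .data$d
    ) |>
    dplyr::arrange(dplyr::desc(.data$a), .data$pt)
}

#' Reporting odds ratio with Wald 95% CI
#'
#' ROR = (a d)/(b c); CI = exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' When any cell is zero the Haldane correction (+0.5 to all four cells) is
#' applied and the row flagged; an all-zero table yields `NA` with the flag.
#'
#' @param a,b,c,d Integer vectors of fourfold cell counts (recycled).
#' @return Tibble with `ror`, `ror_025`, `ror_975`, `haldane` (correction
#'   applied) per input table.
#' @examples
#' ror_stats(10, 90, 100, 9900)
#' @export
ror_stats <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  stopifnot(all(c(a, b, c, d) >= 0))
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  allz <- a + b + c + d == 0
  aa <- ifelse(zero, a + 0.5, a); bb <- ifelse(zero, b + 0.5, b)
  cc <- ifelse(zero, c + 0.5, c); dd <- ifelse(zero, d + 0.5, d)
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  out <- tibble::tibble(
    ror = ror,
    ror_025 = exp(log(ror) - 1.96 * se),
    ror_975 = exp(log(ror) + 1.96 * se),
    haldane = zero
  )
  out[allz, c("ror", "ror_025", "ror_975")] <- NA_real_
  out
}

#' Bayesian information component with lower credibility bound
#'
#' Default `"gamma"` formulation: with expected count E = (a+b)(a+c)/N, the
#' shrunken observed-to-expected ratio is IC = log2((a + 0.5)/(E + 0.5)) and
#' IC_025 is log2 of the 2.5% quantile of a Gamma(shape = a + 0.5,
#' rate = E + 0.5) posterior. The `"bate"` variant is the closed-form BCPNN
#' of the original neural-network formulation (Beta-priors centred on
#' independence; IC_025 = E[IC] - 1.96 sd[IC]).
#'
#' @param a,b,c,d Fourfold cell counts (recycled).
#' @param method `"gamma"` (default) or `"bate"`.
#' @return Tibble with `ic`, `ic_025` (bits).
#' @examples
#' ic_stats(10, 90, 100, 9900)
#' @export
ic_stats <- function(a, b, c, d, method = c("gamma", "bate")) {
  method <- match.arg(method)
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  n <- a + b + c + d
  stopifnot(all(n > 0))
  if (method == "gamma") {
    e <- (a + b) * (a + c) / n
    tibble::tibble(
      ic = log2((a + 0.5) / (e + 0.5)),
      ic_025 = log2(stats::qgamma(0.025, shape = a + 0.5, rate = e + 0.5))
    )
  } else {
    ic_bate(a, b, c, d)
  }
}

# Closed-form BCPNN: posterior expectation and variance of IC with the
# standard priors (alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1 and
# gamma chosen so the prior IC is centred on independence).
ic_bate <- function(a, b, c, d) {
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  eic <- (log((a + g11) * (n + al) * (n + be)) -
            log((n + gam) * (a + b + a1) * (a + c + b1))) / log(2)
  vic <- ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
            (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
            (n - a - c + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  tibble::tibble(ic = eic, ic_025 = eic - 1.96 * sqrt(vic))
}

#' Chi-square / Fisher p-value for a fourfold table
#'
#' Pearson chi-square without continuity correction, switching to the
#' two-sided Fisher exact test when any expected cell is below 5. Degenerate
#' margins give p = 1.
#'
#' @param a,b,c,d Fourfold cell counts (recycled).
#' @return Tibble with `p` and `p_method` (`"chisq"`, `"fisher"`,
#'   `"degenerate"`).
#' @export
pt_p_value <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  one <- function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(c(p = 1, fisher = NA))
    }
    n <- sum(m)
    expected <- outer(rowSums(m), colSums(m)) / n
    if (any(expected < 5)) {
      c(p = stats::fisher.test(m)$p.value, fisher = 1)
    } else {
      c(p = suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value),
        fisher = 0)
    }
  }
  res <- purrr::pmap(list(a, b, c, d), one)
  tibble::tibble(
    p = purrr::map_dbl(res, 1),
    p_method = purrr::map_chr(res, \(r) {
      if (is.na(r[[2]])) "degenerate" else if (r[[2]] == 1) "fisher" else "chisq"
    })
  )
}

#' Joint dual-criteria signal flag
#'
#' A (group, PT) pair is a positive signal when the ROR and BCPNN criteria
#' hold simultaneously: a >= 3, ROR_025 > 1, and IC_025 > 0. A
#' not-computable component (NA) makes the flag `FALSE`.
#'
#' @param a Target cell count.
#' @param ror_025 Lower ROR confidence bound.
#' @param ic_025 Lower IC credibility bound.
#' @return Logical vector.
#' @export
signal_flag <- function(a, ror_025, ic_025) {
  flag <- a >= 3 & ror_025 > 1 & ic_025 > 0
  dplyr::coalesce(flag, FALSE)
}

#' Detect disproportionality signals for one or more groups
#'
#' Runs the whole signal battery per target group: fourfold tables over the
#' background comparator, ROR with Wald CI, Bayesian IC with lower bound,
#' chi-square/Fisher p with Benjamini-Hochberg adjustment (one testing
#' family per group), and the joint positivity flag.
#'
#' @param reac Cleaned REAC tibble.
#' @param assignments Output of [assign_groups()].
#' @param groups Target group labels (default: all six background groups).
#' @param ic_method `"gamma"` or `"bate"` (see [ic_stats()]).
#' @return A tibble of class `"faers_signals"` with one row per (group, PT):
#'   cell counts, `ror`, `ror_025`, `ror_975`, `ic`, `ic_025`, `p_raw`,
#'   `p_fdr`, `positive`, plus `haldane` and `p_method` provenance columns
#'   and `n_cases` (patients reporting the PT in the group).
#' @export
detect_signals <- function(reac, assignments, groups = ici_groups,
                           ic_method = c("gamma", "bate")) {
  ic_method <- match.arg(ic_method)
  case_counts <- reac |>
    dplyr::inner_join(dplyr::select(dplyr::filter(assignments, .data$is_background),
                                    "primaryid", "group"),
                      by = "primaryid") |>
    dplyr::filter(!is.na(.data$pt)) |>
    dplyr::mutate(pt = trimws(.data$pt)) |>
    dplyr::distinct(.data$primaryid, .data$group, .data$pt) |>
    dplyr::count(.data$group, .data$pt, name = "n_cases")
  res <- purrr::map(groups, \(g) build_contingency(reac, assignments, g)) |>
    purrr::list_rbind()
  if (nrow(res) == 0L) {
    return(structure(res, class = c("faers_signals", class(res))))
  }
  res <- res |>
    dplyr::bind_cols(ror_stats(res$a, res$b, res$c, res$d)) |>
    dplyr::bind_cols(ic_stats(res$a, res$b, res$c, res$d, method = ic_method)) |>
    dplyr::bind_cols(dplyr::rename(pt_p_value(res$a, res$b, res$c, res$d),
                                   p_raw = "p")) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(p_fdr = stats::p.adjust(.data$p_raw, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(positive = signal_flag(.data$a, .data$ror_025, .data$ic_025)) |>
    dplyr::left_join(case_counts, by = c("group", "pt"))
  structure(res, class = c("faers_signals", class(res)), ic_method = ic_method)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wide IC_025 matrix (PT x group)
#'
#' @param signals A `"faers_signals"` tibble.
#' @param min_a Keep only PTs with `a > min_a` in at least one group
#'   (display filter; 0 keeps everything).
#' @return Tibble with `pt` and one IC_025 column per group.
#' @export
ic_matrix <- function(signals, min_a = 0) {
  keep <- signals |>
    dplyr::group_by(.data$pt) |>
    dplyr::filter(max(.data$a) > min_a) |>
    dplyr::ungroup()
  tidyr::pivot_wider(
    dplyr::select(keep, "pt", "group", "ic_025"),
    names_from = "group", values_from = "ic_025"
  )
}

#' @export
print.faers_signals <- function(x, ...) {
  cat("FAERS disproportionality signals:", nrow(x), "(group, PT) pairs,",
      sum(x$positive), "positive\n")
  NextMethod()
}

#' Tidy a signal table
#'
#' Broom-style accessor returning one row per (group, PT) with the estimate
#' columns; `tidy()` is the stable programmatic surface, the object itself
#' may carry extra provenance columns.
#'
#' @param x A `"faers_signals"` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  tibble::as_tibble(x)[, c("group", "pt", "a", "ror", "ror_025", "ror_975",
                           "ic", "ic_025", "p_raw", "p_fdr", "positive")]
}

#' Summarise a signal run
#'
#' @param x A `"faers_signals"` object.
#' @param ... Unused.
#' @return One row per group: pairs tested, positives, minimum adjusted p.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_pt = dplyr::n(), n_positive = sum(.data$positive),
                     min_p_fdr = suppressWarnings(min(.data$p_fdr)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Heatmap-style plot of IC_025 by PT and group
#'
#' @param object A `"faers_signals"` object.
#' @param min_a Display threshold on the a cell (default 0 shows all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, min_a = 0, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$pt) |>
    dplyr::filter(max(.data$a) > min_a) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pt,
                                   fill = .data$ic_025)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "IC 2.5%") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
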