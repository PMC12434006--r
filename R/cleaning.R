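# Case-version deduplication and deleted-report removal.
#
# FAERS cases accumulate versions: each follow-up gets a new PRIMARYID under
# the same CASEID. The cleaning rule keeps, per CASEID, the version with the
# largest (FDA_DT, PRIMARYID); withdrawn cases named on the quarterly
# deletion lists are then removed by CASEID.

#' Deduplicate multi-version case reports
#'
#' Sorts by CASEID, FDA_DT, PRIMARYID and keeps the last record per CASEID,
#' i.e. the version maximizing FDA receipt date with PRIMARYID as the
#' tie-break. Numeric-looking PRIMARYIDs compare numerically, others
#' lexicographically; partial FDA_DT values order before full dates in the
#' same year(-month). The operation is idempotent and order-independent.
#'
#' @param demo DEMO tibble with `primaryid`, `caseid`, `fda_dt`.
#' @return The kept DEMO rows (one per caseid), with a
#'   [cleaning_report()]-style count tibble in attribute `"funnel"`.
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0L) {
    return(structure(demo, funnel = tibble::tibble(
      stage = c("raw", "deduplicated"), n = c(0L, 0L))))
  }
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  kept <- demo |>
    dplyr::mutate(
      .date_key = faers_date_key(.data$fda_dt),
      .pid_key = pid_num,
      .pid_chr = as.character(.data$primaryid)
    ) |>
    dplyr::arrange(.data$caseid, .data$.date_key,
                   !is.na(.data$.pid_key), .data$.pid_key, .data$.pid_chr) |>
    dplyr::group_by(.data$caseid) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".date_key", -".pid_key", -".pid_chr")
  structure(kept, funnel = tibble::tibble(
    stage = c("raw", "deduplicated"),
    n = c(nrow(demo), nrow(kept))
  ))
}

#' Remove deleted cases
#'
#' Drops every record whose CASEID appears on a deletion list. Lists from all
#' quarters should be unioned before the call: a case withdrawn in a later
#' quarter must not survive from an earlier one.
#'
#' @param demo Deduplicated DEMO tibble.
#' @param deleted_caseids Character vector of withdrawn case ids.
#' @return Surviving DEMO rows with a `"funnel"` count attribute.
#' @export
remove_deleted_cases <- function(demo, deleted_caseids) {
  kept <- dplyr::filter(demo, !(.data$caseid %in% deleted_caseids))
  structure(kept, funnel = tibble::tibble(
    stage = c("deduplicated", "after_deletion"),
    n = c(nrow(demo), nrow(kept))
  ))
}

#' Restrict satellite tables to surviving reports
#'
#' @param tables List with tibbles `drug`, `reac`, `outc`, `ther`.
#' @param primaryids Surviving report ids.
#' @return The list with each table filtered to `primaryid %in% primaryids`.
#' @export
filter_to_cases <- function(tables, primaryids) {
  for (nm in intersect(c("drug", "reac", "outc", "ther"), names(tables))) {
    tables[[nm]] <- dplyr::filter(tables[[nm]], .data$primaryid %in% primaryids)
  }
  tables
}

#' Clean a FAERS package end to end
#'
#' Applies version deduplication then deleted-case removal to DEMO and
#' restricts DRUG/REAC/OUTC/THER to the surviving reports, logging the
#' record funnel (one count per stage) along the way.
#'
#' @param pkg A `"faers_package"` list from [read_faers_package()], or any
#'   list with the same members.
#' @param extra_deleted Additional deleted case ids to union with the
#'   package's own list (e.g. from later quarters).
#' @param quiet Suppress the funnel log messages.
#' @return A list with the cleaned tables (`demo`, `drug`, `reac`, `outc`,
#'   `ther`) and `funnel`, a tibble of per-stage record counts satisfying
#'   raw >= deduplicated >= after_deletion.
#' @export
clean_faers <- function(pkg, extra_deleted = character(), quiet = FALSE) {
  deleted <- union(as.character(pkg$deleted %||% character()),
                   as.character(extra_deleted))
  dedup <- deduplicate_cases(pkg$demo)
  survivors <- remove_deleted_cases(dedup, deleted)
  funnel <- tibble::tibble(
    stage = c("raw", "deduplicated", "after_deletion"),
    n = c(nrow(pkg$demo), nrow(dedup), nrow(survivors))
  )
  if (!quiet) {
    for (i in seq_len(nrow(funnel))) {
      message(sprintf("cleaning: %-15s %d records", funnel$stage[i], funnel$n[i]))
    }
  }
  sat <- filter_to_cases(pkg[c("drug", "reac", "outc", "ther")],
                         survivors$primaryid)
  list(demo = tibble::as_tibble(survivors), drug = sat$drug, reac = sat$reac,
       outc = sat$outc, ther = sat$ther, funnel = funnel)
}
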