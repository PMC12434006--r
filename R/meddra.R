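# PT -> SOC aggregation. MedDRA itself is licensed, so the mapping table is
# user-supplied; PTs may be multiaxial but each must carry exactly one
# primary SOC, and positive signals are counted under that primary SOC only.

#' Read and validate a PT-to-SOC mapping table
#'
#' @param path TSV with columns `pt_name`, `soc_name` and optionally
#'   `pt_code`, `soc_code`, `is_primary_soc` (logical; defaults to TRUE when
#'   absent, i.e. a single-axis map).
#' @return Validated tibble of class `"pt_soc_map"`.
#' @export
read_pt_soc_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  validate_pt_soc_map(map)
}

#' @rdname read_pt_soc_map
#' @param map A data frame with the columns above (for maps built in code).
#' @export
validate_pt_soc_map <- function(map) {
  stopifnot(all(c("pt_name", "soc_name") %in% names(map)))
  map <- tibble::as_tibble(map)
  if (!"pt_code" %in% names(map)) map$pt_code <- NA_character_
  if (!"soc_code" %in% names(map)) map$soc_code <- NA_character_
  if (!"is_primary_soc" %in% names(map)) {
    map$is_primary_soc <- TRUE
  } else {
    map$is_primary_soc <- as.logical(map$is_primary_soc)
  }
  map <- dplyr::mutate(map, pt_key = fold_pt(.data$pt_name))
  dup <- map |>
    dplyr::count(.data$pt_key, .data$soc_name) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate (PT, SOC) pair(s) in map: ",
         paste(head(dup$pt_key, 5), collapse = ", "))
  }
  nprim <- map |>
    dplyr::group_by(.data$pt_key) |>
    dplyr::summarise(k = sum(.data$is_primary_soc))
  bad <- nprim$pt_key[nprim$k != 1L]
  if (length(bad) > 0L) {
    stop("PT(s) without exactly one primary SOC: ",
         paste(head(bad, 5), collapse = ", "))
  }
  structure(map, class = c("pt_soc_map", class(map)))
}

#' Write a PT-to-SOC map back to TSV
#'
#' @param map A validated map.
#' @param path Output path.
#' @export
write_pt_soc_map <- function(map, path) {
  readr::write_tsv(dplyr::select(tibble::as_tibble(map), -dplyr::any_of("pt_key")),
                   path)
  invisible(path)
}

fold_pt <- function(x) stringr::str_squish(tolower(x))

#' Count positive-signal PT types per SOC and group
#'
#' Each positive PT is counted once, under its primary SOC; PTs absent from
#' the map land in an `"UNMAPPED"` bucket with a warning. Counts are of PT
#' types, not of reports.
#'
#' @param signals A `"faers_signals"` tibble.
#' @param map A validated `"pt_soc_map"`.
#' @return Tibble `group`, `soc_name`, `n_positive_pt`.
#' @export
soc_counts <- function(signals, map) {
  primary <- tibble::as_tibble(map) |>
    dplyr::filter(.data$is_primary_soc) |>
    dplyr::select("pt_key", "soc_name")
  pos <- tibble::as_tibble(signals) |>
    dplyr::filter(.data$positive) |>
    dplyr::mutate(pt_key = fold_pt(.data$pt)) |>
    dplyr::left_join(primary, by = "pt_key")
  n_unmapped <- sum(is.na(pos$soc_name))
  if (n_unmapped > 0L) {
    warning(n_unmapped, " positive PT(s) not covered by the SOC map ",
            "counted as UNMAPPED", call. = FALSE)
  }
  pos |>
    dplyr::mutate(soc_name = dplyr::coalesce(.data$soc_name, "UNMAPPED")) |>
    dplyr::distinct(.data$group, .data$soc_name, .data$pt_key) |>
    dplyr::count(.data$group, .data$soc_name, name = "n_positive_pt") |>
    dplyr::arrange(.data$group, dplyr::desc(.data$n_positive_pt))
}
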