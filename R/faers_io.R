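#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data %||%
#' @importFrom stats median quantile sd rpois rbinom runif rlnorm setNames
#' @importFrom utils head
NULL

# Mandatory columns per FAERS table (matched case-insensitively; extra
# columns in a quarter's header are ignored).
faers_columns <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country", "occr_country"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")
)

# Columns that must be present in the header (the rest default to NA when
# absent; real quarters differ in which optional demographics they carry).
faers_required <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt")
)

faers_role_codes <- c("PS", "SS", "C", "I")
faers_outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
faers_age_codes <- c("DEC", "YR", "MON", "WK", "DY", "HR")

#' Read one FAERS quarterly ASCII table
#'
#' FAERS quarterly packages distribute each table as a dollar-delimited text
#' file with a single header line and no quoting or escape mechanism. The
#' reader matches header names case-insensitively, ignores extra columns,
#' turns empty fields into `NA`, and counts (rather than silently drops)
#' data lines that carry fewer fields than the header.
#'
#' @param path Path to the ASCII table file.
#' @param table Table name, one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"THER"`.
#' @return A tibble with the table's standard lower-case columns. The number
#'   of malformed (dropped) lines is attached as attribute `"n_malformed"`
#'   and reported with a warning when nonzero.
#' @examples
#' f <- tempfile()
#' writeLines(c("primaryid$caseid$fda_dt", "101$901$20230301"), f)
#' read_faers_table(f, "DEMO")
#' @export
read_faers_table <- function(path, table = names(faers_columns)) {
  table <- match.arg(toupper(table), names(faers_columns))
  if (!file.exists(path)) {
    stop("cannot read FAERS ", table, " table: no file at '", path, "'")
  }
  lines <- readLines(path, warn = FALSE, encoding = "latin1")
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (length(lines) == 0L) {
    stop("FAERS ", table, " file '", path, "' is empty (no header line)")
  }
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  missing_cols <- setdiff(faers_required[[table]], header)
  if (length(missing_cols) > 0L) {
    stop("FAERS ", table, " header in '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1L]
  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty fields are dropped by strsplit; pad, but a line with
  # fewer separators than the header is malformed
  nsep <- stringr::str_count(body, stringr::fixed("$"))
  ok <- nsep == (length(header) - 1L)
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warning("dropped ", n_malformed, " malformed line(s) in FAERS ",
            table, " file '", path, "'", call. = FALSE)
  }
  parts <- parts[ok]
  cols <- faers_columns[[table]]
  if (length(parts) == 0L) {
    out <- tibble::as_tibble(setNames(rep(list(character()), length(cols)), cols))
  } else {
    mat <- matrix(NA_character_, nrow = length(parts), ncol = length(header))
    for (i in seq_along(parts)) {
      v <- parts[[i]]
      mat[i, seq_along(v)] <- v
    }
    out <- tibble::as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                                      header))[, intersect(header, cols), drop = FALSE]
    for (col in setdiff(cols, names(out))) out[[col]] <- NA_character_
    out <- out[, cols]
    out <- dplyr::mutate(out, dplyr::across(dplyr::everything(),
                                            ~ dplyr::na_if(trimws(.x), "")))
  }
  if ("age" %in% names(out)) out$age <- suppressWarnings(as.numeric(out$age))
  if ("drug_seq" %in% names(out)) out$drug_seq <- suppressWarnings(as.integer(out$drug_seq))
  if ("dsg_drug_seq" %in% names(out)) {
    out$dsg_drug_seq <- suppressWarnings(as.integer(out$dsg_drug_seq))
  }
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read a FAERS quarterly package from a directory
#'
#' Expects files `DEMO.txt`, `DRUG.txt`, `REAC.txt` (mandatory) and
#' `OUTC.txt`, `THER.txt`, `DELETED.txt` (optional; missing ones yield empty
#' tables) in `dir`. This is the layout [write_faers_package()] emits; for
#' real quarterly archives point the individual paths at the extracted
#' `ascii/` members.
#'
#' @param dir Directory containing the package files.
#' @param paths Optional named list overriding individual file paths
#'   (names among DEMO, DRUG, REAC, OUTC, THER, DELETED).
#' @return A list of class `"faers_package"` with tibbles `demo`, `drug`,
#'   `reac`, `outc`, `ther` and a character vector `deleted` of case ids.
#' @export
read_faers_package <- function(dir, paths = list()) {
  pick <- function(name) paths[[name]] %||% file.path(dir, paste0(name, ".txt"))
  need <- c("DEMO", "DRUG", "REAC")
  for (nm in need) {
    if (!file.exists(pick(nm))) {
      stop("FAERS package in '", dir, "' lacks mandatory table ", nm)
    }
  }
  opt_read <- function(nm) {
    p <- pick(nm)
    if (file.exists(p)) read_faers_table(p, nm) else {
      tibble::as_tibble(setNames(rep(list(character()), length(faers_columns[[nm]])),
                                 faers_columns[[nm]]))
    }
  }
  out <- list(
    demo = read_faers_table(pick("DEMO"), "DEMO"),
    drug = read_faers_table(pick("DRUG"), "DRUG"),
    reac = read_faers_table(pick("REAC"), "REAC"),
    outc = opt_read("OUTC"),
    ther = opt_read("THER"),
    deleted = load_deleted_cases(pick("DELETED"))
  )
  structure(out, class = c("faers_package", "list"))
}

#' Read a deleted-case list
#'
#' Quarterly FAERS packages from 2019Q1 onwards ship a list of case ids whose
#' reports were withdrawn; earlier quarters have none, so a missing file is
#' tolerated (empty set plus a warning).
#'
#' @param path Path to a text file with one case id per line (a non-numeric
#'   first line is treated as a header).
#' @return Character vector of distinct case ids.
#' @export
load_deleted_cases <- function(path) {
  if (!file.exists(path)) {
    warning("no deleted-case list at '", path,
            "'; assuming none (packages before 2019Q1 ship no list)",
            call. = FALSE)
    return(character())
  }
  ids <- trimws(readLines(path, warn = FALSE))
  if (length(ids) > 0L && grepl("[^0-9]", ids[[1L]]) && nzchar(ids[[1L]])) {
    ids <- ids[-1L]
  }
  unique(ids[nzchar(ids)])
}

#' Convert a reported age to years
#'
#' FAERS ages carry a unit code: DEC (decades), YR, MON, WK, DY, HR. A
#' missing code with a present age is read as years (the dominant FAERS
#' convention); negative ages become missing with a warning.
#'
#' @param age Numeric vector of reported ages.
#' @param age_cod Character vector of unit codes (may be `NA`).
#' @return Numeric vector of ages in years.
#' @examples
#' normalize_age(c(6, 18, 65), c("DEC", "MON", NA))
#' @export
normalize_age <- function(age, age_cod) {
  stopifnot(length(age) == length(age_cod) || length(age_cod) == 1L)
  age_cod <- rep_len(toupper(trimws(as.character(age_cod))), length(age))
  neg <- !is.na(age) & age < 0
  if (any(neg)) {
    warning(sum(neg), " negative age value(s) set to missing", call. = FALSE)
    age[neg] <- NA_real_
  }
  factor_for <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_for[age_cod])
  f[is.na(age_cod) | age_cod == ""] <- 1     # missing code: assume years
  f[!is.na(age_cod) & age_cod != "" & is.na(f)] <- NA_real_
  age * f
}

# Partial FAERS dates ("YYYY", "YYYYMM", "YYYYMMDD") -> components.
# Missing month/day stay NA; full dates additionally get a Date value.
faers_date_parts <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x %||% "")] <- NA_character_
  year <- ifelse(is.na(x), NA_integer_, as.integer(substr(x, 1, 4)))
  month <- ifelse(!is.na(x) & nchar(x) >= 6, as.integer(substr(x, 5, 6)), NA_integer_)
  day <- ifelse(!is.na(x) & nchar(x) == 8, as.integer(substr(x, 7, 8)), NA_integer_)
  full <- !is.na(day) & !is.na(month) & !is.na(year)
  date <- rep(as.Date(NA), length(x))
  if (any(full)) {
    date[full] <- suppressWarnings(
      as.Date(sprintf("%04d-%02d-%02d", year[full], month[full], day[full]))
    )
  }
  tibble::tibble(year = year, month = month, day = day, date = date)
}

# Sortable numeric key for partial dates: missing month/day count as 0 so a
# partial date orders before any full date of the same year(-month). Used
# only for the deduplication max rule, never for arithmetic.
faers_date_key <- function(x) {
  p <- faers_date_parts(x)
  ifelse(is.na(p$year), -Inf,
         p$year * 10000 + dplyr::coalesce(p$month, 0L) * 100 +
           dplyr::coalesce(p$day, 0L))
}

sanitize_field <- function(x) {
  x <- gsub("$", "/", as.character(x), fixed = TRUE)
  x[is.na(x)] <- ""
  x
}

write_one_table <- function(df, path, table) {
  cols <- faers_columns[[table]]
  for (col in setdiff(cols, names(df))) df[[col]] <- NA_character_
  df <- df[, cols, drop = FALSE]
  body <- do.call(paste, c(lapply(df, sanitize_field), sep = "$"))
  writeLines(c(paste(cols, collapse = "$"), body), path)
  invisible(path)
}

#' Write a FAERS-dialect quarterly package
#'
#' Emits DEMO/DRUG/REAC/OUTC/THER plus a deleted-case list in the exact
#' dollar-delimited dialect that [read_faers_table()] consumes. The dialect
#' has no escape mechanism, so literal `$` inside free text is replaced by
#' `/`. Re-reading the written package reproduces every (sanitized) field.
#'
#' @param tables A list with tibbles `demo`, `drug`, `reac` and optionally
#'   `outc`, `ther`, plus an optional character vector `deleted`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_faers_package <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create package directory '", dir, "'")
  empty <- function(nm) {
    tibble::as_tibble(setNames(rep(list(character()), length(faers_columns[[nm]])),
                               faers_columns[[nm]]))
  }
  write_one_table(tables$demo %||% empty("DEMO"), file.path(dir, "DEMO.txt"), "DEMO")
  write_one_table(tables$drug %||% empty("DRUG"), file.path(dir, "DRUG.txt"), "DRUG")
  write_one_table(tables$reac %||% empty("REAC"), file.path(dir, "REAC.txt"), "REAC")
  write_one_table(tables$outc %||% empty("OUTC"), file.path(dir, "OUTC.txt"), "OUTC")
  write_one_table(tables$ther %||% empty("THER"), file.path(dir, "THER.txt"), "THER")
  writeLines(as.character(tables$deleted %||% character()),
             file.path(dir, "DELETED.txt"))
  invisible(dir)
}
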