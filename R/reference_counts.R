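# Published reference tabulations used as worked-example inputs.

#' Reference baseline counts for ICI mono- versus dual therapy
#'
#' Patient-level baseline contingency counts from a published FAERS analysis
#' of checkpoint-inhibitor therapy (2011Q1-2024Q2; 42,233 single-agent and
#' 12,819 dual-therapy cases). Each element is a counts matrix with one
#' column per arm (`sICI`, `DIG`), suitable for [cramers_v()]: reproducing
#' the published association statistics from these printed counts is the
#' package's main numerical cross-check.
#'
#' @return Named list of integer matrices: `gender`, `age`, `serious`,
#'   `hospitalization`, `death`, `disability`, `reporting_year`, `reporter`.
#' @examples
#' cramers_v(ici_baseline_counts()$gender)
#' @export
ici_baseline_counts <- function() {
  m <- function(rows, sici, dig) {
    matrix(c(sici, dig), ncol = 2,
           dimnames = list(rows, c("sICI", "DIG")))
  }
  list(
    gender = m(c("Female", "Male", "Unspecified"),
               c(11721, 21617, 8895), c(3691, 6863, 2265)),
    age = m(c("<18", "18-44", "45-64", "65-74", ">=75", "Unspecified"),
            c(82, 1654, 8787, 7678, 4776, 19256),
            c(28, 803, 3314, 2745, 1738, 4191)),
    reporting_year = m(as.character(2011:2024),
                       c(263, 839, 649, 972, 1802, 4648, 5788, 4970, 5368,
                         4500, 4256, 3745, 2801, 1632),
                       c(0, 0, 3, 9, 113, 381, 741, 1068, 1671, 1683, 1754,
                         2056, 1889, 1451)),
    reporter = m(c("Consumer", "Lawyer", "Unspecified",
                   "Other health-professional", "Pharmacist", "Physician"),
                 c(13625, 20, 816, 6856, 7425, 13491),
                 c(1987, 6, 29, 1756, 3310, 5731)),
    serious = m(c("Serious", "Non-Serious"),
                c(35686, 6547), c(11664, 1155)),
    hospitalization = m(c("Yes", "No"), c(10091, 32142), c(4845, 7974)),
    death = m(c("Yes", "No"), c(12985, 29248), c(3238, 9581)),
    disability = m(c("Yes", "No"), c(509, 41724), c(143, 12676))
  )
}
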