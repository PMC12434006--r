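# Shared fixtures, built in code at test time.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A tiny hand-checkable package: 5 cases (one with a superseded version),
# one deleted case, two cohort groups.
toy_package_lines <- function() {
  list(
    demo = c(
      "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country$occr_country",
      "101$901$20230101$20230206$65$YR$F$MD$US$US",   # superseded version
      "102$901$20230301$20230206$65$YR$F$MD$US$US",   # kept version
      "201$902$20230115$$6$DEC$M$CN$JP$JP",
      "301$903$20230120$20230110$54$YR$M$PH$FR$",
      "401$904$20230201$$18$MON$F$OT$US$US",
      "501$905$20230210$$$$$$GB$GB"                    # deleted later
    ),
    drug = c(
      "primaryid$drug_seq$role_cod$drugname$prod_ai",
      "101$1$PS$OPDIVO$NIVOLUMAB",
      "102$1$PS$OPDIVO$NIVOLUMAB",
      "201$1$PS$Nivolumab 240 MG$NIVOLUMAB",
      "301$1$PS$YERVOY$IPILIMUMAB",
      "301$2$SS$OPDIVO$NIVOLUMAB",
      "401$1$PS$PEMBROLIZUMAB$",
      "501$1$PS$IMFINZI$DURVALUMAB"
    ),
    reac = c(
      "primaryid$pt",
      "102$Colitis", "102$Pyrexia",
      "201$Colitis",
      "301$Myocarditis", "301$Colitis",
      "401$Rash",
      "501$Pyrexia"
    ),
    outc = c(
      "primaryid$outc_cod",
      "102$HO", "102$OT",
      "301$DE"
    ),
    ther = c(
      "primaryid$dsg_drug_seq$start_dt$end_dt",
      "102$1$20230101$",
      "301$1$20230301$"
    ),
    deleted = c("905")
  )
}

toy_package_dir <- function(env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  lines <- toy_package_lines()
  writeLines(lines$demo, file.path(d, "DEMO.txt"))
  writeLines(lines$drug, file.path(d, "DRUG.txt"))
  writeLines(lines$reac, file.path(d, "REAC.txt"))
  writeLines(lines$outc, file.path(d, "OUTC.txt"))
  writeLines(lines$ther, file.path(d, "THER.txt"))
  writeLines(lines$deleted, file.path(d, "DELETED.txt"))
  d
}

# Brute-force chi-square statistic: explicit sum((O - E)^2 / E).
brute_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - expected)^2 / expected)
}

# Brute-force ROR and Wald CI evaluated from first principles.
brute_ror <- function(a, b, c, d) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, lo = exp(log(ror) - 1.96 * se), hi = exp(log(ror) + 1.96 * se))
}

random_2x2 <- function() {
  matrix(sample(1:500, 4, replace = TRUE), nrow = 2)
}
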