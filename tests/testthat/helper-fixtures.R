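# In-code fixtures shared across test files.

write_demo_fixture <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

make_cases <- function(primaryid, caseid = primaryid, ...) {
  extra <- list(...)
  dt <- data.table::data.table(
    primaryid = as.numeric(primaryid), caseid = as.numeric(caseid),
    sex = "female", age_years = 50, reporter_type = "consumer",
    reporter_country = "US", quarter = "2020Q1")
  for (nm in names(extra)) dt[[nm]] <- extra[[nm]]
  dt
}

# hand-built dataset: exposed report 1 carries events {X, X, Y},
# report 2 (unexposed) carries {X, Z}
toy_dataset <- function() {
  cases <- make_cases(1:2)
  drugs <- data.table::data.table(
    primaryid = c(1, 2), drugname = c("ALPHADRUG", "OTHERDRUG"),
    prod_ai = c("ALPHADRUG", "OTHERDRUG"), role_cod = c("PS", "PS"))
  events <- data.table::data.table(
    primaryid = c(1, 1, 1, 2, 2), pt = c("X", "X", "Y", "X", "Z"))
  build_dataset(cases, drugs, events,
                list(drug_query("alpha", "alphadrug")))
}

# screening-result rows with prescribed flags, for reporting tests
fake_results <- function(n, positive_idx = integer(0)) {
  res <- signal_stats_table(data.frame(
    label = sprintf("pt%02d", seq_len(n)),
    a = 5 + seq_len(n), b = 100, c = 50, d = 10000))
  data.table::setnames(res, "label", "pt")
  res[, drug_label := "drugX"]
  res
}

pt_soc_map_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("pt\tsoc", rows), path)
  path
}
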