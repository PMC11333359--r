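#' @name preprocess
#' @title Case deduplication and analysis-dataset construction
#' @description
#' FAERS re-submits cases across quarters, so the pooled raw tables contain
#' duplicates. Two rules clean them: (1) a `primaryid` occurring on more than
#' one raw row is treated as a data error and every row bearing it is
#' excluded; (2) among rows sharing a `caseid`, only the row with the largest
#' `primaryid` (the latest version) is kept. The analysis dataset then pairs
#' the deduplicated cases with their reaction terms and, per queried drug, an
#' exposure set: reports where the drug is the primary suspect (role code
#' `PS`) matched by name.
NULL

#' Define a drug query
#'
#' @param label short label used in outputs, e.g. `"suvorexant"`.
#' @param generic_names,brand_names character vectors of names matched
#'   (case-insensitively, as substrings) against `drugname` and `prod_ai`.
#'   At least one non-empty name overall.
#' @return an object of class `drug_query`.
#' @export
drug_query <- function(label, generic_names = character(), brand_names = character()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(trimws(label)))
  names_all <- trimws(c(generic_names, brand_names))
  if (length(names_all) == 0L || any(!nzchar(names_all))) {
    stop("drug_query '", label, "': needs at least one name, all non-empty")
  }
  structure(list(label = label,
                 generic_names = trimws(generic_names),
                 brand_names = trimws(brand_names)),
            class = "drug_query")
}

#' @export
print.drug_query <- function(x, ...) {
  cat("<drug_query>", x$label, "\n  names:",
      paste(c(x$generic_names, x$brand_names), collapse = ", "), "\n")
  invisible(x)
}

#' Deduplicate report cases
#'
#' Rule order matters and is fixed: `primaryid` collisions are detected on
#' the raw input and all bearers excluded first (a collision marks the rows
#' as invalid, which trumps version selection), then the max-`primaryid`-per-
#' `caseid` rule keeps the latest version of each case. The output is sorted
#' by `primaryid`, making the result invariant to input row order; the
#' operation is idempotent.
#'
#' @param cases a `data.table`/data.frame of cases with numeric `primaryid`
#'   and `caseid` columns (from [parse_demo()]).
#' @return a list: `cases` (surviving rows), `log` (named counts:
#'   `n_input`, `n_primaryid_collision`, `n_caseid_superseded`, `n_output`).
#' @export
deduplicate_cases <- function(cases) {
  cases <- as.data.table(cases)
  n_input <- nrow(cases)
  if (n_input == 0L) {
    return(list(cases = cases,
                log = c(n_input = 0L, n_primaryid_collision = 0L,
                        n_caseid_superseded = 0L, n_output = 0L)))
  }
  pid_n <- cases[, .N, by = primaryid]
  colliding <- pid_n[N > 1L, primaryid]
  step1 <- cases[!primaryid %in% colliding]
  n_collision <- n_input - nrow(step1)

  setorder(step1, caseid, -primaryid)
  keep <- step1[!duplicated(caseid)]
  n_superseded <- nrow(step1) - nrow(keep)
  setorder(keep, primaryid)

  list(cases = keep,
       log = c(n_input = n_input,
               n_primaryid_collision = n_collision,
               n_caseid_superseded = n_superseded,
               n_output = nrow(keep)))
}

#' Match a drug query against drug entries
#'
#' A report is matched iff some entry for it has role code `PS` (primary
#' suspect) and its `drugname` or `prod_ai`, lowercased and trimmed, contains
#' any query name as a substring. No fuzzy matching or spelling
#' normalization: the query names are taken as exact keywords.
#'
#' @param entries drug entries: `data.table` with `primaryid`, `drugname`,
#'   optionally `prod_ai`, and `role_cod` columns.
#' @param query a [drug_query()].
#' @return sorted numeric vector of matched `primaryid`s.
#' @export
match_drug <- function(entries, query) {
  if (!inherits(query, "drug_query")) stop("query must be a drug_query")
  entries <- as.data.table(entries)
  needles <- .norm_term(c(query$generic_names, query$brand_names))
  needles <- needles[nzchar(needles)]
  if (length(needles) == 0L) stop("malformed query: no usable names")
  if (nrow(entries) == 0L) return(numeric(0))

  ps <- entries[toupper(trimws(role_cod)) == "PS"]
  if (nrow(ps) == 0L) return(numeric(0))
  hay <- .norm_term(ps$drugname)
  if ("prod_ai" %in% names(ps)) {
    ai <- .norm_term(ps$prod_ai)
    ai[is.na(ai)] <- ""
    hay <- paste(hay, ai, sep = "\x01")
  }
  hit <- rep(FALSE, length(hay))
  for (nd in needles) hit <- hit | grepl(nd, hay, fixed = TRUE)
  sort(unique(as.numeric(ps$primaryid[hit])))
}

#' Build the analysis dataset
#'
#' Deduplicates the cases, restricts event entries to surviving reports
#' (dropping empty preferred terms), and computes the primary-suspect
#' exposure set for each query. Exposure sets may overlap across drugs: a
#' report naming two queried drugs as primary suspect counts in both.
#'
#' @param cases typed cases from [parse_demo()] (all quarters pooled;
#'   deduplication is global).
#' @param drug_entries `data.table` with `primaryid`, `drugname`,
#'   optionally `prod_ai`, `role_cod`.
#' @param event_entries `data.table` with `primaryid`, `pt`.
#' @param queries list of [drug_query()] objects (possibly empty).
#' @return an object of class `faers_dataset`: list with `cases`, `events`,
#'   `exposure` (named list label -> numeric primaryid vector), `dedup_log`.
#' @export
build_dataset <- function(cases, drug_entries, event_entries, queries = list()) {
  if (inherits(queries, "drug_query")) queries <- list(queries)
  dd <- deduplicate_cases(cases)
  surviving <- dd$cases$primaryid

  events <- as.data.table(event_entries)
  if (nrow(events)) {
    events <- events[, .(primaryid = as.numeric(primaryid), pt = trimws(pt))]
    events <- events[nzchar(pt) & primaryid %in% surviving]
  } else {
    events <- data.table(primaryid = numeric(0), pt = character(0))
  }

  drugs <- as.data.table(drug_entries)
  if (nrow(drugs)) drugs <- drugs[as.numeric(primaryid) %in% surviving]

  exposure <- list()
  for (q in queries) {
    exposure[[q$label]] <- match_drug(drugs, q)
  }

  structure(list(cases = dd$cases, events = events, exposure = exposure,
                 dedup_log = dd$log, queries = queries),
            class = "faers_dataset")
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("<faers_dataset>\n",
      " cases:  ", nrow(x$cases), " (from ", x$dedup_log[["n_input"]],
      " raw rows; ", x$dedup_log[["n_primaryid_collision"]],
      " excluded by primaryid collision, ",
      x$dedup_log[["n_caseid_superseded"]], " superseded case versions)\n",
      " events: ", nrow(x$events), " PT mentions\n", sep = "")
  for (lab in names(x$exposure)) {
    cat("  exposure[", lab, "]: ", length(x$exposure[[lab]]), " reports\n",
        sep = "")
  }
  invisible(x)
}
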