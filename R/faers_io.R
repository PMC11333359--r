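#' @name faers_io
#' @title FAERS quarterly ASCII table input/output
#' @description
#' The public FAERS database ships as quarterly ASCII files, one table per
#' file (DEMO, DRUG, REAC, OUTC, RPSR, THER, INDI), dollar-delimited with a
#' header row. [read_faers_table()] reads one such file into a raw
#' string-valued `data.table`; [parse_demo()] types the demographic table
#' into report cases; [write_delimited()] writes any pipeline output back to
#' a delimited text file.
NULL

.FAERS_TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI")

#' Read one FAERS-style quarterly ASCII table
#'
#' Lines whose field count disagrees with the header are skipped with a
#' warning each; the number skipped is recorded in the `n_skipped` attribute.
#' Values are kept as raw strings (empty string = missing); nothing is
#' coerced. Input is decoded as Latin-1 (real FAERS files are not clean
#' UTF-8; any byte decodes, so no replacement errors occur).
#'
#' @param path path to the file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"RPSR"`,
#'   `"THER"`, `"INDI"`.
#' @param quarter quarter label matching `YYYYQ[1-4]`, e.g. `"2014Q3"`.
#' @param delim field delimiter, a single character; FAERS uses `"$"`.
#' @return a `data.table` of character columns named from the header, with
#'   attributes `table_kind`, `quarter`, `n_skipped`.
#' @export
read_faers_table <- function(path, table_kind, quarter, delim = "$") {
  table_kind <- match.arg(table_kind, .FAERS_TABLE_KINDS)
  .assert_quarter(quarter)
  if (!file.exists(path)) stop("FAERS table file not found: ", path)
  if (nchar(delim) != 1L) stop("delim must be a single character")

  con <- file(path, encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header line): ", path)

  # strsplit drops a trailing empty field; a sentinel preserves it
  sentinel <- "\x01"
  split1 <- function(x) {
    parts <- strsplit(paste0(x, delim, sentinel), delim, fixed = TRUE)
    lapply(parts, function(p) p[-length(p)])
  }
  header <- split1(lines[1L])[[1L]]
  if (anyDuplicated(header)) stop("duplicate column names in header: ", path)
  ncol <- length(header)

  body <- lines[-1L]
  out <- if (length(body) == 0L) {
    setNames(replicate(ncol, character(0), simplify = FALSE), header)
  } else {
    parts <- split1(body)
    nf <- lengths(parts)
    bad <- which(nf != ncol)
    for (i in bad) {
      warning(sprintf("%s line %d: %d fields, expected %d; line skipped",
                      basename(path), i + 1L, nf[i], ncol), call. = FALSE)
    }
    if (length(bad)) parts <- parts[-bad]
    setNames(data.table::transpose(parts), header)
  }
  dt <- as.data.table(out)
  setattr(dt, "table_kind", table_kind)
  setattr(dt, "quarter", quarter)
  setattr(dt, "n_skipped", if (length(body)) length(body) - nrow(dt) else 0L)
  dt[]
}

#' Column-name conventions for the DEMO table
#'
#' FAERS column names drifted across years (e.g. `gndr_cod` became `sex`);
#' aliases are tried in order and the first present wins. Supply a custom
#' list to handle a quarter's schema explicitly rather than relying on
#' position.
#'
#' @param primaryid,caseid,sex,age,age_cod,occp_cod,reporter_country,quarter
#'   character vectors of candidate column names, tried in order.
#' @return a named list of alias vectors, for [parse_demo()].
#' @export
demo_conventions <- function(primaryid = "primaryid",
                             caseid = "caseid",
                             sex = c("sex", "gndr_cod"),
                             age = "age",
                             age_cod = "age_cod",
                             occp_cod = "occp_cod",
                             reporter_country = "reporter_country",
                             quarter = "quarter") {
  list(primaryid = primaryid, caseid = caseid, sex = sex, age = age,
       age_cod = age_cod, occp_cod = occp_cod,
       reporter_country = reporter_country, quarter = quarter)
}

# age-unit codebook: multiply the reported age by this to get years
.AGE_UNIT_FACTOR <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                      DY = 1 / 365.25, HR = 1 / 8766)

# occupation codebook: Consumer / Health-professional / Other-Missing
.OCCP_CONSUMER <- "CN"
.OCCP_HEALTH <- c("MD", "PH", "OT", "HP", "RN")

#' Parse a raw DEMO table into typed report cases
#'
#' Maps the coded demographic fields into the analysis vocabulary:
#' sex `F`/`M` to `female`/`male` (anything else missing); age converted to
#' years via the unit code (`DEC` decades, `YR` years, `MON` months, `WK`
#' weeks, `DY` days, `HR` hours; unknown unit or age outside \[0, 130\]
#' becomes missing); occupation code `CN` to `consumer`, `MD`/`PH`/`OT`/
#' `HP`/`RN` to `health_professional`, everything else (including empty) to
#' `other_missing`. Rows whose `primaryid` or `caseid` is not numeric are
#' dropped with a warning. No field of the output is invented: every
#' non-missing value is a deterministic function of its input row.
#'
#' @param rows a raw DEMO `data.table` from [read_faers_table()] (or any
#'   table with the configured columns).
#' @param conventions column-name aliases, see [demo_conventions()].
#' @return a `data.table` of cases: `primaryid`, `caseid` (numeric
#'   identifiers), `sex`, `age_years`, `reporter_type`, `reporter_country`
#'   (`NA` = missing), `quarter`.
#' @export
parse_demo <- function(rows, conventions = demo_conventions()) {
  rows <- as.data.table(rows)
  cols <- names(rows)
  col_of <- function(field) .resolve_alias(conventions[[field]], cols)
  need <- c("primaryid", "caseid")
  for (f in need) {
    if (is.na(col_of(f))) stop("DEMO table lacks a ", f, " column (aliases: ",
                               paste(conventions[[f]], collapse = ", "), ")")
  }
  get_col <- function(field) {
    cn <- col_of(field)
    if (is.na(cn)) rep(NA_character_, nrow(rows)) else as.character(rows[[cn]])
  }

  pid <- suppressWarnings(as.numeric(get_col("primaryid")))
  cid <- suppressWarnings(as.numeric(get_col("caseid")))
  bad <- is.na(pid) | is.na(cid)
  if (any(bad)) {
    warning(sprintf("parse_demo: dropped %d row(s) with non-numeric primaryid/caseid",
                    sum(bad)), call. = FALSE)
  }

  sex_raw <- toupper(trimws(get_col("sex")))
  sex <- fcase(sex_raw == "F", "female",
               sex_raw == "M", "male",
               default = "missing")

  age_num <- suppressWarnings(as.numeric(get_col("age")))
  unit <- toupper(trimws(get_col("age_cod")))
  factor <- .AGE_UNIT_FACTOR[unit]
  age_years <- age_num * as.numeric(factor)
  age_years[is.na(factor)] <- NA_real_
  age_years[!is.na(age_years) & (age_years < 0 | age_years > 130)] <- NA_real_

  occ <- toupper(trimws(get_col("occp_cod")))
  reporter_type <- fcase(occ == .OCCP_CONSUMER, "consumer",
                         occ %chin% .OCCP_HEALTH, "health_professional",
                         default = "other_missing")

  country <- trimws(get_col("reporter_country"))
  country[is.na(country) | country == ""] <- NA_character_

  qtr_attr <- attr(rows, "quarter", exact = TRUE)
  quarter <- if (!is.null(qtr_attr)) rep(qtr_attr, nrow(rows)) else {
    q <- get_col("quarter")
    q[is.na(q) | q == ""] <- NA_character_
    q
  }

  out <- data.table(primaryid = pid, caseid = cid, sex = sex,
                    age_years = age_years, reporter_type = reporter_type,
                    reporter_country = country, quarter = quarter)
  out[!bad]
}

#' Write tabular records as delimited text
#'
#' Header plus one line per record; missing values are written as empty
#' fields; output is bit-stable for a fixed input and schema (no quoting,
#' fixed numeric formatting via `data.table::fwrite`).
#'
#' @param records a data.frame/data.table of records sharing a schema.
#' @param path output path.
#' @param delim single-character delimiter (default tab).
#' @return the path, invisibly.
#' @export
write_delimited <- function(records, path, delim = "\t") {
  if (nchar(delim) != 1L) stop("delim must be a single character")
  records <- as.data.table(records)
  ok <- tryCatch({
    fwrite(records, path, sep = delim, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}
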