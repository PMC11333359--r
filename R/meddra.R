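#' @name meddra
#' @title Preferred-term to system-organ-class mapping
#' @description
#' MedDRA itself is licensed and cannot ship with the package; the user
#' supplies a two-column TSV mapping each preferred term (PT) to its primary
#' system organ class (SOC). Joining is by trimmed, case-folded PT; the
#' emitted tables preserve the map's original SOC spelling.
NULL

#' Load a PT -> SOC mapping table
#'
#' @param path TSV file with a header and columns `pt`, `soc`.
#' @param version_label free-text label recorded with the map (e.g. the
#'   MedDRA version the table was derived from).
#' @return an object of class `pt_soc_map`.
#' @details Duplicate identical rows are collapsed; duplicate PTs mapping to
#'   different SOCs are an error (each PT has exactly one primary SOC), with
#'   the offending PT(s) named.
#' @export
load_pt_soc_map <- function(path, version_label = "unspecified") {
  if (!file.exists(path)) stop("PT/SOC map file not found: ", path)
  m <- fread(path, sep = "\t", colClasses = "character", header = TRUE)
  if (!all(c("pt", "soc") %in% names(m))) {
    stop("PT/SOC map must have columns 'pt' and 'soc'")
  }
  m <- unique(m[, .(pt_norm = .norm_term(pt), soc = trimws(soc))])
  conflicts <- m[, .N, by = pt_norm][N > 1L, pt_norm]
  if (length(conflicts)) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(conflicts, collapse = ", "))
  }
  structure(list(entries = m, version_label = version_label),
            class = "pt_soc_map")
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat("<pt_soc_map> ", nrow(x$entries), " PTs, ",
      length(unique(x$entries$soc)), " SOCs (version: ",
      x$version_label, ")\n", sep = "")
  invisible(x)
}

#' Look up the SOC of preferred terms
#'
#' @param map a [load_pt_soc_map()] object.
#' @param pt character vector of preferred terms.
#' @return character vector of SOCs; `NA` where unmapped.
#' @export
soc_of <- function(map, pt) {
  if (!inherits(map, "pt_soc_map")) stop("map must be a pt_soc_map")
  map$entries$soc[match(.norm_term(pt), map$entries$pt_norm)]
}

#' Aggregate positive signals by system organ class
#'
#' Frequencies count report-event occurrences: per drug, a SOC's frequency
#' is the sum of the `a` cells of the positive PTs mapping to it (so a
#' drug's SOC total can exceed its report count — each report can carry
#' several events). Percentages are against the same per-drug total,
#' rounded half-up to 2 decimals. PTs absent from the map are collected
#' under `"UNMAPPED"` and reported via a message.
#'
#' @param results screening results ([screen_signals()] output, one or
#'   several drugs row-bound); only rows with `positive == TRUE` are used.
#' @param map a [load_pt_soc_map()] object.
#' @return `data.table` with `drug_label`, `soc`, `frequency`, `percent`,
#'   sorted by drug then descending frequency; empty when there are no
#'   positive signals.
#' @export
aggregate_soc <- function(results, map) {
  results <- as.data.table(results)
  pos <- results[positive == TRUE]
  if (nrow(pos) == 0L) {
    return(data.table(drug_label = character(0), soc = character(0),
                      frequency = numeric(0), percent = numeric(0)))
  }
  pos[, soc := soc_of(map, pt)]
  n_unmapped <- sum(is.na(pos$soc))
  if (n_unmapped > 0L) {
    message("aggregate_soc: ", n_unmapped,
            " positive PT(s) not in the map, collected under UNMAPPED")
    pos[is.na(soc), soc := "UNMAPPED"]
  }
  out <- pos[, .(frequency = sum(a)), by = .(drug_label, soc)]
  out[, percent := percent_of(frequency, sum(frequency)), by = drug_label]
  setorder(out, drug_label, -frequency, soc)
  out[]
}
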