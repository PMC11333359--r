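#' @name reporting
#' @title Result surfaces: demographics, ranked signals, method comparison,
#'   intersections, clustered signal matrix
NULL

.AGE_BIN_LEVELS <- c("<18", "18-64.9", "65-85", ">85", "missing")

.age_bin <- function(age_years) {
  fcase(is.na(age_years), "missing",
        age_years < 18, "<18",
        age_years < 65, "18-64.9",
        age_years <= 85, "65-85",
        default = ">85")
}

.demo_block <- function(cases, group) {
  total <- nrow(cases)
  blk <- function(block, level, count) {
    data.table(group = group, block = block, level = level,
               count = as.numeric(count), total = total,
               percent = if (total > 0) percent_of(count, total) else NA_real_)
  }
  count_levels <- function(x, levels) {
    vapply(levels, function(l) sum(x == l), numeric(1))
  }
  sex <- count_levels(cases$sex, c("female", "male", "missing"))
  age <- count_levels(.age_bin(cases$age_years), .AGE_BIN_LEVELS)
  rep_type <- count_levels(cases$reporter_type,
                           c("consumer", "health_professional", "other_missing"))
  rbind(blk("sex", names(sex), sex),
        blk("age", names(age), age),
        blk("reporter_type", names(rep_type), rep_type))
}

.country_block <- function(cases, group, top_countries) {
  total <- nrow(cases)
  cty <- cases$reporter_country
  counts <- vapply(top_countries, function(cn) sum(!is.na(cty) & cty == cn),
                   numeric(1))
  other <- total - sum(counts)
  data.table(group = group, block = "reporter_country",
             level = c(top_countries, "Other/Missing"),
             count = as.numeric(c(counts, other)), total = total,
             percent = if (total > 0)
               percent_of(c(counts, other), total) else NA_real_)
}

#' Demographic summary per drug and overall
#'
#' Tabulates sex, age bins (`<18`, `[18, 65)`, `[65, 85]`, `>85`, missing),
#' reporter type and reporter country for each queried drug's exposed
#' reports, plus two overall columns: `overall_sum` stacks the per-drug
#' groups (a report exposed to two queried drugs is counted twice — the
#' convention under which the overall total is the sum of the drug columns)
#' and `overall_distinct` counts each exposed report once. Percentages are
#' against each group's own total, half-up to 2 decimals.
#'
#' @param dataset a `faers_dataset`.
#' @param n_countries number of individually listed top reporter countries
#'   (ranked by pooled frequency); the rest fall in `Other/Missing`.
#' @return long `data.table`: `group`, `block`, `level`, `count`, `total`,
#'   `percent`.
#' @export
demographics <- function(dataset, n_countries = 4L) {
  labels <- names(dataset$exposure)
  if (length(labels) == 0L) stop("dataset has no exposure groups")
  per_drug <- lapply(labels, function(lab) {
    dataset$cases[primaryid %in% dataset$exposure[[lab]]]
  })
  names(per_drug) <- labels
  pooled_sum <- rbindlist(per_drug)
  pooled_distinct <- dataset$cases[
    primaryid %in% unique(unlist(dataset$exposure, use.names = FALSE))]

  cty <- pooled_distinct$reporter_country
  cty_rank <- sort(table(cty[!is.na(cty)]), decreasing = TRUE)
  top_cty <- head(names(cty_rank), n_countries)

  groups <- c(per_drug,
              list(overall_sum = pooled_sum,
                   overall_distinct = pooled_distinct))
  out <- rbindlist(lapply(names(groups), function(g) {
    rbind(.demo_block(groups[[g]], g),
          .country_block(groups[[g]], g, top_cty))
  }))
  out[]
}

#' Top-N signals ranked by intensity
#'
#' @param results positive screening results (rows of [screen_signals()]
#'   output; typically pre-filtered to `positive == TRUE`).
#' @param n number of rows to keep (fewer if there are fewer results).
#' @param sort_key column to rank by, descending (default `"ror"`); ties
#'   are broken by descending `a`, then PT alphabetically.
#' @return the ranked `data.table` (at most `n` rows).
#' @export
top_signals <- function(results, n = 20L, sort_key = "ror") {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) stop("n must be > 0")
  results <- as.data.table(results)
  if (!sort_key %in% names(results)) stop("unknown sort_key: ", sort_key)
  setorderv(results, c(sort_key, "a", "pt"), order = c(-1L, -1L, 1L),
            na.last = TRUE)
  head(results, n)
}

#' Format a ranked signal table in the conventional printed layout
#'
#' Emits `frequency`, `ROR (95% CI)`, `PRR (chi2)`, `EBGM (EBGM05)`,
#' `IC (IC025)` as strings with 2-decimal half-up rounding.
#'
#' @param results a (ranked) screening result table.
#' @return `data.table` of formatted strings, one row per signal.
#' @export
format_signal_table <- function(results) {
  results <- as.data.table(results)
  f <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  results[, .(pt,
              frequency = a,
              ror_ci = sprintf("%s (%s-%s)", f(ror), f(ror_low), f(ror_high)),
              prr_chi2 = sprintf("%s (%s)", f(prr), f(chi2)),
              ebgm_ebgm05 = sprintf("%s (%s)", f(ebgm), f(ebgm05)),
              ic_ic025 = sprintf("%s (%s)", f(ic), f(ic025)))]
}

#' Count positive PTs per detection method
#'
#' @param results screening results for one drug or pooled.
#' @return one-row `data.table`: `n_pts` (PTs screened), `n_ror`, `n_prr`,
#'   `n_bcpnn`, `n_mgps` (PTs meeting each criterion individually),
#'   `n_any` (at least one), `n_all` (all four simultaneously).
#' @export
method_comparison <- function(results) {
  results <- as.data.table(results)
  if (nrow(results) == 0L) {
    return(data.table(n_pts = 0L, n_ror = 0L, n_prr = 0L, n_bcpnn = 0L,
                      n_mgps = 0L, n_any = 0L, n_all = 0L))
  }
  results[, .(n_pts = .N,
              n_ror = sum(flag_ror), n_prr = sum(flag_prr),
              n_bcpnn = sum(flag_bcpnn), n_mgps = sum(flag_mgps),
              n_any = sum(flag_ror | flag_prr | flag_bcpnn | flag_mgps),
              n_all = sum(positive))]
}

#' Venn-region counts for per-drug positive-signal sets
#'
#' @param sets named list of 2 to 4 character vectors (e.g. positive PTs
#'   per drug).
#' @return `data.table` with `region` (labels joined by `&`) and `count`;
#'   regions partition the union of the sets.
#' @export
intersect_signals <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("intersect_signals needs 2-4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = k,
                       dimnames = list(NULL, names(sets)))
  key <- apply(membership, 1L, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  regions <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- vapply(regions, function(r) sum(key == r), numeric(1))
  data.table(region = regions, count = as.integer(counts))
}

# deterministic leaf order for an hclust tree: at each internal node the
# shorter (tighter) subtree comes first; exact height ties by smallest label
.leaf_order <- function(hc, labels) {
  n <- length(labels)
  if (n == 1L) return(1L)
  height_of <- function(node) if (node < 0) 0 else hc$height[node]
  min_label <- function(node) {
    if (node < 0) labels[-node] else {
      m <- hc$merge[node, ]
      min(min_label(m[1]), min_label(m[2]))
    }
  }
  walk <- function(node) {
    if (node < 0) return(-node)
    m <- hc$merge[node, ]
    h1 <- height_of(m[1]); h2 <- height_of(m[2])
    first <- if (h1 < h2 || (h1 == h2 && min_label(m[1]) <= min_label(m[2]))) {
      c(m[1], m[2])
    } else c(m[2], m[1])
    c(walk(first[1]), walk(first[2]))
  }
  walk(nrow(hc$merge))
}

#' Clustered log(ROR+1) signal matrix across drugs
#'
#' Rows are the union of each drug's top-`n` positive PTs by ROR; the cell
#' value is `log(ROR + 1)` (natural log by default) when the PT is a
#' detected (positive) signal for that drug with a defined ROR, and `0`
#' otherwise — so a PT positive for one drug only shows zeros in the other
#' columns. Rows are ordered by agglomerative hierarchical clustering
#' (Euclidean distance, average linkage) with deterministic tie-breaking,
#' making the ordering invariant to the input row order.
#'
#' @param per_drug_results named list of [screen_signals()] outputs, one per
#'   drug, or a single row-bound `data.table` with a `drug_label` column.
#' @param n per-drug top-list size (default 20).
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return a numeric matrix (PT rows x drug columns, clustered row order)
#'   of class `signal_matrix`, with attribute `row_order` giving the
#'   clustering permutation relative to alphabetical PT order.
#' @export
heatmap_matrix <- function(per_drug_results, n = 20L, log_base = exp(1)) {
  if (is.data.frame(per_drug_results)) {
    per_drug_results <- split(as.data.table(per_drug_results),
                              by = "drug_label")
  }
  labels <- names(per_drug_results)
  picked <- lapply(per_drug_results, function(res) {
    res <- as.data.table(res)
    top_signals(res[positive == TRUE], n = n, sort_key = "ror")$pt
  })
  pts <- sort(unique(unlist(picked, use.names = FALSE)))
  mat <- matrix(0, nrow = length(pts), ncol = length(labels),
                dimnames = list(pts, labels))
  for (lab in labels) {
    res <- as.data.table(per_drug_results[[lab]])
    det <- res[positive == TRUE & !is.na(ror) & pt %in% pts]
    if (nrow(det)) mat[det$pt, lab] <- log(det$ror + 1) / log(log_base)
  }
  ord <- if (nrow(mat) > 2L) {
    hc <- hclust(dist(mat), method = "average")
    .leaf_order(hc, rownames(mat))
  } else seq_len(nrow(mat))
  out <- mat[ord, , drop = FALSE]
  attr(out, "row_order") <- ord
  class(out) <- c("signal_matrix", class(out))
  out
}

#' Long-format view of a signal matrix
#'
#' @param mat a [heatmap_matrix()] result.
#' @return `data.table` with `pt`, `drug`, `value`, `row_rank`, suitable for
#'   any plotting layer.
#' @export
signal_matrix_long <- function(mat) {
  dt <- data.table(pt = rep(rownames(mat), ncol(mat)),
                   drug = rep(colnames(mat), each = nrow(mat)),
                   value = as.vector(mat),
                   row_rank = rep(seq_len(nrow(mat)), ncol(mat)))
  dt[]
}

#' Render a signal matrix as a heatmap image (optional)
#'
#' Thin wrapper over `pheatmap` (Suggests); rows keep the matrix's
#' clustering order.
#'
#' @param mat a [heatmap_matrix()] result.
#' @param file output image path (extension decides the device).
#' @return the file path, invisibly.
#' @export
render_heatmap <- function(mat, file) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("rendering requires the 'pheatmap' package")
  }
  m <- mat
  attr(m, "row_order") <- NULL
  class(m) <- "matrix"
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     filename = file)
  invisible(file)
}
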