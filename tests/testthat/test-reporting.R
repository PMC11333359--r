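make_demo_dataset <- function() {
  cases <- make_cases(1:10)
  cases$sex <- c(rep("female", 5), rep("male", 3), "missing", "missing")
  cases$age_years <- c(10, 30, 65, 85, 86, NA, NA, 40, 64.9, 17.9)
  cases$reporter_type <- c(rep("consumer", 7), "health_professional",
                           "other_missing", "other_missing")
  cases$reporter_country <- c(rep("US", 6), "JP", "JP", NA, "CA")
  drugs <- data.table::data.table(
    primaryid = 1:10,
    drugname = c(rep("ALPHA", 6), rep("BETA", 4)),
    role_cod = "PS")
  events <- data.table::data.table(primaryid = 1:10, pt = "e")
  build_dataset(cases, drugs, events,
                list(drug_query("alpha", "alpha"), drug_query("beta", "beta")))
}

test_that("demographics bins ages as printed and sums to 100%", {
  ds <- make_demo_dataset()
  d <- demographics(ds)
  alpha_age <- d[group == "alpha" & block == "age"]
  # ages 10, 30, 65, 85, 86, NA: <18=1, 18-64.9=1, 65-85=2, >85=1, missing=1
  expect_equal(alpha_age[match(c("<18", "18-64.9", "65-85", ">85", "missing"),
                               level), count],
               c(1, 1, 2, 1, 1))
  for (g in unique(d$group)) {
    for (b in unique(d$block)) {
      expect_equal(sum(d[group == g & block == b, percent]), 100,
                   tolerance = 0.02)
    }
  }
  # boundary: 64.9 is in 18-64.9, 65 in 65-85, 85 in 65-85, 86 in >85
  beta_age <- d[group == "beta" & block == "age"]
  expect_equal(beta_age[level == "18-64.9", count], 2) # 40 and 64.9
  expect_equal(beta_age[level == "<18", count], 1)     # 17.9
})

test_that("overall_sum stacks drug groups; overall_distinct does not", {
  ds <- make_demo_dataset()
  # make report 1 exposed to both drugs
  ds$exposure$beta <- sort(unique(c(ds$exposure$beta, 1)))
  d <- demographics(ds)
  tot <- function(g) d[group == g & block == "sex", sum(count)]
  expect_equal(tot("overall_sum"), tot("alpha") + tot("beta"))
  expect_equal(tot("overall_distinct"), 10)
  expect_equal(tot("overall_sum"), 11)
})

test_that("all-missing ages give a 100% missing bin", {
  ds <- make_demo_dataset()
  ds$cases$age_years <- NA_real_
  d <- demographics(ds)
  expect_equal(d[group == "overall_distinct" & block == "age" &
                   level == "missing", percent], 100)
})

test_that("top_signals ranks by the sort key with deterministic ties", {
  res <- fake_results(25)
  top <- top_signals(res, 20)
  expect_equal(nrow(top), 20L)
  expect_equal(top$ror[1], max(res$ror))
  expect_true(!is.unsorted(rev(top$ror)))
  expect_equal(nrow(top_signals(res, 100)), 25L)
  expect_error(top_signals(res, 0), "n must be")
  # stability: identical input, identical output
  expect_identical(top_signals(res, 10), top_signals(data.table::copy(res), 10))
})

test_that("format_signal_table renders the printed layout", {
  res <- fake_results(2)
  f <- format_signal_table(top_signals(res, 2))
  expect_match(f$ror_ci[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
  expect_equal(f$frequency, top_signals(res, 2)$a)
})

test_that("method_comparison matches brute-force pattern enumeration", {
  # 16 PTs, one per flag combination
  grid <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                      f3 = c(FALSE, TRUE), f4 = c(FALSE, TRUE))
  res <- data.table::data.table(
    pt = sprintf("pt%02d", 1:16),
    flag_ror = grid$f1, flag_prr = grid$f2,
    flag_bcpnn = grid$f3, flag_mgps = grid$f4)
  res[, positive := flag_ror & flag_prr & flag_bcpnn & flag_mgps]
  mc <- method_comparison(res)
  expect_equal(mc$n_pts, 16L)
  expect_equal(mc$n_ror, sum(grid$f1))
  expect_equal(mc$n_prr, sum(grid$f2))
  expect_equal(mc$n_bcpnn, sum(grid$f3))
  expect_equal(mc$n_mgps, sum(grid$f4))
  expect_equal(mc$n_any, sum(grid$f1 | grid$f2 | grid$f3 | grid$f4))
  expect_equal(mc$n_all, sum(grid$f1 & grid$f2 & grid$f3 & grid$f4))
  expect_true(all(mc$n_all <= unlist(mc[, .(n_ror, n_prr, n_bcpnn, n_mgps)])))
  empty <- method_comparison(res[0])
  expect_equal(unlist(empty), setNames(rep(0L, 7), names(empty)))
})

test_that("intersect_signals partitions the union", {
  out <- intersect_signals(list(s1 = c("A", "B"), s2 = c("B", "C"),
                                s3 = "B"))
  expect_equal(out[region == "s1&s2&s3", count], 1L) # {B}
  expect_equal(sum(out$count), 3L)                   # |{A, B, C}|
  disjoint <- intersect_signals(list(x = "A", y = "B"))
  expect_equal(disjoint[region == "x&y", count], 0L)
  expect_equal(sum(disjoint$count), 2L)
  expect_error(intersect_signals(list(a = "A")), "2-4")
  expect_error(intersect_signals(list("A", "B")), "named")
})

test_that("heatmap_matrix zeros non-detected cells and is finite", {
  strong <- signal_stats_table(data.frame(
    label = c("shared", "only1"), a = c(50, 40), b = 100, c = 50, d = 10000))
  weak <- signal_stats_table(data.frame(
    label = c("shared", "null"), a = c(30, 1), b = 100, c = c(50, 500),
    d = 10000))
  data.table::setnames(strong, "label", "pt")
  data.table::setnames(weak, "label", "pt")
  strong[, drug_label := "d1"]; weak[, drug_label := "d2"]
  mat <- heatmap_matrix(list(d1 = strong, d2 = weak), n = 20)
  expect_true(all(is.finite(mat)) && all(mat >= 0))
  expect_true("only1" %in% rownames(mat))
  expect_equal(mat["only1", "d2"], 0) # not detected for d2
  expect_gt(mat["only1", "d1"], 0)
  expect_equal(mat["shared", "d1"],
               log(strong[pt == "shared", ror] + 1))
})

test_that("heatmap row clustering is invariant to input order", {
  set.seed(33)
  res <- signal_stats_table(data.frame(
    label = sprintf("pt%02d", 1:15),
    a = sample(30:90, 15), b = 100, c = 50, d = 20000))
  data.table::setnames(res, "label", "pt")
  mk <- function(r1, r2) {
    r1 <- data.table::copy(r1); r2 <- data.table::copy(r2)
    r1[, drug_label := "d1"]; r2[, drug_label := "d2"]
    heatmap_matrix(list(d1 = r1, d2 = r2), n = 10)
  }
  m1 <- mk(res, res[15:1])
  m2 <- mk(res[sample(15)], res[sample(15)])
  expect_identical(rownames(m1), rownames(m2))
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
  long <- signal_matrix_long(m1)
  expect_equal(nrow(long), nrow(m1) * 2)
  expect_equal(long[drug == "d1" & pt == rownames(m1)[1], row_rank], 1L)
})
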