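small_cfg <- function(...) {
  synth_config(n_reports = 400, n_quarters = 2, seed = 123, ...)
}

test_that("generation is a pure function of the seed", {
  g1 <- synth_generate(small_cfg())
  g2 <- synth_generate(small_cfg())
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$truth$pair_counts, g2$truth$pair_counts)
  # different seed differs
  g3 <- synth_generate(synth_config(n_reports = 400, n_quarters = 2, seed = 9))
  expect_false(identical(g1$tables$reac, g3$tables$reac))
  # the caller's RNG stream is not disturbed
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(synth_generate(small_cfg())); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("written quarter files are byte-identical across runs and readable", {
  d1 <- file.path(tempdir(), "synq1"); d2 <- file.path(tempdir(), "synq2")
  unlink(c(d1, d2), recursive = TRUE)
  g1 <- synth_generate(small_cfg(), dir = d1)
  g2 <- synth_generate(small_cfg(), dir = d2)
  f1 <- sort(basename(g1$files)); f2 <- sort(basename(g2$files))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # round trip: re-read record counts equal written counts
  back <- read_quarter_dir(d1)
  expect_equal(nrow(back$demo), nrow(g1$tables$demo))
  expect_equal(nrow(back$reac), nrow(g1$tables$reac))
  expect_equal(sort(names(back$demo)), sort(names(g1$tables$demo)))
})

test_that("duplicate injection inflates rows; dedup recovers exactly", {
  cfg <- synth_config(n_reports = 1000, duplicate_case_rate = 0.1,
                      same_primaryid_error_rate = 0, n_quarters = 1,
                      seed = 42)
  g <- synth_generate(cfg)
  n_demo <- nrow(g$tables$demo)
  expect_gt(n_demo, 1050) # ~1100 expected
  expect_lt(n_demo, 1150)
  cases <- parse_demo(g$tables$demo)
  expect_equal(nrow(deduplicate_cases(cases)$cases), 1000L)
})

test_that("primaryid-error cases are excluded exactly", {
  cfg <- synth_config(n_reports = 2000, duplicate_case_rate = 0.05,
                      same_primaryid_error_rate = 0.01, n_quarters = 2,
                      seed = 77)
  g <- synth_generate(cfg)
  expect_gt(g$truth$n_error_cases, 0)
  cases <- parse_demo(g$tables$demo)
  dd <- deduplicate_cases(cases)
  expect_equal(nrow(dd$cases), 2000L - g$truth$n_error_cases)
  expect_equal(g$truth$n_surviving_reports, nrow(dd$cases))
})

test_that("truth pair counts equal the pipeline's a-cells", {
  cfg <- synth_config(n_reports = 3000, seed = 5)
  g <- synth_generate(cfg)
  cases <- parse_demo(g$tables$demo)
  ds <- build_dataset(cases, g$tables$drug, g$tables$reac,
                      list(drug_query("agent_a", "agent_a", "Avexa")))
  res <- screen_signals(ds, "agent_a")
  truth <- g$truth$pair_counts[drug_label == "agent_a"]
  merged <- merge(res[, .(pt, a)], truth[, .(pt, a_true = a)], by = "pt")
  expect_equal(nrow(merged), nrow(truth)) # every truth PT is screened
  expect_equal(merged$a, merged$a_true)
})

test_that("expected_ror: closed form, limits and oracle agreement", {
  null_cfg <- synth_config(planted = data.frame(
    drug_label = character(0), pt = character(0), lambda = numeric(0)))
  expect_equal(expected_ror(null_cfg, "agent_a", "pt_010"), 1)
  cfg10 <- synth_config(planted = data.frame(
    drug_label = "agent_b", pt = "pt_050", lambda = 10))
  expect_equal(expected_ror(cfg10, "agent_b", "pt_050"), 10)
  # arbitrary multi-planted config vs brute-force probability oracle
  cfg <- synth_config(planted = data.frame(
    drug_label = c("agent_a", "agent_a", "agent_b"),
    pt = c("pt_003", "pt_020", "pt_003"),
    lambda = c(4, 0.5, 7)))
  for (dl in c("agent_a", "agent_b", "comparator_01")) {
    for (p in c("pt_003", "pt_020", "pt_001")) {
      expect_equal(expected_ror(cfg, dl, p),
                   oracle_expected_ror(cfg, dl, p), tolerance = 1e-12)
    }
  }
  expect_error(expected_ror(cfg, "nope", "pt_001"), "unknown drug")
  expect_error(expected_ror(cfg, "agent_a", "nope"), "unknown pt")
})

test_that("lambda = 1 generates counts consistent with independence", {
  # ~50,000 mentions; goodness of fit of the exposed drug's PT histogram
  # against the shared background rates
  cfg <- synth_config(
    n_reports = 25000, events = synth_default_events(30),
    planted = data.frame(drug_label = character(0), pt = character(0),
                         lambda = numeric(0)),
    duplicate_case_rate = 0, same_primaryid_error_rate = 0,
    n_quarters = 1, seed = 202)
  g <- synth_generate(cfg)
  reac <- g$tables$reac
  expect_gt(nrow(reac), 40000)
  exp_probs <- cfg$events$rate / sum(cfg$events$rate)
  counts <- table(factor(reac$pt, levels = cfg$events$pt))
  gof <- suppressWarnings(chisq.test(counts, p = exp_probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("invalid configurations fail before generation", {
  expect_error(synth_config(n_reports = 0), "n_reports")
  expect_error(synth_config(duplicate_case_rate = 1.5), "rates")
  expect_error(synth_config(sex_probs = c(F = 0.5, M = 0.2, missing = 0.1)),
               "sum to 1")
  expect_error(synth_config(planted = data.frame(
    drug_label = "nope", pt = "pt_001", lambda = 2)), "drug_label")
  expect_error(synth_config(planted = data.frame(
    drug_label = "agent_a", pt = "pt_001", lambda = -1)), "lambda")
})
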