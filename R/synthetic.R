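#' @name synthetic_data
#' @title Synthetic FAERS-format quarters with known ground truth
#' @description
#' Generates quarterly DEMO/DRUG/REAC tables in the exact dialect
#' [read_faers_table()] reads, with a fully specified generative model:
#' each report draws one primary-suspect drug from the background shares,
#' then `1 + Poisson` preferred terms from the event-rate vector, where a
#' planted (drug, PT) pair multiplies that PT's rate by `lambda` for
#' reports whose suspect drug is the planted one. Duplicate case versions
#' and colliding-primaryid error rows are injected at configurable rates to
#' exercise deduplication. Generation is a pure function of the seed, with
#' per-quarter derived substreams so adding quarters does not perturb
#' earlier ones. The implied population reporting odds ratio of any
#' (drug, PT) pair is available in closed form via [expected_ror()]; for a
#' drug with a single planted PT it equals `lambda` exactly.
NULL

#' Default synthetic drug universe
#'
#' Three small-share study drugs (each with a generic and a brand name, so
#' name matching is exercised) plus twelve background comparators. Study
#' shares are 1-3% of reports, echoing how a newly marketed drug class is a
#' tiny fraction of the whole database.
#'
#' @return `data.table` with `label`, `generic`, `brand`, `share`.
#' @export
synth_default_drugs <- function() {
  bg <- sprintf("comparator_%02d", 1:12)
  bg_share <- 0.94 * (13 - (1:12)) / sum(13 - (1:12))
  rbind(
    data.table(label = c("agent_a", "agent_b", "agent_c"),
               generic = c("agent_a", "agent_b", "agent_c"),
               brand = c("Avexa", "Bevexa", "Cevexa"),
               share = c(0.03, 0.01, 0.02)),
    data.table(label = bg, generic = bg, brand = toupper(bg),
               share = bg_share))
}

#' Default synthetic event vocabulary
#'
#' @param n_events number of preferred terms.
#' @return `data.table` with `pt`, `rate` (Zipf-like, normalized), the
#'   heavy tail mimicking how a few PTs dominate real reporting.
#' @export
synth_default_events <- function(n_events = 80L) {
  r <- 1 / seq_len(n_events)
  data.table(pt = sprintf("pt_%03d", seq_len(n_events)), rate = r / sum(r))
}

#' Build a synthetic-data configuration
#'
#' Defaults mirror the printed demographic margins of a DORA-class FAERS
#' cohort: sex female/male/missing 0.55/0.33/0.12, age missing 0.60,
#' consumer/health-professional/other 0.75/0.24/0.01, country
#' US/JP/CA/AU/missing 0.92/0.07/0.003/0.003/0.004.
#'
#' @param n_reports number of true reports (before duplicate/error rows).
#' @param drugs drug universe, see [synth_default_drugs()].
#' @param events event vocabulary, see [synth_default_events()].
#' @param planted data.frame `(drug_label, pt, lambda)` of planted
#'   disproportionality; `lambda > 0` multiplies the PT's rate for the
#'   planted drug (1 = no signal).
#' @param events_per_report_lambda each report carries
#'   `1 + rpois(events_per_report_lambda)` PT mentions.
#' @param duplicate_case_rate probability a case is re-submitted under a
#'   larger primaryid (same caseid, identical content).
#' @param same_primaryid_error_rate probability a report's primaryid is
#'   reused by a spurious second row (a data error; both rows are excluded
#'   by deduplication).
#' @param concomitant_rate probability a report carries an extra
#'   non-suspect (role `C`) drug row, exercising role filtering.
#' @param sex_probs,occupation_probs,country_probs named probability
#'   vectors over the emitted codes ("" = missing).
#' @param age_missing_rate,age_mean,age_sd age model: missing with the
#'   given rate, otherwise normal, truncated to \[18, 95\] and rounded.
#' @param n_quarters,start_quarter quarter range, labels `YYYYQ[1-4]`.
#' @param seed root seed (integer, < 2^31).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_reports = 5000L,
                         drugs = synth_default_drugs(),
                         events = synth_default_events(),
                         planted = data.frame(
                           drug_label = "agent_a", pt = "pt_010", lambda = 8),
                         events_per_report_lambda = 1,
                         duplicate_case_rate = 0.05,
                         same_primaryid_error_rate = 0.005,
                         concomitant_rate = 0.3,
                         sex_probs = c(F = 0.55, M = 0.33, missing = 0.12),
                         age_missing_rate = 0.60,
                         age_mean = 55, age_sd = 18,
                         occupation_probs = c(CN = 0.75, MD = 0.10, PH = 0.06,
                                              OT = 0.04, RN = 0.04,
                                              missing = 0.01),
                         country_probs = c(US = 0.92, JP = 0.07, CA = 0.003,
                                           AU = 0.003, missing = 0.004),
                         n_quarters = 4L,
                         start_quarter = "2014Q3",
                         seed = 1L) {
  cfg <- structure(list(
    n_reports = as.integer(n_reports),
    drugs = as.data.table(drugs), events = as.data.table(events),
    planted = as.data.table(planted),
    events_per_report_lambda = events_per_report_lambda,
    duplicate_case_rate = duplicate_case_rate,
    same_primaryid_error_rate = same_primaryid_error_rate,
    concomitant_rate = concomitant_rate,
    sex_probs = sex_probs, age_missing_rate = age_missing_rate,
    age_mean = age_mean, age_sd = age_sd,
    occupation_probs = occupation_probs, country_probs = country_probs,
    n_quarters = as.integer(n_quarters), start_quarter = start_quarter,
    seed = as.integer(seed)), class = "synth_config")
  synth_validate(cfg)
  cfg
}

#' Validate a synthetic configuration
#'
#' @param config a `synth_config`.
#' @return the config, invisibly; errors (before anything is generated or
#'   written) on invalid shares, rates, probabilities or planted pairs.
#' @export
synth_validate <- function(config) {
  with(config, {
    stopifnot(n_reports > 0, n_quarters > 0)
    .assert_quarter(start_quarter)
    if (any(drugs$share <= 0)) stop("drug shares must be positive")
    if (any(events$rate <= 0)) stop("event rates must be positive")
    if (anyDuplicated(drugs$label)) stop("duplicate drug labels")
    if (anyDuplicated(events$pt)) stop("duplicate event PTs")
    rates <- c(duplicate_case_rate, same_primaryid_error_rate,
               concomitant_rate, age_missing_rate)
    if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
    for (p in list(sex_probs, occupation_probs, country_probs)) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop("probability vectors must be non-negative and sum to 1")
      }
    }
    if (nrow(planted)) {
      if (!all(planted$drug_label %in% drugs$label)) {
        stop("planted drug_label not in the drug universe")
      }
      if (!all(planted$pt %in% events$pt)) {
        stop("planted pt not in the event vocabulary")
      }
      if (any(planted$lambda <= 0)) stop("planted lambda must be > 0")
    }
  })
  invisible(config)
}

# per-drug PT sampling probabilities: base rates, reweighted by planted
# multipliers for that drug, renormalized
.event_probs_for <- function(config, lab) {
  r <- config$events$rate / sum(config$events$rate)
  if (nrow(config$planted)) {
    sel <- config$planted[["drug_label"]] == lab
    pl <- config$planted[sel]
    if (nrow(pl)) {
      mult <- rep(1, nrow(config$events))
      mult[match(pl$pt, config$events$pt)] <- pl$lambda
      r <- r * mult
    }
  }
  r / sum(r)
}

.quarter_seq <- function(start_quarter, n_quarters) {
  y <- as.integer(substr(start_quarter, 1, 4))
  q <- as.integer(substr(start_quarter, 6, 6))
  labs <- character(n_quarters)
  for (i in seq_len(n_quarters)) {
    labs[i] <- sprintf("%dQ%d", y, q)
    q <- q + 1L
    if (q > 4L) { q <- 1L; y <- y + 1L }
  }
  labs
}

.derive_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + i * 16807) %% 2147483629)
}

#' Generate synthetic FAERS-format quarters
#'
#' @param config a [synth_config()].
#' @param dir if non-NULL, quarter files `DEMOyyQq.txt` / `DRUGyyQq.txt` /
#'   `REACyyQq.txt` (dollar-delimited) plus a `truth.json` sidecar are
#'   written there.
#' @return list:
#'   * `tables`: pooled in-memory raw tables (`demo`, `drug`, `reac`)
#'     exactly as they would be read back from the files;
#'   * `truth`: list with `planted` (pairs, lambda, `expected_ror`,
#'     analytic cell probabilities and expected `a`), `pair_counts` (exact
#'     generated mention counts per (drug, PT) among surviving reports),
#'     `n_reports`, `n_error_cases`, `n_duplicate_cases`,
#'     `n_surviving_reports`, `exposed_reports` per study drug, `seed`;
#'   * `files`: written paths (empty if `dir` is NULL).
#' @details The caller's RNG state is saved and restored: generation is a
#'   pure function of `config$seed`.
#' @export
synth_generate <- function(config, dir = NULL) {
  synth_validate(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  quarters <- .quarter_seq(config$start_quarter, config$n_quarters)
  n_q <- rep(config$n_reports %/% config$n_quarters, config$n_quarters)
  extra <- config$n_reports %% config$n_quarters
  if (extra > 0) n_q[seq_len(extra)] <- n_q[seq_len(extra)] + 1L

  drug_probs <- config$drugs$share / sum(config$drugs$share)
  ev_probs <- lapply(config$drugs$label, function(l) .event_probs_for(config, l))
  names(ev_probs) <- config$drugs$label
  n_ev <- nrow(config$events)

  demo_l <- list(); drug_l <- list(); reac_l <- list()
  truth_counts <- list()
  n_err_total <- 0L; n_dup_total <- 0L
  offset <- 0L

  for (qi in seq_along(quarters)) {
    set.seed(.derive_seed(config$seed, qi))
    nq <- n_q[qi]
    gidx <- offset + seq_len(nq)
    offset <- offset + nq
    pid <- gidx * 10
    cid <- gidx

    di <- sample.int(nrow(config$drugs), nq, replace = TRUE, prob = drug_probs)
    dlab <- config$drugs$label[di]
    k <- 1L + rpois(nq, config$events_per_report_lambda)

    mention_report <- rep(seq_len(nq), k)
    mention_drug <- dlab[mention_report]
    pt_idx <- integer(length(mention_report))
    for (lab in unique(mention_drug)) {
      sel <- mention_drug == lab
      pt_idx[sel] <- sample.int(n_ev, sum(sel), replace = TRUE,
                                prob = ev_probs[[lab]])
    }
    pt <- config$events$pt[pt_idx]

    sex <- sample(c("F", "M", ""), nq, replace = TRUE, prob = config$sex_probs)
    age_val <- round(pmin(pmax(rnorm(nq, config$age_mean, config$age_sd),
                               18), 95))
    age_missing <- runif(nq) < config$age_missing_rate
    unit <- sample(c("YR", "DEC", "MON"), nq, replace = TRUE,
                   prob = c(0.90, 0.05, 0.05))
    age_str <- fcase(age_missing, "",
                     unit == "YR", as.character(age_val),
                     unit == "DEC", as.character(age_val / 10),
                     default = as.character(age_val * 12))
    age_cod <- ifelse(age_missing, "", unit)
    occ <- sample(c("CN", "MD", "PH", "OT", "RN", ""), nq, replace = TRUE,
                  prob = config$occupation_probs)
    cty <- sample(c("US", "JP", "CA", "AU", ""), nq, replace = TRUE,
                  prob = config$country_probs)

    name_form <- sample.int(3L, nq, replace = TRUE)
    generic <- config$drugs$generic[di]
    brand <- config$drugs$brand[di]
    drugname <- fcase(name_form == 1L, toupper(generic),
                      name_form == 2L, brand,
                      default = paste(generic, "10MG TABLET"))
    prod_ai <- toupper(generic)

    # error-row injection first, duplicates among the remainder (disjoint,
    # so dedup recovery is exact: surviving = nq - n_errors)
    err <- runif(nq) < config$same_primaryid_error_rate
    dup <- !err & runif(nq) < config$duplicate_case_rate
    n_err_total <- n_err_total + sum(err)
    n_dup_total <- n_dup_total + sum(dup)

    demo <- data.table(primaryid = pid, caseid = cid, sex = sex,
                       age = age_str, age_cod = age_cod, occp_cod = occ,
                       reporter_country = cty, quarter = quarters[qi])
    drg <- data.table(primaryid = pid, drugname = drugname,
                      prod_ai = prod_ai, role_cod = "PS")
    conc <- runif(nq) < config$concomitant_rate
    if (any(conc)) {
      other <- ((di[conc] + 3L) %% nrow(config$drugs)) + 1L
      drg <- rbind(drg, data.table(primaryid = pid[conc],
                                   drugname = toupper(config$drugs$generic[other]),
                                   prod_ai = toupper(config$drugs$generic[other]),
                                   role_cod = "C"))
    }
    rc <- data.table(primaryid = pid[mention_report], pt = pt)

    if (any(dup)) { # re-submission: same case, larger primaryid, same content
      dpid <- pid[dup] + 5
      demo <- rbind(demo, copy(demo[dup])[, primaryid := dpid])
      dmap <- setNames(dpid, pid[dup])
      ddr <- drg[primaryid %in% pid[dup]]
      ddr[, primaryid := dmap[as.character(primaryid)]]
      drc <- rc[primaryid %in% pid[dup]]
      drc[, primaryid := dmap[as.character(primaryid)]]
      drug_l[[length(drug_l) + 1L]] <- ddr
      reac_l[[length(reac_l) + 1L]] <- drc
    }
    if (any(err)) { # spurious reuse of an existing primaryid, new caseid
      epid <- pid[err]
      demo <- rbind(demo, data.table(
        primaryid = epid, caseid = 900000000 + gidx[err], sex = "",
        age = "", age_cod = "", occp_cod = "", reporter_country = "",
        quarter = quarters[qi]))
    }

    demo_l[[length(demo_l) + 1L]] <- demo
    drug_l[[length(drug_l) + 1L]] <- drg
    reac_l[[length(reac_l) + 1L]] <- rc

    survive <- !err # content of surviving reports = originals minus errors
    keep_mention <- survive[mention_report]
    truth_counts[[qi]] <- data.table(
      drug_label = mention_drug[keep_mention], pt = pt[keep_mention])
  }

  demo <- rbindlist(demo_l); drg <- rbindlist(drug_l); rc <- rbindlist(reac_l)
  pair_counts <- rbindlist(truth_counts)[, .(a = .N), by = .(drug_label, pt)]
  setorder(pair_counts, drug_label, pt)

  planted <- copy(config$planted)
  if (nrow(planted)) {
    planted[, expected_ror := vapply(seq_len(.N), function(i) {
      expected_ror(config, drug_label[i], pt[i])
    }, numeric(1))]
  }
  exposed <- pair_counts[, .(mentions = sum(a)), by = drug_label]

  truth <- list(planted = planted, pair_counts = pair_counts,
                n_reports = config$n_reports,
                n_error_cases = n_err_total,
                n_duplicate_cases = n_dup_total,
                n_surviving_reports = config$n_reports - n_err_total,
                exposed_mentions = exposed, seed = config$seed)

  files <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (qi in seq_along(quarters)) {
      qlab <- quarters[qi]
      suffix <- paste0(substr(qlab, 3, 4), "Q", substr(qlab, 6, 6))
      fd <- file.path(dir, paste0("DEMO", suffix, ".txt"))
      fg <- file.path(dir, paste0("DRUG", suffix, ".txt"))
      fr <- file.path(dir, paste0("REAC", suffix, ".txt"))
      dq <- demo[quarter == qlab, !"quarter"]
      write_delimited(dq, fd, delim = "$")
      qpid <- demo[quarter == qlab, primaryid]
      write_delimited(drg[primaryid %in% qpid], fg, delim = "$")
      write_delimited(rc[primaryid %in% qpid], fr, delim = "$")
      files <- c(files, fd, fg, fr)
    }
    tf <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, tf)
  }

  list(tables = list(demo = demo, drug = drg, reac = rc),
       truth = truth, files = files, config = config)
}

#' Population reporting odds ratio implied by a synthetic configuration
#'
#' Closed form from the generative model: per event mention,
#' `P(drug = i) = share_i` and `P(pt = j | drug = i)` is the reweighted,
#' renormalized event-rate vector. The four cell probabilities follow, and
#' `expected_ror = (p_a p_d)/(p_b p_c)`. For a drug with a single planted
#' PT the renormalization cancels and the value equals that pair's
#' `lambda` exactly; with `lambda = 1` everywhere it is exactly 1.
#'
#' @param config a [synth_config()].
#' @param drug_label,pt the pair (must exist in the universe).
#' @return the population odds ratio (positive real).
#' @export
expected_ror <- function(config, drug_label, pt) {
  if (!drug_label %in% config$drugs$label) {
    stop("unknown drug_label: ", drug_label)
  }
  if (!pt %in% config$events$pt) stop("unknown pt: ", pt)
  s <- config$drugs$share / sum(config$drugs$share)
  names(s) <- config$drugs$label
  j <- match(pt, config$events$pt)
  q <- vapply(config$drugs$label,
              function(l) .event_probs_for(config, l)[j], numeric(1))
  pa <- s[drug_label] * q[drug_label]
  pb <- s[drug_label] * (1 - q[drug_label])
  pc <- sum(s[names(s) != drug_label] * q[names(s) != drug_label])
  pd <- 1 - pa - pb - pc
  unname((pa * pd) / (pb * pc))
}

#' Read back a directory of synthetic (or real) quarter files
#'
#' @param dir directory containing `DEMOyyQq.txt` / `DRUGyyQq.txt` /
#'   `REACyyQq.txt` files.
#' @return list of pooled raw tables `demo`, `drug`, `reac`, each with a
#'   `quarter` column.
#' @export
read_quarter_dir <- function(dir) {
  pick <- function(kind) {
    fs <- sort(list.files(dir, pattern = paste0("^", kind, "[0-9]{2}Q[1-4]\\.txt$"),
                          full.names = TRUE))
    if (length(fs) == 0L) stop("no ", kind, " files found in ", dir)
    rbindlist(lapply(fs, function(f) {
      m <- regmatches(basename(f), regexec("([0-9]{2})Q([1-4])", basename(f)))[[1]]
      qlab <- sprintf("20%sQ%s", m[2], m[3])
      dt <- read_faers_table(f, kind, qlab, delim = "$")
      dt[, quarter := qlab]
    }))
  }
  list(demo = pick("DEMO"), drug = pick("DRUG"), reac = pick("REAC"))
}
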