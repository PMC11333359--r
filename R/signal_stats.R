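#' @name signal_stats
#' @title Disproportionality statistics on 2x2 contingency tables
#' @description
#' Every statistic is computed from the 2x2 table of a (drug, event) pair
#' against the background of all other reports:
#' \preformatted{
#'                 target event   other events
#'   target drug        a              b
#'   other drugs        c              d
#' }
#' Four estimators are screened jointly; a pair is a positive signal only
#' when all four criteria hold simultaneously:
#' * ROR `= ad/bc`, Woolf 95% CI; positive if CI lower bound > 1 and a >= 3.
#' * PRR `= [a/(a+b)] / [c/(c+d)]` with uncorrected Pearson chi-square;
#'   positive if PRR >= 2, chi2 >= 4 and a >= 3.
#' * BCPNN information component (closed-form posterior, priors
#'   gamma11 = 1, alpha = beta = 2, alpha1 = beta1 = 1); positive if
#'   IC025 = E(IC) - 2*sqrt(V(IC)) > 0.
#' * Simplified EBGM `= aN/[(a+b)(a+c)]` (observed/expected under
#'   independence) with a log-normal lower bound EBGM05; positive if
#'   EBGM05 >= 2 and a > 0.
#'
#' Zero cells get no continuity correction: estimates whose formula is
#' undefined are `NA` and their flag is `FALSE`. The IC is defined for every
#' table with `N > 0` (the priors shrink all terms away from zero).
NULL

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative counts; `a` = target drug and target event,
#'   `b` = target drug, other events, `c` = other drugs, target event,
#'   `d` = other drugs, other events. `N = a+b+c+d` must be positive.
#' @return an object of class `contingency_2x2`.
#' @export
contingency <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || any(v < 0)) stop("cells must be finite and >= 0")
  if (sum(v) <= 0) stop("N = a+b+c+d must be > 0")
  structure(as.list(v), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

# Vectorized engine: all four statistics on parallel cell vectors.
# Returns a data.table; scalar wrappers and screen_signals() both call this.
disprop_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n <= 0)) stop("every table must have N > 0")
  any_zero <- a == 0 | b == 0 | c == 0 | d == 0
  se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d) # Inf when any cell is 0

  ## ROR with Woolf interval
  ror <- (a * d) / (b * c)
  ror[any_zero] <- NA_real_
  ror_low <- exp(log(ror) - 1.96 * se_log)
  ror_high <- exp(log(ror) + 1.96 * se_log)
  flag_ror <- !is.na(ror_low) & ror_low > 1 & a >= 3

  ## PRR + uncorrected Pearson chi-square
  prr <- (a / (a + b)) / (c / (c + d))
  prr[c == 0 | (a + b) == 0] <- NA_real_
  chi_den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(chi_den > 0, (a * d - b * c)^2 * n / chi_den, NA_real_)
  flag_prr <- !is.na(prr) & !is.na(chi2) & prr >= 2 & chi2 >= 4 & a >= 3

  ## BCPNN information component, closed form
  md <- a + b # drug margin
  me <- a + c # event margin
  gam <- (n + 2)^2 / ((md + 1) * (me + 1))
  ic <- (log(a + 1) + 2 * log(n + 2) - log(n + gam) -
           log(md + 1) - log(me + 1)) / log(2)
  vic <- (1 / log(2))^2 *
    ((n - a + gam - 1) / ((a + 1) * (1 + n + gam)) +
       (n - md + 1) / ((md + 1) * (n + 3)) +
       (n - me + 1) / ((me + 1) * (n + 3)))
  ic025 <- ic - 2 * sqrt(vic)
  flag_bcpnn <- ic025 > 0

  ## simplified EBGM (observed / expected) with log-normal lower bound
  ebgm <- a * n / (me * md)
  ebgm[a == 0 | me == 0 | md == 0] <- NA_real_
  ebgm05 <- exp(log(ebgm) - 1.96 * se_log) # NA when ebgm NA or 0 when se Inf
  ebgm05[any_zero] <- NA_real_
  flag_mgps <- !is.na(ebgm05) & ebgm05 >= 2 & a > 0

  data.table(a = a, b = b, c = c, d = d,
             ror = ror, ror_low = ror_low, ror_high = ror_high,
             prr = prr, chi2 = chi2,
             ic = ic, ic025 = ic025,
             ebgm = ebgm, ebgm05 = ebgm05,
             flag_ror = flag_ror, flag_prr = flag_prr,
             flag_bcpnn = flag_bcpnn, flag_mgps = flag_mgps,
             positive = flag_ror & flag_prr & flag_bcpnn & flag_mgps)
}

.as_cells <- function(t) {
  if (inherits(t, "contingency_2x2")) t else do.call(contingency, as.list(t))
}

#' Reporting odds ratio
#'
#' @param t a [contingency()] table (or a list/vector with a, b, c, d).
#' @return list: `ror`, `ror_low`, `ror_high` (NA when any cell is 0),
#'   `flag_ror`.
#' @export
ror <- function(t) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(ror = s$ror, ror_low = s$ror_low, ror_high = s$ror_high,
       flag_ror = s$flag_ror)
}

#' Proportional reporting ratio and chi-square
#'
#' @inheritParams ror
#' @return list: `prr` (NA when `c == 0` or `a+b == 0`), `chi2`, `flag_prr`.
#' @export
prr <- function(t) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(prr = s$prr, chi2 = s$chi2, flag_prr = s$flag_prr)
}

#' BCPNN information component
#'
#' @inheritParams ror
#' @return list: `ic`, `ic025`, `flag_bcpnn`. Finite for every table.
#' @export
bcpnn_ic <- function(t) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(ic = s$ic, ic025 = s$ic025, flag_bcpnn = s$flag_bcpnn)
}

#' Simplified empirical Bayes geometric mean
#'
#' The printed simplified form — observed over expected with a log-normal
#' lower bound — not the full gamma-Poisson mixture fit.
#'
#' @inheritParams ror
#' @return list: `ebgm`, `ebgm05`, `flag_mgps`.
#' @export
ebgm <- function(t) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(ebgm = s$ebgm, ebgm05 = s$ebgm05, flag_mgps = s$flag_mgps)
}

# shared 2x2 counting; unit "mentions" counts (report, PT) rows,
# unit "reports" counts distinct reports
.pt_margins <- function(dataset, drug_label, unit = c("mentions", "reports")) {
  unit <- match.arg(unit)
  if (!drug_label %in% names(dataset$exposure)) {
    stop("unknown drug label: ", drug_label)
  }
  ev <- dataset$events
  if (unit == "reports") ev <- unique(ev, by = c("primaryid", "pt"))
  exposed <- dataset$exposure[[drug_label]]
  is_exp <- ev$primaryid %in% exposed
  list(ev = ev, is_exp = is_exp,
       n_total = if (unit == "mentions") nrow(ev) else nrow(dataset$cases),
       n_exp = if (unit == "mentions") sum(is_exp) else
         sum(dataset$cases$primaryid %in% exposed))
}

#' Build the 2x2 table for one (drug, PT) pair
#'
#' With the default `unit = "mentions"` the counting unit is the
#' (report, PT) mention: `a` = mentions of the target PT among exposed
#' reports, `b` = other-PT mentions among exposed reports, `c` = target-PT
#' mentions among all other reports, `d` = the rest, so the four cells sum
#' to the total number of event mentions. `unit = "reports"` counts distinct
#' reports instead (each report contributes once per PT, and `N` is the
#' number of deduplicated reports).
#'
#' @param dataset a `faers_dataset` from [build_dataset()].
#' @param drug_label a label present in `dataset$exposure`.
#' @param pt preferred term (matched case-insensitively after trimming).
#' @param unit `"mentions"` (default) or `"reports"`.
#' @return a [contingency()] table. A PT absent from the dataset yields
#'   `a = c = 0` (not an error).
#' @export
make_contingency <- function(dataset, drug_label, pt,
                             unit = c("mentions", "reports")) {
  m <- .pt_margins(dataset, drug_label, unit)
  is_pt <- .norm_term(m$ev$pt) == .norm_term(pt)
  a <- sum(is_pt & m$is_exp)
  cc <- sum(is_pt & !m$is_exp)
  b <- m$n_exp - a
  d <- m$n_total - a - b - cc
  contingency(a, b, cc, d)
}

#' Screen every PT reported with a drug
#'
#' One row per distinct preferred term occurring in the drug's exposed set,
#' with all four estimators, their interval bounds, the per-method flags and
#' the conjunctive `positive` flag, sorted by descending ROR (ties: larger
#' `a` first, then PT alphabetically; NA ROR last).
#'
#' @inheritParams make_contingency
#' @return a `data.table`: `drug_label`, `pt`, the four cells and all
#'   statistics of [disprop_stats()].
#' @export
screen_signals <- function(dataset, drug_label,
                           unit = c("mentions", "reports")) {
  m <- .pt_margins(dataset, drug_label, unit)
  ev <- m$ev
  pt_tot <- ev[, .(m_pt = .N), by = pt]
  pt_exp <- ev[m$is_exp, .(a = .N), by = pt]
  tab <- merge(pt_exp, pt_tot, by = "pt")
  if (nrow(tab) == 0L) {
    out <- disprop_stats(numeric(0), numeric(0), numeric(0), numeric(0))
    return(cbind(data.table(drug_label = character(0), pt = character(0)), out))
  }
  tab[, b := m$n_exp - a]
  tab[, cc := m_pt - a]
  tab[, d := m$n_total - a - b - cc]
  stats <- disprop_stats(tab$a, tab$b, tab$cc, tab$d)
  out <- cbind(data.table(drug_label = drug_label, pt = tab$pt), stats)
  setorderv(out, c("ror", "a", "pt"), order = c(-1L, -1L, 1L), na.last = TRUE)
  out[]
}

#' Compute all statistics for a plain table of counts
#'
#' The screening statistics without any FAERS input: takes rows of labelled
#' 2x2 cells, as read from a CSV with columns `label, a, b, c, d`, and
#' returns the full statistic set. This is the engine behind the `screen`
#' command-line subcommand.
#'
#' @param counts data.frame with columns `label`, `a`, `b`, `c`, `d`.
#' @return `data.table` with `label` plus all [disprop_stats()] columns.
#' @export
signal_stats_table <- function(counts) {
  counts <- as.data.table(counts)
  need <- c("label", "a", "b", "c", "d")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  cbind(counts[, .(label)],
        disprop_stats(counts$a, counts$b, counts$c, counts$d))
}
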