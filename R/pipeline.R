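#' @name pipeline
#' @title Pipeline configuration and command-line entry
#' @description
#' A flat YAML-style `key: value` configuration drives the end-to-end run:
#' input directory, drug queries, counting unit, top-N, PT/SOC map path,
#' output directory. [run_pipeline()] executes ingest -> screen -> report
#' and writes every surface as TSV; [pv_cli()] wraps it (plus `simulate`
#' and `screen`) for `Rscript` use — see `inst/cli/pvsignal.R`.
NULL

#' Read a flat key: value configuration file
#'
#' Lines are `key: value`; `#` starts a comment; repeated keys collect into
#' vectors; values are split on commas for list-valued keys. This is a
#' deliberately minimal subset of YAML — enough for the pipeline, with no
#' external dependency.
#'
#' @param path config file path.
#' @return named list of character vectors.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- m[2]
    val <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    cfg[[key]] <- c(cfg[[key]], val[nzchar(val)])
  }
  cfg
}

.cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

# queries from config keys: drug.<label>.generic / drug.<label>.brand
.queries_from_config <- function(cfg) {
  keys <- grep("^drug\\.", names(cfg), value = TRUE)
  labels <- unique(sub("^drug\\.([^.]+)\\..*$", "\\1", keys))
  lapply(labels, function(lab) {
    drug_query(lab,
               generic_names = .cfg_get(cfg, paste0("drug.", lab, ".generic"),
                                        character()),
               brand_names = .cfg_get(cfg, paste0("drug.", lab, ".brand"),
                                      character()))
  })
}

#' Run the full pipeline from a configuration
#'
#' Reads quarter files from `input_dir`, builds the analysis dataset for
#' the configured drug queries, screens every PT per drug, and writes the
#' reporting surfaces (`signals_<drug>.tsv`, `demographics.tsv`,
#' `soc_frequencies.tsv` when a map is configured, `method_comparison.tsv`,
#' `intersections.tsv`, `signal_matrix.csv`, `dedup_log.tsv`) to
#' `output_dir`.
#'
#' @param config a config list from [read_pipeline_config()], or a path.
#' @return invisibly, a list with the dataset, per-drug results and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  input_dir <- .cfg_get(config, "input_dir")
  output_dir <- .cfg_get(config, "output_dir", "pvsignal_out")
  if (is.null(input_dir)) stop("config needs input_dir")
  unit <- .cfg_get(config, "unit", "mentions")
  top_n <- as.integer(.cfg_get(config, "top_n", "20"))
  queries <- .queries_from_config(config)
  if (length(queries) == 0L) stop("config defines no drug queries")
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  raw <- read_quarter_dir(input_dir)
  cases <- parse_demo(raw$demo)
  ds <- build_dataset(cases, raw$drug, raw$reac, queries)

  results <- lapply(names(ds$exposure), function(lab) {
    screen_signals(ds, lab, unit = unit)
  })
  names(results) <- names(ds$exposure)

  paths <- character(0)
  for (lab in names(results)) {
    p <- file.path(output_dir, paste0("signals_", lab, ".tsv"))
    write_delimited(results[[lab]], p)
    paths <- c(paths, p)
  }
  p <- file.path(output_dir, "demographics.tsv")
  write_delimited(demographics(ds), p); paths <- c(paths, p)

  pooled <- rbindlist(results)
  p <- file.path(output_dir, "method_comparison.tsv")
  write_delimited(cbind(data.table(drug_label = "pooled"),
                        method_comparison(pooled)), p)
  paths <- c(paths, p)

  pos_sets <- lapply(results, function(r) r[positive == TRUE, pt])
  if (length(pos_sets) >= 2L) {
    p <- file.path(output_dir, "intersections.tsv")
    write_delimited(intersect_signals(pos_sets), p); paths <- c(paths, p)
  }

  map_path <- .cfg_get(config, "pt_soc_map")
  if (!is.null(map_path)) {
    map <- load_pt_soc_map(map_path)
    p <- file.path(output_dir, "soc_frequencies.tsv")
    write_delimited(aggregate_soc(pooled, map), p); paths <- c(paths, p)
  }

  mat <- heatmap_matrix(results, n = top_n)
  p <- file.path(output_dir, "signal_matrix.csv")
  write_delimited(signal_matrix_long(mat), p, delim = ","); paths <- c(paths, p)

  p <- file.path(output_dir, "dedup_log.tsv")
  write_delimited(as.data.table(as.list(ds$dedup_log)), p); paths <- c(paths, p)

  invisible(list(dataset = ds, results = results, matrix = mat,
                 paths = paths))
}

#' Command-line entry point
#'
#' Subcommands:
#' * `simulate --out DIR [--seed S] [--n-reports N]` — write synthetic
#'   quarters plus the truth sidecar;
#' * `screen --in counts.csv --out stats.tsv` — statistics for a plain CSV
#'   of `label,a,b,c,d` rows (no FAERS input needed);
#' * `report --config FILE` — run the full pipeline.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status 0 invisibly; stops with a message on usage errors.
#' @export
pv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: pvsignal <simulate|screen|report> [options]",
                 " simulate --out DIR [--seed S] [--n-reports N]",
                 " screen --in counts.csv --out stats.tsv",
                 " report --config FILE", sep = "\n")
  if (length(args) == 0L) stop(usage, call. = FALSE)
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cmd <- args[1L]
  if (cmd == "simulate") {
    out <- opt("--out"); if (is.null(out)) stop(usage, call. = FALSE)
    cfg <- synth_config(
      n_reports = as.integer(opt("--n-reports", "5000")),
      seed = as.integer(opt("--seed", "1")))
    res <- synth_generate(cfg, dir = out)
    message("wrote ", length(res$files), " files to ", out)
  } else if (cmd == "screen") {
    inp <- opt("--in"); out <- opt("--out")
    if (is.null(inp) || is.null(out)) stop(usage, call. = FALSE)
    counts <- fread(inp)
    write_delimited(signal_stats_table(counts), out)
    message("wrote ", out)
  } else if (cmd == "report") {
    cfgp <- opt("--config"); if (is.null(cfgp)) stop(usage, call. = FALSE)
    res <- run_pipeline(cfgp)
    message("wrote ", length(res$paths), " output files")
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
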