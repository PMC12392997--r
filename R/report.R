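# Pipeline orchestration and tabular outputs.  `run_pipeline()` is the
# programmatic entry point behind the thin Rscript wrapper in inst/cli/.

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("usage error: unexpected argument '", a, "'", call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("usage error: missing value for --", key, call. = FALSE)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Write result tables with a run manifest
#'
#' Writes each named data frame to `<destination>/<name>.csv` with full
#' numeric precision (numeric columns additionally get a 2-decimal
#' `<name>_2dp` display column) and a `manifest.json` recording the
#' command, seeds, config hash and every file written.
#'
#' @param results Named list of data frames.
#' @param destination Output directory (created if needed).
#' @param manifest Extra manifest fields (command, seed, config path).
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, destination, manifest = list()) {
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(results)) {
    df <- results[[nm]]
    for (col in names(df)) {
      if (is.numeric(df[[col]]) && !col %in% c("iteration", "wtp", "value"))
        df[[paste0(col, "_2dp")]] <- round(df[[col]], 2)
    }
    path <- file.path(destination, paste0(nm, ".csv"))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = TRUE)
    files <- c(files, path)
  }
  man <- c(manifest,
           list(package_version = as.character(utils::packageVersion("ugcscreen")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                outputs = as.list(files)))
  jsonlite::write_json(man, file.path(destination, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "cost", "qalys")
  if (!all(need %in% names(df)))
    stop("outcomes file must have columns code, cost, qalys", call. = FALSE)
  for (col in setdiff(names(df), "code")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Run a pipeline subcommand
#'
#' Subcommands: `synth` (write a synthetic config; `--seed`, `--out`),
#' `run` (evaluate strategies; `--config`, `--out-dir`, optional
#' `--strategies all|code,code,...`), `frontier` (`--outcomes` CSV or
#' `--config`, `--out-dir`), `dsa` (`--config`, `--param`, `--out-dir`),
#' `psa` (`--config`, `--n`, `--seed`, `--out-dir`) and `ceac`
#' (`--psa` CSV, `--wtp-grid lo:hi:step`, `--out-dir`).
#'
#' @param command One of `synth`, `run`, `frontier`, `dsa`, `psa`, `ceac`.
#' @param args Character vector of `--key value` options.
#' @return Invisibly, the primary result object.
#' @export
run_pipeline <- function(command, args = character()) {
  command <- match.arg(command,
                       c("synth", "run", "frontier", "dsa", "psa", "ceac"))
  opt <- parse_cli_args(args)
  outdir <- if (!is.null(opt[["out-dir"]])) opt[["out-dir"]] else "."
  load_cfg <- function() {
    if (is.null(opt$config))
      stop("usage error: --config is required", call. = FALSE)
    load_parameter_set(opt$config)
  }
  manifest_base <- function() list(
    command = command,
    options = opt,
    config_md5 = if (!is.null(opt$config))
      unname(tools::md5sum(opt$config)) else NULL)
  pick_strategies <- function() {
    sel <- opt$strategies
    if (is.null(sel) || identical(sel, "all")) return(enumerate_strategies())
    codes <- strsplit(sel, ",")[[1]]
    stats::setNames(lapply(codes, parse_strategy), codes)
  }

  switch(command,
    synth = {
      seed <- as.integer(if (is.null(opt$seed)) 42L else opt$seed)
      if (is.null(opt$out)) stop("usage error: --out is required", call. = FALSE)
      ps <- synth_parameter_set(synthetic_spec(seed = seed))
      write_parameter_config(ps, opt$out)
      invisible(ps)
    },
    run = {
      ps <- load_cfg()
      res <- evaluate_strategies(ps, pick_strategies())
      res$cost_10k <- res$cost / 1e4
      res$cur <- cost_utility_ratio(res)
      write_results(list(outcomes = res), outdir, manifest_base())
      invisible(res)
    },
    frontier = {
      df <- if (!is.null(opt$outcomes)) read_outcomes_csv(opt$outcomes)
            else {
              ps <- load_cfg()
              evaluate_strategies(ps, pick_strategies())
            }
      fr <- efficient_frontier(df)
      tab <- fr$frontier
      tab$cost_10k <- tab$cost / 1e4
      tab$inc_cost_10k_neighbor <- tab$inc_cost_neighbor / 1e4
      write_results(list(frontier = tab, excluded = fr$excluded),
                    outdir, manifest_base())
      invisible(fr)
    },
    dsa = {
      ps <- load_cfg()
      if (is.null(opt$param)) stop("usage error: --param is required", call. = FALSE)
      strategies <- pick_strategies()
      sweep <- one_way_sweep(ps, opt$param, strategies = strategies)
      torn <- tornado_table(ps, params = opt$param, strategies = strategies)
      write_results(list(sweep = sweep, tornado = torn), outdir,
                    manifest_base())
      invisible(torn)
    },
    psa = {
      ps <- load_cfg()
      n <- as.integer(if (is.null(opt$n)) 1000L else opt$n)
      seed <- as.integer(if (is.null(opt$seed)) 1L else opt$seed)
      psa <- run_psa(ps, n = n, seed = seed, strategies = pick_strategies())
      write_results(list(psa = psa), outdir,
                    c(manifest_base(), list(seed = seed, n = n)))
      invisible(psa)
    },
    ceac = {
      if (is.null(opt$psa)) stop("usage error: --psa is required", call. = FALSE)
      psa <- utils::read.csv(opt$psa, stringsAsFactors = FALSE)
      psa$iteration <- as.integer(psa$iteration)
      psa$cost <- as.numeric(psa$cost); psa$qalys <- as.numeric(psa$qalys)
      lambdas <- if (is.null(opt[["wtp-grid"]])) seq(0, 3 * 70653, by = 5000)
        else {
          g <- as.numeric(strsplit(opt[["wtp-grid"]], ":")[[1]])
          if (length(g) != 3L || any(is.na(g)) || g[3] <= 0 || g[2] < g[1])
            stop("usage error: malformed --wtp-grid, expected lo:hi:step",
                 call. = FALSE)
          seq(g[1], g[2], by = g[3])
        }
      cc <- compute_ceac(psa, lambdas)
      write_results(list(ceac = cc), outdir, manifest_base())
      invisible(cc)
    })
}

#' Export a cohort trace as tidy tables
#'
#' @param trace A `ugc_trace`.
#' @param destination Output directory.
#' @return Invisibly the manifest, after writing `trace.csv` (cycle, age,
#'   state, occupancy) and `events.csv`.
#' @export
export_trace <- function(trace, destination) {
  occ <- trace$occupancy
  long <- data.frame(
    cycle = rep(seq_len(nrow(occ)) - 1L, times = ncol(occ)),
    age = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ), stringsAsFactors = FALSE)
  write_results(list(trace = long, events = trace$events), destination,
                list(command = "export_trace", strategy = trace$strategy))
}
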