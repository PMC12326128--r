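#' Write an experiment result to CSV with a JSON run manifest
#'
#' Writes the tidy trial and summary tables of an experiment object
#' (`av_bias_table`, `av_sw_grid`, `av_rt_task`, `av_sensitivity`) to
#' `<prefix>_trials.csv` / `<prefix>_summary.csv` and a manifest
#' `<prefix>_manifest.json` holding the full configuration snapshot, the
#' seed, the package version, timestamps and MD5 checksums of every written
#' file. Re-running the same experiment with the manifest's config and seed
#' reproduces the checksummed outputs.
#'
#' @param result an experiment result object.
#' @param prefix output path prefix (directories are created).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(result, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  tabs <- list()
  if (is.data.frame(result)) {
    tabs$table <- result
  } else {
    for (nm in intersect(c("trials", "records", "summary"), names(result))) {
      tabs[[nm]] <- result[[nm]]
    }
  }
  for (nm in names(tabs)) {
    f <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(tabs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  params <- if (!is.data.frame(result) && !is.null(result$params)) {
    unclass(result$params)
  } else NULL
  manifest <- list(
    tool = "avnet",
    version = as.character(utils::packageVersion("avnet")),
    seed = if (!is.data.frame(result)) result$seed else NULL,
    config = params,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  mf <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Command-line dispatcher for the experiment battery
#'
#' Thin entry point used by the shipped `avnet` Rscript (see
#' `system.file("cli", "avnet", package = "avnet")`). Subcommands:
#' `simulate`, `rt-task`, `ventriloquism`, `sw-grid`, `bias-grid`,
#' `sensitivity`, `race-analysis`. Common flags: `--config` (key=value
#' parameter file), `--seed`, `--out-dir`, `--reps`, and per-command extras
#' (`--disparities`, `--isis`, `--trials`, `--literal-grid`, `--quiet`).
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status, invisibly: 0 on success, non-zero on a
#'   usage or configuration error (a message naming the offending option is
#'   printed on stderr; the function never calls `q()` itself).
#' @export
av_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: avnet <command> [options]",
    "commands: simulate | rt-task | ventriloquism | sw-grid | bias-grid |",
    "          sensitivity | race-analysis",
    "options: --config FILE  --seed INT  --out-dir DIR  --reps INT",
    "         --trials INT  --disparities a,b,c  --isis a,b,c",
    "         --literal-grid  --quiet", sep = "\n")
  fail <- function(...) {
    message(...)
    return(invisible(1L))
  }
  if (length(argv) < 1L) return(fail(usage))
  cmd <- argv[[1]]
  args <- argv[-1]
  opts <- list(config = NULL, seed = 1L, out_dir = "avnet-results",
               reps = NULL, trials = 120L, disparities = NULL, isis = NULL,
               literal_grid = FALSE, quiet = FALSE)
  parsed <- tryCatch({
    i <- 1L
    while (i <= length(args)) {
      a <- args[[i]]
      take <- function() {
        if (i + 1L > length(args)) stop("missing value for option ", a)
        args[[i + 1L]]
      }
      step <- 2L
      switch(a,
        "--config" = opts$config <- take(),
        "--seed" = opts$seed <- as.integer(take()),
        "--out-dir" = opts$out_dir <- take(),
        "--reps" = opts$reps <- as.integer(take()),
        "--trials" = opts$trials <- as.integer(take()),
        "--disparities" = opts$disparities <-
          as.numeric(strsplit(take(), ",")[[1]]),
        "--isis" = opts$isis <- as.numeric(strsplit(take(), ",")[[1]]),
        "--literal-grid" = { opts$literal_grid <- TRUE; step <- 1L },
        "--quiet" = { opts$quiet <- TRUE; step <- 1L },
        stop("unknown option ", a)
      )
      i <- i + step
    }
    TRUE
  }, error = function(e) e)
  if (inherits(parsed, "error")) return(fail(conditionMessage(parsed)))
  if (any(is.na(c(opts$seed, opts$trials)))) {
    return(fail("options --seed/--trials/--reps require integer values"))
  }
  p <- tryCatch(
    if (is.null(opts$config)) av_params() else read_av_config(opts$config),
    error = function(e) e
  )
  if (inherits(p, "error")) return(fail("config error: ", conditionMessage(p)))
  say <- function(...) if (!opts$quiet) message(...)
  reps <- function(default) if (is.null(opts$reps)) default else opts$reps
  say("avnet ", cmd, " (seed ", opts$seed, ")")
  res <- tryCatch(switch(cmd,
    "simulate" = {
      sq <- make_rt_sequence(opts$trials, p, seed = opts$seed)
      sim <- simulate_network(sq$events, p, record_stride_ms = 1)
      f <- file.path(opts$out_dir, "simulate_trace.csv")
      dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(sim$trace, f, row.names = FALSE)
      write_trial_sequence(sq, file.path(opts$out_dir, "simulate_events.csv"))
      structure(list(trials = sq$trials, summary = NULL, seed = opts$seed,
                     params = p), class = "av_rt_task")
    },
    "rt-task" = run_rt_task(opts$trials, p, seed = opts$seed),
    "ventriloquism" = run_ventriloquism(
      disparities = if (is.null(opts$disparities)) c(0, 5, 10, 15, 20)
                    else opts$disparities,
      n_reps = reps(100), params = p, seed = opts$seed),
    "sw-grid" = run_sw_grid(
      isis = if (is.null(opts$isis)) c(seq(0, 1000, 100), seq(1250, 3000, 250))
             else opts$isis,
      disparities = if (is.null(opts$disparities)) seq(0, 20, 5)
                    else opts$disparities,
      n_reps = reps(100), params = p, seed = opts$seed),
    "bias-grid" = run_bias_vs_isi(
      isis = if (is.null(opts$isis)) c(200, 500, 800) else opts$isis,
      disparities = if (is.null(opts$disparities)) c(5, 10, 15, 20)
                    else opts$disparities,
      n_reps = reps(250), params = p, seed = opts$seed),
    "sensitivity" = run_sensitivity(
      n_reps = reps(100), params = p, seed = opts$seed,
      literal_grid = opts$literal_grid),
    "race-analysis" = {
      task <- run_rt_task(opts$trials, p, seed = opts$seed)
      ra <- race_analysis(task)
      dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
      cdf <- data.frame(grid_ms = ra$grid_ms, p_a = ra$cdf_a$p,
                        p_v = ra$cdf_v$p, p_av = ra$cdf_av$p,
                        p_race = ra$cdf_race$p)
      utils::write.csv(cdf, file.path(opts$out_dir, "race_cdfs.csv"),
                       row.names = FALSE)
      areas <- data.frame(gain = ra$gain, benefit_av = ra$benefit_av,
                          benefit_race = ra$benefit_race)
      utils::write.csv(areas, file.path(opts$out_dir, "race_areas.csv"),
                       row.names = FALSE)
      task
    },
    return(fail("unknown command '", cmd, "'\n", usage))
  ), error = function(e) e)
  if (inherits(res, "error")) {
    return(fail("error: ", conditionMessage(res)))
  }
  write_results(res, file.path(opts$out_dir, gsub("-", "_", cmd)))
  say("results written to ", opts$out_dir)
  invisible(0L)
}
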