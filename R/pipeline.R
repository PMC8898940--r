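#' Run the full seasonal-change analysis
#'
#' End-to-end orchestration over a paired cohort table: input validation,
#' effect-size summary, per-technique percent-change matrix,
#' EBIC-graphical-lasso partial-correlation network, and z-scored
#' centrality table, with every artifact written to `out_dir`:
#'
#' * `effects.csv` / `effects.json` -- effect-size table over all
#'   variables;
#' * per technique: `weights_<tech>.csv` (+ `_full`, `_edges`,
#'   optional `.graphml`), `centrality_<tech>.csv` (+ `_raw`),
#'   `ebic_trace_<tech>.csv`;
#' * `run_summary.json` and `swimnet.log` -- selected penalty, edge count
#'   and EBIC per technique, package version, seed and configuration echo.
#'
#' The pipeline is deterministic: identical input and configuration give
#' identical numeric outputs. The seed is recorded for provenance and
#' seeds any downstream resampling; the estimation itself involves no
#' randomness.
#'
#' @param input Cohort data frame or path to the standard input CSV.
#' @param out_dir Output directory (created if absent).
#' @param techniques Techniques to analyse, subset of
#'   `c("breast", "fly")`.
#' @param gamma,n_lambda,lambda_min_ratio Network-estimation settings,
#'   see [pcnetwork()].
#' @param seed Integer seed, logged and set before the run.
#' @param digits Rounding for display tables, default 2 (full-precision
#'   companions are always written).
#' @param graphml Also write GraphML network exports, default `FALSE`.
#' @return Invisibly, a list with `effects`, per-technique `networks` and
#'   `centrality`, `violations` (empty), and `files`.
#' @export
run_pipeline <- function(input, out_dir, techniques = c("breast", "fly"),
                         gamma = 0.25, n_lambda = 100L,
                         lambda_min_ratio = 0.01, seed = 1L, digits = 2,
                         graphml = FALSE) {
  techniques <- match.arg(techniques, several.ok = TRUE)
  if (is.character(input)) input <- read_cohort(input)
  viol <- validate_cohort(input)
  if (nrow(viol) > 0) {
    swim_stop(sprintf("input validation failed (%d violation%s): %s",
                      nrow(viol), if (nrow(viol) == 1) "" else "s",
                      paste(utils::head(viol$message, 5), collapse = "; ")),
              "swimnet_validation_error", violations = viol)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  files <- character()
  log_lines <- c(
    sprintf("swimnet %s", as.character(packageVersion("swimnet"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed = %d", as.integer(seed)),
    sprintf("gamma = %g, n_lambda = %d, lambda_min_ratio = %g",
            gamma, as.integer(n_lambda), lambda_min_ratio),
    sprintf("techniques = %s", paste(techniques, collapse = ", ")),
    sprintf("swimmers = %d", length(unique(input$swimmer_id)))
  )
  effects <- effect_table(input, techniques)
  files <- c(files, write_effect_table(
    effects, file.path(out_dir, "effects.csv")))
  networks <- list()
  centrality <- list()
  summary_list <- list(
    package = "swimnet",
    version = as.character(packageVersion("swimnet")),
    seed = as.integer(seed),
    gamma = gamma, n_lambda = as.integer(n_lambda),
    lambda_min_ratio = lambda_min_ratio,
    techniques = list()
  )
  for (tech in techniques) {
    x <- change_matrix(input, tech)
    fit <- pcnetwork(x, gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
    ct <- centrality_table(fit)
    networks[[tech]] <- fit
    centrality[[tech]] <- ct
    wpath <- file.path(out_dir, sprintf("weights_%s.csv", tech))
    files <- c(files, write_weight_matrix(
      fit, wpath, digits = digits,
      graphml = if (graphml) file.path(out_dir,
                                       sprintf("network_%s.graphml", tech))
                else NULL))
    files <- c(files, write_centrality(
      ct, file.path(out_dir, sprintf("centrality_%s.csv", tech)),
      digits = digits))
    tpath <- file.path(out_dir, sprintf("ebic_trace_%s.csv", tech))
    write.csv(fit$trace, tpath, row.names = FALSE)
    files <- c(files, tpath)
    E <- edge_count(fit$weights, fit$threshold)
    log_lines <- c(log_lines, sprintf(
      "%s: selected lambda = %.6g, edges = %d, EBIC = %.4f",
      toupper(tech), fit$lambda, E, fit$ebic))
    summary_list$techniques[[tech]] <- list(
      lambda = fit$lambda, edges = E, ebic = fit$ebic)
  }
  spath <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary_list, spath, auto_unbox = TRUE, digits = NA)
  lpath <- file.path(out_dir, "swimnet.log")
  writeLines(log_lines, lpath)
  files <- c(files, spath, lpath)
  invisible(list(effects = effects, networks = networks,
                 centrality = centrality, violations = viol,
                 files = files))
}

# ---------------------------------------------------------------------------
# Thin command-line front end (see inst/cli/swimnet.R). Subcommands map
# one-to-one onto exported functions; this function returns an exit
# status instead of quitting so it can be tested in-process.
# 0 = success, 2 = validation failure, 3 = convergence failure.

cli_usage <- function() {
  paste(
    "usage: swimnet <command> [options]",
    "commands:",
    "  simulate   --out <csv> [--truth <json>] [--n-girls N] [--n-boys N] [--seed N]",
    "  sample-ggm --out <csv> --truth <json> --p N --density X --n N [--seed N]",
    "  validate   --input <csv>",
    "  describe   --input <csv> --out <csv>",
    "  network    --input <csv> --out-dir <dir> [--technique T] [--gamma X]",
    "  centrality --input <csv> --out-dir <dir> [--technique T] [--gamma X]",
    "  run        --input <csv> --out-dir <dir> [--gamma X] [--n-lambda N]",
    "             [--lambda-min-ratio X] [--seed N] [--graphml]",
    sep = "\n")
}

cli_opts <- function(args) {
  opts <- list(flags = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      swim_stop(sprintf("unexpected argument '%s'", a), "swimnet_cli_error")
    }
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts$flags <- c(opts$flags, key)
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

opt_or <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else opts[[key]]
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the bundled `swimnet` command-line
#' script (`system.file("cli", "swimnet.R", package = "swimnet")`):
#' `simulate`, `sample-ggm`, `validate`, `describe` (effect table only),
#' `network`, `centrality` and `run` (full pipeline). Implemented as a
#' regular function returning the exit status (0 success, 2 validation
#' failure, 3 convergence failure) so it can be driven in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
swimnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- args[1]
  opts <- tryCatch(cli_opts(args[-1]), swimnet_error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts))
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(
      cmd,
      simulate = {
        sim <- simulate_cohort(cohort_config(
          n_girls = as.integer(opt_or(opts, "n_girls", 11L)),
          n_boys = as.integer(opt_or(opts, "n_boys", 9L)),
          seed = as.integer(opt_or(opts, "seed", 1L))))
        write.csv(sim$cohort, opts$out, row.names = FALSE)
        if (!is.null(opts$truth)) {
          jsonlite::write_json(
            list(latent_factor = sim$truth$latent_factor,
                 change_targets = sim$truth$config$change),
            opts$truth, auto_unbox = TRUE, digits = NA)
        }
        0L
      },
      `sample-ggm` = {
        gg <- sample_ggm(p = as.integer(opts$p),
                         edge_density = as.numeric(opts$density),
                         n = as.integer(opts$n),
                         seed = as.integer(opt_or(opts, "seed", 1L)))
        write.csv(gg$data, opts$out, row.names = FALSE)
        jsonlite::write_json(
          list(theta = gg$truth$theta, edges = gg$truth$edges),
          opts$truth, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
        0L
      },
      validate = {
        viol <- validate_cohort(opts$input)
        if (nrow(viol) == 0) {
          message("input is valid")
          0L
        } else {
          message(paste(sprintf("[row %s] %s: %s", viol$row, viol$rule,
                                viol$message), collapse = "\n"))
          2L
        }
      },
      describe = {
        et <- effect_table(read_cohort(opts$input))
        write_effect_table(et, opts$out)
        0L
      },
      network = ,
      centrality = ,
      run = {
        res <- run_pipeline(
          opts$input, opts$out_dir,
          techniques = if (is.null(opts$technique)) c("breast", "fly")
                       else opts$technique,
          gamma = as.numeric(opt_or(opts, "gamma", 0.25)),
          n_lambda = as.integer(opt_or(opts, "n_lambda", 100L)),
          lambda_min_ratio = as.numeric(opt_or(opts, "lambda_min_ratio",
                                               0.01)),
          seed = as.integer(opt_or(opts, "seed", 1L)),
          graphml = "graphml" %in% opts$flags)
        0L
      },
      {
        message(cli_usage())
        2L
      })
  },
  swimnet_validation_error = function(e) {
    message(conditionMessage(e))
    2L
  },
  swimnet_convergence_error = function(e) {
    message(conditionMessage(e))
    3L
  },
  swimnet_error = function(e) {
    message(conditionMessage(e))
    2L
  })
  invisible(status)
}
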