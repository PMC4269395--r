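# End-to-end pipeline and the command-line interface.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full registry-to-reports pipeline
#'
#' Executes ingest -> deduplicate -> classify -> network -> metrics +
#' trends + conditions, writing into `output_dir`: the edge list
#' (`edges.csv`), GraphML and GEXF exports, connectivity and participation
#' tables, the trend series and summary, the condition-by-region table, and
#' a run log (`run_log.txt`) with record counts at every filter stage in
#' pipeline order (records read, unique studies, single-nation /
#' multinational / unlocated, dated multinational). All writers are sorted
#' and timestamp-free, so repeated runs on the same input are
#' byte-identical.
#'
#' @param input Path to the registry file.
#' @param output_dir Directory for all outputs (created if missing).
#' @param format Input dialect, see [read_registry()].
#' @param region_map Named country -> region vector.
#' @param aliases Named alias -> canonical vector.
#' @param strict Fatal (`TRUE`) vs warn-and-continue handling of malformed
#'   records and unmapped countries.
#' @param policy Region attribution policy, see
#'   [region_connection_totals()].
#' @param growth_method `"mean_yoy"` or `"cagr"`.
#' @param growth_window Optional length-2 year vector for annualized
#'   growth.
#' @param top_k Number of strongest edges and condition ranks to report.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the registry, network, reports, trend
#'   series, condition table and stage counts.
#' @export
run_pipeline <- function(input, output_dir, format = c("tsv", "ctgov_xml"),
                         region_map = default_region_map(),
                         aliases = default_alias_table(),
                         strict = FALSE,
                         policy = c("endpoint_half", "endpoint_full"),
                         growth_method = c("mean_yoy", "cagr"),
                         growth_window = NULL, top_k = 10L, quiet = FALSE) {
  format <- match.arg(format)
  policy <- match.arg(policy)
  growth_method <- match.arg(growth_method)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  raw <- .stage("ingest", read_registry(input, format = format,
                                        aliases = aliases, strict = strict,
                                        quiet = quiet))
  studies <- .stage("deduplicate", deduplicate_studies(raw))
  scope <- .stage("classify", classify_scope(studies))
  mult <- studies[scope == "multinational", , drop = FALSE]
  rownames(mult) <- NULL
  counts <- list(records_read = nrow(raw),
                 unique_studies = nrow(studies),
                 single_nation = sum(scope == "single_nation"),
                 multinational = sum(scope == "multinational"),
                 unlocated = sum(scope == "unlocated"),
                 dated_multinational = sum(!is.na(mult$start_year)))
  say("records read: ", counts$records_read,
      "; unique studies: ", counts$unique_studies,
      "; multinational: ", counts$multinational)

  net <- .stage("network", build_network(mult))
  .stage("network", {
    write_edge_list(net, file.path(output_dir, "edges.csv"))
    write_network_graphml(net, file.path(output_dir, "network.graphml"),
                          region_map = region_map)
    write_network_gexf(net, file.path(output_dir, "network.gexf"),
                       region_map = region_map)
  })
  conn <- .stage("metrics", connectivity_report(net, region_map,
                                                policy = policy, k = top_k,
                                                strict = strict))
  part <- .stage("metrics", participation_report(mult, region_map,
                                                 strict = strict))
  .stage("metrics", {
    write_connectivity_report(conn, output_dir)
    write_participation_report(part, output_dir)
  })
  series <- .stage("trends", studies_per_year(mult, quiet = quiet))
  .stage("trends", write_trend_series(series, output_dir,
                                      growth_window = growth_window,
                                      method = growth_method))
  ctab <- .stage("conditions",
                 condition_region_table(mult, region_map, k = top_k,
                                        strict = strict))
  .stage("conditions",
         write_condition_table(ctab, file.path(output_dir,
                                               "conditions.csv")))
  log_lines <- c(
    paste0("records_read: ", counts$records_read),
    paste0("unique_studies: ", counts$unique_studies),
    paste0("single_nation: ", counts$single_nation),
    paste0("multinational: ", counts$multinational),
    paste0("unlocated: ", counts$unlocated),
    paste0("dated_multinational: ", counts$dated_multinational),
    paste0("network_countries: ", nrow(net$nodes)),
    paste0("network_edges: ", nrow(net$edges)),
    paste0("total_connections: ", total_connections(net)))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(list(registry = studies, multinational = mult, network = net,
                 connectivity = conn, participation = part, trends = series,
                 conditions = ctab, counts = counts))
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE        # bare flag
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.cli_get <- function(opts, key, default = NULL, required = FALSE) {
  if (!is.null(opts[[key]])) return(opts[[key]])
  if (required) stop("missing required option --", key)
  default
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `ingest`, `build-network`,
#' `metrics`, `trends`, `conditions` (individual stages) and `simulate`
#' (write a seeded synthetic registry plus ground truth). Common options:
#' `--input PATH`, `--format tsv|ctgov_xml`, `--out DIR`,
#' `--region-map PATH`, `--aliases PATH`, `--strict`,
#' `--policy endpoint_half|endpoint_full`,
#' `--growth-method mean_yoy|cagr`, `--top-k N`; `simulate` takes `--n N`
#' and `--seed N`. An executable wrapper ships in `inst/cli/trialnet`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, an exit status: 0 on success, 1 on error (the error
#'   message, tagged with the failing stage, goes to stderr).
#' @export
trialnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      stop("usage: trialnet <run|ingest|build-network|metrics|trends|",
           "conditions|simulate> [--options]")
    }
    cmd <- args[1L]
    opts <- .cli_opts(args[-1L])
    out <- .cli_get(opts, "out", required = TRUE)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    strict <- isTRUE(opts[["strict"]])
    region_map <- if (!is.null(opts[["region-map"]])) {
      read_region_map(opts[["region-map"]])
    } else default_region_map()
    aliases <- if (!is.null(opts[["aliases"]])) {
      read_alias_table(opts[["aliases"]])
    } else default_alias_table()
    load_mult <- function() {
      reg <- read_registry(.cli_get(opts, "input", required = TRUE),
                           format = .cli_get(opts, "format", "tsv"),
                           aliases = aliases, strict = strict, quiet = TRUE)
      filter_multinational(deduplicate_studies(reg))
    }
    switch(cmd,
      run = {
        run_pipeline(.cli_get(opts, "input", required = TRUE), out,
                     format = .cli_get(opts, "format", "tsv"),
                     region_map = region_map, aliases = aliases,
                     strict = strict,
                     policy = .cli_get(opts, "policy", "endpoint_half"),
                     growth_method = .cli_get(opts, "growth-method",
                                              "mean_yoy"),
                     top_k = as.integer(.cli_get(opts, "top-k", "10")),
                     quiet = TRUE)
      },
      ingest = {
        reg <- read_registry(.cli_get(opts, "input", required = TRUE),
                             format = .cli_get(opts, "format", "tsv"),
                             aliases = aliases, strict = strict,
                             quiet = TRUE)
        studies <- deduplicate_studies(reg)
        write_registry_tsv(studies, file.path(out, "studies.tsv"))
        writeLines(c(paste0("records_read: ", nrow(reg)),
                     paste0("unique_studies: ", nrow(studies))),
                   file.path(out, "ingest_log.txt"))
      },
      `build-network` = {
        net <- build_network(load_mult())
        write_edge_list(net, file.path(out, "edges.csv"))
        write_network_graphml(net, file.path(out, "network.graphml"),
                              region_map = region_map)
        write_network_gexf(net, file.path(out, "network.gexf"),
                           region_map = region_map)
      },
      metrics = {
        mult <- load_mult()
        net <- build_network(mult)
        write_connectivity_report(
          connectivity_report(net, region_map,
                              policy = .cli_get(opts, "policy",
                                                "endpoint_half"),
                              k = as.integer(.cli_get(opts, "top-k", "10")),
                              strict = strict), out)
        write_participation_report(
          participation_report(mult, region_map, strict = strict), out)
      },
      trends = {
        write_trend_series(studies_per_year(load_mult(), quiet = TRUE), out,
                           method = .cli_get(opts, "growth-method",
                                             "mean_yoy"))
      },
      conditions = {
        write_condition_table(
          condition_region_table(load_mult(), region_map,
                                 k = as.integer(.cli_get(opts, "top-k",
                                                         "5")),
                                 strict = strict),
          file.path(out, "conditions.csv"))
      },
      simulate = {
        cfg <- registry_config(
          n_studies = as.integer(.cli_get(opts, "n", "1000")))
        sim <- generate_registry(cfg,
                                 seed = as.integer(.cli_get(opts, "seed",
                                                            "1")))
        write_registry_tsv(sim$registry, file.path(out, "registry.tsv"))
        gt <- sim$ground_truth
        gt$config <- NULL
        jsonlite::write_json(gt, file.path(out, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("trialnet error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
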