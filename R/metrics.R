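# Connectivity and participation summaries over the integrated network.

#' Total number of connections in a network
#'
#' The sum of edge weights, i.e. the total number of (study, pair)
#' connection instances across all multinational studies.
#'
#' @param net A `trial_network`.
#' @return Non-negative integer.
#' @export
total_connections <- function(net) {
  stopifnot(inherits(net, "trial_network"))
  as.integer(sum(net$edges$weight))
}

#' Per-country weighted connection totals
#'
#' A country's total is its node size (sum of incident edge weights); its
#' share is the fraction of the total endpoint-incidence mass 2 x W, where W
#' is [total_connections()], so shares sum to 1. Rows are ranked by total
#' descending with ties broken by country name.
#'
#' @param net A `trial_network`.
#' @return Data frame with columns `country`, `total`, `share`.
#' @export
country_connection_totals <- function(net) {
  stopifnot(inherits(net, "trial_network"))
  w <- total_connections(net)
  out <- data.frame(country = net$nodes$country,
                    total = net$nodes$size,
                    share = if (w > 0) net$nodes$size / (2 * w) else numeric(
                      nrow(net$nodes)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-region connection totals
#'
#' Attributes each edge's weight to the regions of its two endpoints. Under
#' the default `endpoint_half` policy an edge contributes half its weight to
#' each endpoint's region, so region masses sum to W and shares (mass / W)
#' sum to 1. Under `endpoint_full` each endpoint's region receives the full
#' weight (masses are incidence counts summing to 2W; shares are computed
#' over 2W and again sum to 1, with `endpoint_half` mass exactly half of
#' `endpoint_full` mass for every region).
#'
#' @param net A `trial_network`.
#' @param region_map Named character vector country -> region.
#' @param policy `"endpoint_half"` (default) or `"endpoint_full"`.
#' @param strict If `TRUE`, a network country missing from the map is an
#'   error; otherwise it falls into the `"Unassigned"` region.
#' @return Data frame with columns `region`, `mass`, `share`, ranked by mass
#'   descending, ties by region name.
#' @export
region_connection_totals <- function(net, region_map = default_region_map(),
                                     policy = c("endpoint_half",
                                                "endpoint_full"),
                                     strict = FALSE) {
  stopifnot(inherits(net, "trial_network"))
  policy <- match.arg(policy)
  w <- total_connections(net)
  if (nrow(net$edges) == 0L) {
    return(data.frame(region = character(0), mass = numeric(0),
                      share = numeric(0), stringsAsFactors = FALSE))
  }
  reg <- assign_region(net$nodes$country, region_map, strict = strict)
  ru <- reg[match(net$edges$u, net$nodes$country)]
  rv <- reg[match(net$edges$v, net$nodes$country)]
  unit <- if (policy == "endpoint_half") 0.5 else 1
  mass <- tapply(rep(net$edges$weight * unit, 2L), c(ru, rv), sum)
  denom <- if (policy == "endpoint_half") w else 2 * w
  out <- data.frame(region = names(mass), mass = as.numeric(mass),
                    share = as.numeric(mass) / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mass, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Share of connections crossing region boundaries
#'
#' The fraction of total edge weight carried by edges whose endpoint
#' countries lie in different regions.
#'
#' @inheritParams region_connection_totals
#' @return A fraction in \[0, 1\].
#' @export
cross_region_share <- function(net, region_map = default_region_map(),
                               strict = FALSE) {
  stopifnot(inherits(net, "trial_network"))
  w <- total_connections(net)
  if (w == 0L) stop("cross-region share undefined for an empty network")
  reg <- assign_region(net$nodes$country, region_map, strict = strict)
  ru <- reg[match(net$edges$u, net$nodes$country)]
  rv <- reg[match(net$edges$v, net$nodes$country)]
  sum(net$edges$weight[ru != rv]) / w
}

#' Strongest connections
#'
#' @param net A `trial_network`.
#' @param k Number of edges to return (`k >= 1`); fewer if the network has
#'   fewer edges.
#' @return Data frame `u`, `v`, `weight` sorted by weight descending, ties
#'   by canonical pair order.
#' @export
top_edges <- function(net, k) {
  stopifnot(inherits(net, "trial_network"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  e <- net$edges
  e <- e[order(-e$weight, e$u, e$v), , drop = FALSE]
  e <- utils::head(e, as.integer(k))
  rownames(e) <- NULL
  e
}

#' Regional and per-country study participation
#'
#' For each region, the number and proportion of multinational studies with
#' at least one participating country in that region; for each country, the
#' number of multinational studies listing it. One study can touch several
#' regions, so region proportions may sum to more than 1.
#'
#' @param registry A [trial_registry()] of multinational studies.
#' @param region_map Named character vector country -> region.
#' @param strict Passed to [assign_region()].
#' @return List of class `participation_report`: `region` (data frame
#'   `region`, `n_studies`, `proportion`), `country` (data frame `country`,
#'   `n_studies`), and `n_multinational`.
#' @export
participation_report <- function(registry, region_map = default_region_map(),
                                 strict = FALSE) {
  stopifnot(inherits(registry, "trial_registry"))
  if (any(lengths(registry$countries) < 2L)) {
    stop("participation report requires studies filtered to multinational")
  }
  n <- nrow(registry)
  study_regions <- lapply(registry$countries, function(cs) {
    unique(assign_region(cs, region_map, strict = strict))
  })
  rcount <- table(unlist(study_regions, use.names = FALSE))
  region <- data.frame(region = names(rcount),
                       n_studies = as.integer(rcount),
                       proportion = if (n > 0) as.integer(rcount) / n else
                         numeric(length(rcount)),
                       stringsAsFactors = FALSE)
  region <- region[order(-region$n_studies, region$region), , drop = FALSE]
  rownames(region) <- NULL
  ccount <- table(unlist(registry$countries, use.names = FALSE))
  country <- data.frame(country = names(ccount),
                        n_studies = as.integer(ccount),
                        stringsAsFactors = FALSE)
  country <- country[order(-country$n_studies, country$country), ,
                     drop = FALSE]
  rownames(country) <- NULL
  structure(list(region = region, country = country, n_multinational = n),
            class = "participation_report")
}

#' @export
print.participation_report <- function(x, ...) {
  cat("<participation_report> ", x$n_multinational,
      " multinational studies\n", sep = "")
  print(x$region)
  invisible(x)
}

#' Full connectivity report
#'
#' Bundles [total_connections()], [country_connection_totals()],
#' [region_connection_totals()], [cross_region_share()] and [top_edges()]
#' into one object.
#'
#' @inheritParams region_connection_totals
#' @param k Number of strongest edges to report.
#' @return List of class `connectivity_report`.
#' @export
connectivity_report <- function(net, region_map = default_region_map(),
                                policy = c("endpoint_half", "endpoint_full"),
                                k = 10L, strict = FALSE) {
  policy <- match.arg(policy)
  w <- total_connections(net)
  structure(list(
    total_weight = w,
    country_totals = country_connection_totals(net),
    region_totals = region_connection_totals(net, region_map, policy,
                                             strict = strict),
    cross_region_share = if (w > 0) {
      cross_region_share(net, region_map, strict = strict)
    } else NA_real_,
    top_edges = top_edges(net, k),
    policy = policy
  ), class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("<connectivity_report> total connections: ", x$total_weight,
      "; cross-region share: ",
      ifelse(is.na(x$cross_region_share), "NA",
             sprintf("%.3f", x$cross_region_share)),
      " (policy ", x$policy, ")\n", sep = "")
  cat("Top countries:\n")
  print(utils::head(x$country_totals, 5L))
  invisible(x)
}

#' Write a connectivity report to disk
#'
#' Writes `country_totals.csv`, `region_totals.csv`, `top_edges.csv` and a
#' `connectivity.json` summary into `dir`.
#'
#' @param report A `connectivity_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_connectivity_report <- function(report, dir) {
  stopifnot(inherits(report, "connectivity_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$country_totals,
                   file.path(dir, "country_totals.csv"), row.names = FALSE)
  utils::write.csv(report$region_totals,
                   file.path(dir, "region_totals.csv"), row.names = FALSE)
  te <- report$top_edges
  names(te) <- c("source", "target", "weight")
  utils::write.csv(te, file.path(dir, "top_edges.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(total_weight = report$total_weight,
         cross_region_share = report$cross_region_share,
         policy = report$policy,
         region_totals = report$region_totals,
         top_edges = te),
    file.path(dir, "connectivity.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write a participation report to disk
#'
#' @param report A `participation_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_participation_report <- function(report, dir) {
  stopifnot(inherits(report, "participation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$region,
                   file.path(dir, "participation_region.csv"),
                   row.names = FALSE)
  utils::write.csv(report$country,
                   file.path(dir, "participation_country.csv"),
                   row.names = FALSE)
  invisible(dir)
}
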