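# Shared fixtures and independent oracles.

# The two-study worked example: Study A in countries {1,2,3}, Study B in
# {2,3,4}.
worked_example <- function() {
  trial_registry(c("A", "B"), c(2000L, 2001L),
                 countries = list(c("1", "2", "3"), c("2", "3", "4")),
                 conditions = list("diabetes", "diabetes"))
}

# Random small registry over a generic numbered-country universe; includes
# single-nation and undated studies unless disabled.
random_registry <- function(n_studies, n_countries = 10L,
                            p_single = 0.3, years = 2000:2010) {
  countries <- sprintf("C%02d", seq_len(n_countries))
  cs <- lapply(seq_len(n_studies), function(i) {
    if (stats::runif(1) < p_single) {
      sample(countries, 1L)
    } else {
      sample(countries, sample(2:min(6L, n_countries), 1L))
    }
  })
  yr <- sample(years, n_studies, replace = TRUE)
  yr[stats::runif(n_studies) < 0.1] <- NA_integer_
  trial_registry(sprintf("S%04d", seq_len(n_studies)), yr, cs,
                 conditions = rep(list("x"), n_studies))
}

# Brute-force network oracle: for every unordered country pair, loop over
# studies and count those containing both members. Independent of the
# master-list / table() route used by build_network().
brute_force_network <- function(registry) {
  keep <- lengths(registry$countries) >= 2L
  cs <- registry$countries[keep]
  universe <- sort(unique(unlist(cs)))
  edges <- data.frame(u = character(0), v = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  if (length(universe) >= 2L) {
    for (i in seq_len(length(universe) - 1L)) {
      for (j in (i + 1L):length(universe)) {
        a <- universe[i]; b <- universe[j]
        w <- 0L
        for (s in cs) if (a %in% s && b %in% s) w <- w + 1L
        if (w > 0L) {
          edges <- rbind(edges, data.frame(u = a, v = b, weight = w,
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  sizes <- stats::setNames(rep(0L, length(universe)), universe)
  for (r in seq_len(nrow(edges))) {
    sizes[edges$u[r]] <- sizes[edges$u[r]] + edges$weight[r]
    sizes[edges$v[r]] <- sizes[edges$v[r]] + edges$weight[r]
  }
  sizes <- sizes[sizes > 0L]
  list(edges = edges,
       nodes = data.frame(country = as.character(names(sizes)),
                          size = as.integer(unname(sizes)),
                          stringsAsFactors = FALSE))
}

# A small region map over the generic universe: C01..C05 -> X, rest -> Y.
toy_region_map <- function(n_countries = 10L, split = 5L) {
  countries <- sprintf("C%02d", seq_len(n_countries))
  stats::setNames(ifelse(seq_len(n_countries) <= split,
                         "Europe", "Asia"), countries)
}

# Tiny synthetic config for fast exact computations (6-country universe, so
# the mean multinational size must sit below 6).
tiny_config <- function(n_studies = 500L, mean_countries = 3.5, ...) {
  registry_config(
    n_studies, mean_countries = mean_countries,
    countries = stats::setNames(
      c("North America", "Europe", "Europe", "Asia", "Africa", "Oceania"),
      c("U1", "U2", "U3", "U4", "U5", "U6")),
    popularity = stats::setNames(c(8, 4, 2, 1, 1, 0.5),
                                 c("U1", "U2", "U3", "U4", "U5", "U6")),
    ...)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
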