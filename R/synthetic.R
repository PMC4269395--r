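# Seeded synthetic registries with the statistical structure the pipeline
# assumes: an ~89/11 single-nation/multinational split, multinational
# studies averaging 6-7 countries, a heavy-tailed country popularity with
# one dominant hub, six-region country assignments, a growth-then-plateau
# year profile, and a condition distribution dominated by a diabetes-like
# label. Ground truth is recorded so pipeline recovery can be checked
# exactly, and expected per-pair edge weights are available analytically.

.default_universe <- function() {
  c("United States" = "North America", "Canada" = "North America",
    "Mexico" = "North America",
    "Brazil" = "South America", "Argentina" = "South America",
    "Chile" = "South America", "Colombia" = "South America",
    "Peru" = "South America",
    "Germany" = "Europe", "France" = "Europe", "United Kingdom" = "Europe",
    "Italy" = "Europe", "Spain" = "Europe", "Poland" = "Europe",
    "Netherlands" = "Europe", "Czech Republic" = "Europe",
    "Japan" = "Asia", "China" = "Asia", "India" = "Asia",
    "South Korea" = "Asia", "Taiwan" = "Asia", "Israel" = "Asia",
    "Thailand" = "Asia",
    "South Africa" = "Africa", "Egypt" = "Africa", "Kenya" = "Africa",
    "Nigeria" = "Africa",
    "Australia" = "Oceania", "New Zealand" = "Oceania",
    "Solomon Islands" = "Oceania")
}

.default_popularity <- function(countries, hub = countries[1]) {
  others <- setdiff(countries, hub)
  w <- stats::setNames(seq_along(others)^(-0.8), others)
  w <- c(stats::setNames(10 * stats::median(w), hub), w)
  w[countries]
}

.default_year_profile <- function(peak = 2009L, from = 1982L, to = 2012L,
                                  rise = 0.25, decline = 0.08) {
  years <- seq(from, to)
  w <- ifelse(years <= peak, exp(rise * (years - peak)),
              exp(-decline * (years - peak)))
  stats::setNames(w / sum(w), years)
}

.default_conditions <- function() {
  c(diabetes = 0.28, "breast cancer" = 0.12, "rheumatoid arthritis" = 0.10,
    hiv = 0.08, asthma = 0.07, "lung cancer" = 0.06, schizophrenia = 0.05,
    alcoholism = 0.05, malaria = 0.04, leukemia = 0.04, hypertension = 0.04,
    depression = 0.04, copd = 0.03)
}

#' Configuration for the synthetic registry generator
#'
#' Defaults encode the stated world the generator emulates: an 11%
#' multinational share, multinational studies with a truncated-geometric
#' country count targeting a mean of 6.5, a 30-country universe across the
#' six regions with the hub country at 10x the median popularity, a year
#' profile rising exponentially to a 2009 peak then mildly declining, and a
#' condition distribution led by diabetes.
#'
#' @param n_studies Number of studies to generate.
#' @param p_multinational Probability a study is multinational (default
#'   0.11).
#' @param mean_countries Target mean country count of multinational studies
#'   (default 6.5); ignored when `size_probs` is given.
#' @param size_probs Optional named numeric vector: country count k (>= 2)
#'   -> probability; overrides the truncated-geometric default.
#' @param countries Named character vector country -> region defining the
#'   universe.
#' @param popularity Named numeric sampling weights over `countries`.
#' @param year_profile Named numeric vector year -> relative intensity.
#' @param condition_probs Named numeric vector condition -> probability.
#' @param p_unlocated Probability a record carries no country list (dirty
#'   registry rows; default 0.01).
#' @param p_missing_year Probability a record carries no parseable start
#'   date (default 0.02).
#' @return List of class `registry_config` with normalized distributions.
#' @export
registry_config <- function(n_studies,
                            p_multinational = 0.11,
                            mean_countries = 6.5,
                            size_probs = NULL,
                            countries = .default_universe(),
                            popularity = .default_popularity(
                              names(countries)),
                            year_profile = .default_year_profile(),
                            condition_probs = .default_conditions(),
                            p_unlocated = 0.01,
                            p_missing_year = 0.02) {
  stopifnot(n_studies >= 0, p_multinational >= 0, p_multinational <= 1,
            p_unlocated >= 0, p_unlocated <= 1,
            p_missing_year >= 0, p_missing_year <= 1)
  m <- length(countries)
  if (m < 2L) stop("country universe must have at least 2 countries")
  if (is.null(names(countries)) || anyDuplicated(names(countries))) {
    stop("countries must be a uniquely named country -> region vector")
  }
  if (!setequal(names(popularity), names(countries))) {
    stop("popularity weights must cover exactly the country universe")
  }
  popularity <- popularity[names(countries)]
  if (any(popularity <= 0)) stop("popularity weights must be positive")
  if (is.null(size_probs)) {
    if (mean_countries <= 2) stop("mean_countries must exceed 2")
    if (mean_countries >= m) stop("mean_countries must be below the ",
                                  "universe size")
    # k = 2 + Geom(p) truncated at m; solve p so the truncated mean hits
    # the target (truncation alone would drag it below).
    ks <- 2:m
    trunc_mean <- function(p) {
      q <- stats::dgeom(ks - 2L, p)
      sum(ks * q / sum(q))
    }
    p <- stats::uniroot(function(p) trunc_mean(p) - mean_countries,
                        c(1e-6, 1 - 1e-6), tol = 1e-12)$root
    size_probs <- stats::setNames(stats::dgeom(ks - 2L, p), ks)
  } else {
    ks <- as.integer(names(size_probs))
    if (anyNA(ks) || any(ks < 2L)) stop("size_probs names must be k >= 2")
    if (max(ks) > m) {
      stop("country universe smaller than the largest study size")
    }
    if (any(size_probs < 0)) stop("size_probs must be non-negative")
  }
  size_probs <- size_probs / sum(size_probs)
  if (any(year_profile < 0) || sum(year_profile) <= 0) {
    stop("year_profile must be non-negative with positive mass")
  }
  year_profile <- year_profile / sum(year_profile)
  if (any(condition_probs < 0) || sum(condition_probs) <= 0) {
    stop("condition_probs must be non-negative with positive mass")
  }
  condition_probs <- condition_probs / sum(condition_probs)
  structure(list(n_studies = as.integer(n_studies),
                 p_multinational = p_multinational,
                 size_probs = size_probs,
                 countries = countries,
                 popularity = popularity,
                 year_profile = year_profile,
                 condition_probs = condition_probs,
                 p_unlocated = p_unlocated,
                 p_missing_year = p_missing_year),
            class = "registry_config")
}

#' Generate a seeded synthetic registry with ground truth
#'
#' Per study: the scope is multinational with probability
#' `p_multinational`; the country count k is drawn from the configured size
#' distribution; countries are sampled without replacement with probability
#' proportional to popularity (successive renormalization, i.e. base R
#' `sample()` semantics); the start year is drawn from the year profile and
#' the condition(s) from the condition distribution (a second condition
#' with probability 0.15). A small configurable fraction of records has no
#' country list or no start year, emulating dirty registry rows.
#'
#' @param config A [registry_config()].
#' @param seed Integer seed; identical seeds give identical registries.
#' @return List with elements `registry` (a [trial_registry()]) and
#'   `ground_truth`: realized scope labels, per-study country counts, the
#'   realized per-pair co-occurrence counts (accumulated independently of
#'   the network builder), realized multinational per-year counts, and the
#'   generating parameters.
#' @export
generate_registry <- function(config, seed) {
  stopifnot(inherits(config, "registry_config"))
  set.seed(as.integer(seed))
  n <- config$n_studies
  cn <- names(config$countries)
  years_avail <- as.integer(names(config$year_profile))
  scope <- character(n)
  kvec <- integer(n)
  years <- integer(n)
  countries <- vector("list", n)
  conditions <- vector("list", n)
  pair_env <- new.env(parent = emptyenv())
  if (n > 0) {
    is_mult <- stats::runif(n) < config$p_multinational
    is_unloc <- !is_mult & (stats::runif(n) < config$p_unlocated /
                              max(1 - config$p_multinational, 1e-12))
    years <- sample(years_avail, n, replace = TRUE,
                    prob = config$year_profile)
    years[stats::runif(n) < config$p_missing_year] <- NA_integer_
    ks <- as.integer(names(config$size_probs))
    for (i in seq_len(n)) {
      if (is_mult[i]) {
        k <- sample(ks, 1L, prob = config$size_probs)
        cs <- sample(cn, k, replace = FALSE, prob = config$popularity)
        countries[[i]] <- cs
        scope[i] <- "multinational"
        kvec[i] <- k
        # ground-truth pair bookkeeping, independent of build_master_list
        cs <- sort(cs)
        for (a in seq_len(k - 1L)) {
          for (b in (a + 1L):k) {
            key <- paste(cs[a], cs[b], sep = "\x1f")
            prev <- pair_env[[key]]
            pair_env[[key]] <- if (is.null(prev)) 1L else prev + 1L
          }
        }
      } else if (is_unloc[i]) {
        countries[[i]] <- character(0)
        scope[i] <- "unlocated"
        kvec[i] <- 0L
      } else {
        countries[[i]] <- sample(cn, 1L, prob = config$popularity)
        scope[i] <- "single_nation"
        kvec[i] <- 1L
      }
      nc <- 1L + (stats::runif(1) < 0.15)
      conditions[[i]] <- unique(sample(names(config$condition_probs), nc,
                                       replace = TRUE,
                                       prob = config$condition_probs))
    }
  }
  ids <- sprintf("SYN%06d", seq_len(n))
  registry <- trial_registry(ids, years, countries, conditions)
  keys <- ls(pair_env)
  pc <- if (length(keys) > 0) {
    parts <- strsplit(keys, "\x1f", fixed = TRUE)
    df <- data.frame(u = vapply(parts, `[`, "", 1L),
                     v = vapply(parts, `[`, "", 2L),
                     weight = vapply(keys, function(k) pair_env[[k]],
                                     integer(1), USE.NAMES = FALSE),
                     stringsAsFactors = FALSE)
    df <- df[order(df$u, df$v), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(u = character(0), v = character(0), weight = integer(0),
               stringsAsFactors = FALSE)
  }
  mult_dated <- scope == "multinational" & !is.na(years)
  year_counts <- if (any(mult_dated)) {
    table(years[mult_dated])
  } else {
    table(integer(0))
  }
  ground_truth <- list(
    seed = as.integer(seed),
    scope = scope,
    k = kvec,
    start_year = years,
    pair_counts = pc,
    n_multinational = sum(scope == "multinational"),
    multinational_per_year = stats::setNames(as.integer(year_counts),
                                             names(year_counts)),
    config = config)
  list(registry = registry, ground_truth = ground_truth)
}

# P(countries i and j are both among the k sampled) under popularity-
# weighted sampling without replacement. Uses the exponential-race
# representation: the sampled k-set equals the k smallest of independent
# E_i ~ Exp(w_i), so both are drawn iff at most k-2 of the other countries
# race below max(E_i, E_j). The count of others below a level x is
# Poisson-binomial (dynamic program); the level is integrated out against
# the density of max(E_i, E_j).
.pair_inclusion_prob <- function(w, i, j, k) {
  m <- length(w)
  if (k >= m) return(1)
  if (k < 2L) return(0)
  w <- w / sum(w)
  wa <- w[i]; wb <- w[j]; wo <- w[-c(i, j)]
  kk <- k - 2L
  f <- function(x) {
    dp <- matrix(0, length(x), kk + 1L)
    dp[, 1L] <- 1
    for (wv in wo) {
      p <- 1 - exp(-wv * x)
      ndp <- dp * (1 - p)
      if (kk >= 1L) {
        ndp[, 2:(kk + 1L)] <- ndp[, 2:(kk + 1L)] + dp[, 1:kk] * p
      }
      dp <- ndp
    }
    cdf <- rowSums(dp)
    fmax <- wa * exp(-wa * x) * (1 - exp(-wb * x)) +
      wb * exp(-wb * x) * (1 - exp(-wa * x))
    fmax * cdf
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                   subdivisions = 200L)$value
}

#' Expected edge weight between two countries
#'
#' The expected number of generated studies in which both countries
#' participate, i.e. the expected weight of their network edge:
#' n_studies x p_multinational x sum over k of P(K = k) P(both sampled | k).
#' The pairwise inclusion probability under popularity-weighted sampling
#' without replacement is computed exactly via the exponential-race
#' representation (Poisson-binomial dynamic program plus one-dimensional
#' quadrature); `method = "monte_carlo"` estimates it by simulation instead
#' and attaches its standard error as attribute `"se"`.
#'
#' @param config A [registry_config()].
#' @param a,b Two distinct countries of the configured universe.
#' @param method `"exact"` (default) or `"monte_carlo"`.
#' @param nsim Simulations per study-size value for the Monte-Carlo method.
#' @return Expected weight (numeric). Attribute `"method"` records the
#'   computation route.
#' @export
expected_edge_weight <- function(config, a, b,
                                 method = c("exact", "monte_carlo"),
                                 nsim = 10000L) {
  stopifnot(inherits(config, "registry_config"))
  method <- match.arg(method)
  cn <- names(config$countries)
  i <- match(a, cn); j <- match(b, cn)
  if (is.na(i) || is.na(j)) stop("countries must belong to the universe")
  if (i == j) stop("expected edge weight requires two distinct countries")
  w <- config$popularity
  ks <- as.integer(names(config$size_probs))
  pk <- config$size_probs
  keep <- pk > 1e-12
  ks <- ks[keep]; pk <- pk[keep]
  if (method == "exact") {
    p_both <- vapply(ks, function(k) .pair_inclusion_prob(w, i, j, k),
                     numeric(1))
    p_pair <- sum(pk * p_both)
    se <- NULL
  } else {
    hits <- 0L
    draws <- sample(ks, nsim, replace = TRUE, prob = pk)
    for (k in draws) {
      s <- sample(cn, k, replace = FALSE, prob = w)
      hits <- hits + (a %in% s && b %in% s)
    }
    p_pair <- hits / nsim
    se <- config$n_studies * config$p_multinational *
      sqrt(p_pair * (1 - p_pair) / nsim)
  }
  out <- config$n_studies * config$p_multinational * p_pair
  attr(out, "method") <- method
  if (!is.null(se)) attr(out, "se") <- se
  out
}

#' Write a registry in the TSV dialect read by [read_registry()]
#'
#' @param registry A [trial_registry()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_registry_tsv <- function(registry, path) {
  stopifnot(inherits(registry, "trial_registry"))
  df <- data.frame(
    study_id = registry$study_id,
    start_date = ifelse(is.na(registry$start_year), "",
                        as.character(registry$start_year)),
    countries = vapply(registry$countries, paste, "", collapse = "|"),
    conditions = vapply(registry$conditions, paste, "", collapse = "|"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
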