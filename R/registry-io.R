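# Registry ingestion: readers, normalization, deduplication, scope
# classification, and the country -> region assignment.

.trialnet_env <- new.env(parent = emptyenv())

#' The six geographic regions
#'
#' Every country in a region map must resolve to exactly one of these labels.
#'
#' @return Character vector of the six region names.
#' @export
trialnet_regions <- function() {
  c("North America", "South America", "Africa", "Europe", "Asia", "Oceania")
}

#' Construct a trial registry
#'
#' A trial registry is a data frame with one row per study record and columns
#' `study_id` (character), `start_year` (integer, `NA` when the start date was
#' missing or unparseable), `countries` (list of character vectors, duplicates
#' removed) and `conditions` (list of character vectors, case-folded).
#'
#' @param study_id Character vector of study identifiers.
#' @param start_year Integer vector of start years (`NA` allowed).
#' @param countries List of character vectors of participating countries.
#' @param conditions List of character vectors of studied conditions.
#' @param year_window Length-2 integer vector giving the plausible year range;
#'   years outside it are set to `NA` with a warning.
#' @return An object of class `trial_registry` (a data frame).
#' @examples
#' trial_registry("NCT001", 2009L, list(c("United States", "Canada")),
#'                list("diabetes"))
#' @export
trial_registry <- function(study_id, start_year = NA_integer_,
                           countries = list(), conditions = list(),
                           year_window = c(1900L, 2100L)) {
  study_id <- as.character(study_id)
  n <- length(study_id)
  start_year <- suppressWarnings(as.integer(start_year))
  start_year <- rep_len(start_year, n)
  if (length(countries) == 0L) countries <- rep(list(character(0)), n)
  if (length(conditions) == 0L) conditions <- rep(list(character(0)), n)
  stopifnot(length(countries) == n, length(conditions) == n)
  bad <- !is.na(start_year) &
    (start_year < year_window[1] | start_year > year_window[2])
  if (any(bad)) {
    warning(sum(bad), " start year(s) outside [", year_window[1], ", ",
            year_window[2], "] set to NA")
    start_year[bad] <- NA_integer_
  }
  countries <- lapply(countries, function(x) unique(as.character(x)))
  conditions <- lapply(conditions, function(x) unique(as.character(x)))
  out <- data.frame(study_id = study_id, start_year = start_year,
                    stringsAsFactors = FALSE)
  out$countries <- countries
  out$conditions <- conditions
  class(out) <- c("trial_registry", "data.frame")
  out
}

#' @export
print.trial_registry <- function(x, ...) {
  cat("<trial_registry> ", nrow(x), " record(s), ",
      length(unique(x$study_id)), " unique study id(s)\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(x, 5L)
    for (i in seq_len(nrow(show))) {
      cat("  ", show$study_id[i], " [",
          ifelse(is.na(show$start_year[i]), "----", show$start_year[i]),
          "] {", paste(show$countries[[i]], collapse = ", "), "}\n", sep = "")
    }
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

.read_kv_tsv <- function(path, key_col, val_col) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!all(c(key_col, val_col) %in% names(tab))) {
    stop("expected columns '", key_col, "' and '", val_col, "' in ", path)
  }
  stats::setNames(trimws(tab[[val_col]]), trimws(tab[[key_col]]))
}

#' Read a country-to-region map
#'
#' The file is a two-column TSV with header `country`, `region`. Regions must
#' belong to the six labels of [trialnet_regions()].
#'
#' @param path Path to the TSV file.
#' @return Named character vector: canonical country name -> region.
#' @export
read_region_map <- function(path) {
  map <- .read_kv_tsv(path, "country", "region")
  bad <- setdiff(unique(map), trialnet_regions())
  if (length(bad) > 0) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(map))) {
    stop("duplicate countries in region map: ",
         paste(names(map)[duplicated(names(map))], collapse = ", "))
  }
  map
}

#' Read a country alias table
#'
#' Two-column TSV with header `alias`, `canonical`, mapping registry country
#' spellings to canonical names (e.g. "Korea, Republic of" -> "South Korea").
#'
#' @param path Path to the TSV file.
#' @return Named character vector: alias -> canonical name.
#' @export
read_alias_table <- function(path) .read_kv_tsv(path, "alias", "canonical")

#' Shipped default region map
#'
#' Covers the country vocabulary of the major trial registries; assignments
#' for transcontinental countries (Russia -> Europe, Turkey and Georgia ->
#' Asia, Egypt -> Africa, Mexico and Central America and the Caribbean ->
#' North America) are deliberate defaults and fully overridable by supplying
#' a custom map via [read_region_map()].
#'
#' @return Named character vector: country -> region.
#' @export
default_region_map <- function() {
  if (is.null(.trialnet_env$region_map)) {
    .trialnet_env$region_map <- read_region_map(
      system.file("extdata", "region_map.tsv", package = "trialnet",
                  mustWork = TRUE))
  }
  .trialnet_env$region_map
}

#' Shipped default country alias table
#'
#' @return Named character vector: alias -> canonical name.
#' @export
default_alias_table <- function() {
  if (is.null(.trialnet_env$aliases)) {
    .trialnet_env$aliases <- read_alias_table(
      system.file("extdata", "country_aliases.tsv", package = "trialnet",
                  mustWork = TRUE))
  }
  .trialnet_env$aliases
}

#' Normalize country names to canonical form
#'
#' Trims whitespace, resolves known aliases (case-insensitively), and matches
#' canonical names case-insensitively against the region-map universe.
#' Unknown names pass through unchanged and are counted under themselves; a
#' single warning lists them unless `quiet = TRUE`.
#'
#' @param raw Character vector of country names. Empty strings are an error.
#' @param aliases Named character vector alias -> canonical.
#' @param universe Character vector of known canonical names (used to fix
#'   capitalization and to detect unknowns).
#' @param quiet Suppress the unknown-name warning.
#' @return Character vector of canonical names, same length as `raw`.
#' @export
normalize_country <- function(raw, aliases = default_alias_table(),
                              universe = names(default_region_map()),
                              quiet = FALSE) {
  if (length(raw) == 0L) return(character(0))
  raw <- gsub("\\s+", " ", trimws(as.character(raw)))
  if (any(is.na(raw) | raw == "")) {
    stop("empty country name cannot be normalized")
  }
  out <- raw
  key <- tolower(raw)
  amap <- stats::setNames(unname(aliases), tolower(names(aliases)))
  hit <- key %in% names(amap)
  out[hit] <- amap[key[hit]]
  umap <- stats::setNames(universe, tolower(universe))
  key2 <- tolower(out)
  hit2 <- !hit & key2 %in% names(umap)
  out[hit2] <- umap[key2[hit2]]
  unknown <- unique(out[!(tolower(out) %in% names(umap))])
  if (length(unknown) > 0 && !quiet) {
    warning("unknown country name(s) passed through unchanged: ",
            paste(sort(unknown), collapse = ", "))
  }
  out
}

#' Assign countries to geographic regions
#'
#' @param country Character vector of canonical country names.
#' @param region_map Named character vector country -> region.
#' @param strict If `TRUE`, an unmapped country is an error; otherwise it is
#'   assigned to the `"Unassigned"` bucket with a warning.
#' @return Character vector of regions.
#' @export
assign_region <- function(country, region_map = default_region_map(),
                          strict = FALSE) {
  out <- unname(region_map[as.character(country)])
  miss <- is.na(out)
  if (any(miss)) {
    bad <- sort(unique(country[miss]))
    if (strict) {
      stop("countries not in region map: ", paste(bad, collapse = ", "))
    }
    warning("countries not in region map assigned to 'Unassigned': ",
            paste(bad, collapse = ", "))
    out[miss] <- "Unassigned"
  }
  out
}

# Accepts "YYYY", "YYYY-MM", "YYYY-MM-DD", "Month YYYY" and "Month D, YYYY".
.parse_start_year <- function(x) {
  x <- trimws(as.character(x))
  year <- rep(NA_integer_, length(x))
  iso <- regmatches(x, regexec("^(\\d{4})(-\\d{1,2}(-\\d{1,2})?)?$", x))
  txt <- regmatches(x, regexec(
    "^[A-Za-z]+\\.?\\s+(?:(\\d{1,2}),?\\s+)?(\\d{4})$", x))
  for (i in seq_along(x)) {
    if (length(iso[[i]]) > 0) {
      year[i] <- as.integer(iso[[i]][2])
    } else if (length(txt[[i]]) > 0) {
      year[i] <- as.integer(txt[[i]][3])
    }
  }
  year
}

.split_pipe <- function(x) {
  parts <- strsplit(as.character(x), "|", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    p[!is.na(p) & p != ""]
  })
}

#' Read a clinical trial registry file
#'
#' Two dialects are supported. `"tsv"`: one study per row, UTF-8, header
#' required, columns `study_id`, `start_date`, `countries` (pipe-separated)
#' and `conditions` (pipe-separated). `"ctgov_xml"`: the ClinicalTrials.gov
#' public XML schema; only the study identifier (`id_info/nct_id`),
#' `start_date`, `location_countries/country` and `condition` elements are
#' read, everything else is ignored. A file may hold a single study element
#' or any root wrapping several of them.
#'
#' Country names are normalized through the alias table; conditions are
#' case-folded and trimmed. Records with no parseable country list are kept
#' with an empty country set (they are classified "unlocated" downstream).
#' Unparseable start dates yield a missing year.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"ctgov_xml"`.
#' @param aliases Named alias -> canonical table for country normalization.
#' @param strict If `TRUE`, a malformed record (missing study id) is fatal;
#'   in the default lenient mode it is skipped with a warning.
#' @param quiet Suppress unknown-country warnings.
#' @param year_window Plausibility window for start years.
#' @return A [trial_registry()] with one row per input record.
#' @export
read_registry <- function(path, format = c("tsv", "ctgov_xml"),
                          aliases = default_alias_table(), strict = FALSE,
                          quiet = FALSE, year_window = c(1900L, 2100L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("registry file not found: ", path)
  if (format == "tsv") {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE,
                             quote = "", na.strings = NULL)
    need <- c("study_id", "start_date", "countries", "conditions")
    if (!all(need %in% names(raw))) {
      stop("TSV registry must have columns: ", paste(need, collapse = ", "))
    }
    ids <- trimws(raw$study_id)
    dates <- raw$start_date
    countries <- .split_pipe(raw$countries)
    conditions <- .split_pipe(raw$conditions)
  } else {
    doc <- xml2::read_xml(path)
    nodes <- if (xml2::xml_name(doc) == "clinical_study") {
      list(doc)
    } else {
      xml2::xml_find_all(doc, ".//clinical_study")
    }
    if (length(nodes) == 0L) stop("no <clinical_study> elements in ", path)
    ids <- vapply(nodes, function(n) {
      xml2::xml_text(xml2::xml_find_first(n, "./id_info/nct_id"))
    }, character(1))
    ids <- trimws(ifelse(is.na(ids), "", ids))
    dates <- vapply(nodes, function(n) {
      xml2::xml_text(xml2::xml_find_first(n, "./start_date"))
    }, character(1))
    countries <- lapply(nodes, function(n) {
      trimws(xml2::xml_text(
        xml2::xml_find_all(n, "./location_countries/country")))
    })
    conditions <- lapply(nodes, function(n) {
      trimws(xml2::xml_text(xml2::xml_find_all(n, "./condition")))
    })
  }
  bad <- is.na(ids) | ids == ""
  if (any(bad)) {
    msg <- paste0(sum(bad), " record(s) without a study id")
    if (strict) stop(msg)
    warning(msg, "; skipped")
    keep <- !bad
    ids <- ids[keep]; dates <- dates[keep]
    countries <- countries[keep]; conditions <- conditions[keep]
  }
  years <- .parse_start_year(dates)
  n_undated <- sum(is.na(years) & trimws(dates) != "")
  if (n_undated > 0 && !quiet) {
    message(n_undated, " record(s) with unparseable start date; year missing")
  }
  all_countries <- unlist(countries, use.names = FALSE)
  if (length(all_countries) > 0) {
    norm <- normalize_country(all_countries, aliases = aliases, quiet = quiet)
    countries <- utils::relist(norm, countries)
  }
  countries <- lapply(countries, unique)
  conditions <- lapply(conditions, function(x) unique(tolower(trimws(x))))
  n_noloc <- sum(lengths(countries) == 0L)
  if (n_noloc > 0 && !quiet) {
    message(n_noloc, " record(s) with no country list; kept as unlocated")
  }
  trial_registry(ids, years, countries, conditions, year_window = year_window)
}

#' Collapse registry records to unique studies
#'
#' Multiple registry records may describe the same study (registry updates
#' append locations). Records sharing a `study_id` are merged by unioning
#' their country sets and condition lists and keeping the earliest
#' non-missing start year; conflicting years trigger a warning. Output is
#' sorted by `study_id` and the operation is idempotent.
#'
#' @param registry A [trial_registry()].
#' @return A [trial_registry()] with one row per study id.
#' @export
deduplicate_studies <- function(registry) {
  stopifnot(inherits(registry, "trial_registry"))
  if (nrow(registry) == 0L) return(registry)
  idx <- split(seq_len(nrow(registry)), registry$study_id)
  ids <- names(idx)
  years <- integer(length(idx))
  n_conflict <- 0L
  countries <- vector("list", length(idx))
  conditions <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    i <- idx[[g]]
    ys <- registry$start_year[i]
    ys <- ys[!is.na(ys)]
    if (length(unique(ys)) > 1L) n_conflict <- n_conflict + 1L
    years[g] <- if (length(ys) > 0) min(ys) else NA_integer_
    countries[[g]] <- sort(unique(unlist(registry$countries[i],
                                         use.names = FALSE)))
    conditions[[g]] <- sort(unique(unlist(registry$conditions[i],
                                          use.names = FALSE)))
  }
  if (n_conflict > 0L) {
    warning(n_conflict, " study id(s) with conflicting start years; ",
            "earliest kept")
  }
  trial_registry(ids, years, countries, conditions)
}

#' Classify study scope
#'
#' A study is `multinational` when it lists more than one distinct country,
#' `single_nation` when it lists exactly one, and `unlocated` when it lists
#' none (unlocated studies are excluded from all downstream analyses).
#'
#' @param registry A [trial_registry()].
#' @return Character vector with values `"single_nation"`, `"multinational"`
#'   or `"unlocated"`, one per record.
#' @export
classify_scope <- function(registry) {
  stopifnot(inherits(registry, "trial_registry"))
  k <- lengths(registry$countries)
  ifelse(k == 0L, "unlocated",
         ifelse(k == 1L, "single_nation", "multinational"))
}

#' Keep only multinational studies
#'
#' @param registry A [trial_registry()].
#' @return The subset of records with more than one distinct country.
#' @export
filter_multinational <- function(registry) {
  out <- registry[classify_scope(registry) == "multinational", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_registry", "data.frame")
  out
}
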