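# Condition-by-region stratification: the top-k studied conditions within
# each geographic region's multinational trials.

#' Top conditions per region
#'
#' A study counts toward region R when at least one of its countries maps to
#' R (so one study can count in several regions), and toward each condition
#' it lists. Within each region, conditions are ranked by study count
#' (descending, ties by condition name) and reported with their proportion
#' of the region's multinational-trial count. All conditions tied with the
#' k-th ranked count are reported jointly, so a region's table may exceed k
#' rows.
#'
#' @param registry A [trial_registry()] of multinational studies with
#'   normalized condition labels (case-folded and trimmed at ingestion; pass
#'   `synonyms` to collapse spelling variants further).
#' @param region_map Named character vector country -> region.
#' @param k Number of ranks per region (default 5).
#' @param synonyms Optional named character vector condition -> canonical
#'   label applied before counting.
#' @param strict Passed to [assign_region()].
#' @return Data frame of class `condition_region_table` with columns
#'   `region`, `rank`, `condition`, `count`, `proportion`.
#' @export
condition_region_table <- function(registry,
                                   region_map = default_region_map(),
                                   k = 5L, synonyms = NULL, strict = FALSE) {
  stopifnot(inherits(registry, "trial_registry"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  if (any(lengths(registry$countries) < 2L)) {
    stop("condition table requires studies filtered to multinational")
  }
  conds <- registry$conditions
  if (!is.null(synonyms)) {
    conds <- lapply(conds, function(cc) {
      hit <- cc %in% names(synonyms)
      cc[hit] <- unname(synonyms[cc[hit]])
      unique(cc)
    })
  }
  study_regions <- lapply(registry$countries, function(cs) {
    unique(assign_region(cs, region_map, strict = strict))
  })
  regions <- sort(unique(unlist(study_regions, use.names = FALSE)))
  rows <- list()
  for (r in regions) {
    in_r <- vapply(study_regions, function(x) r %in% x, logical(1))
    n_r <- sum(in_r)
    cc <- unlist(conds[in_r], use.names = FALSE)
    if (length(cc) == 0L) next
    tab <- sort(table(cc), decreasing = TRUE)
    df <- data.frame(condition = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$condition), , drop = FALSE]
    if (nrow(df) > k) {
      cutoff <- df$count[k]
      df <- df[df$count >= cutoff, , drop = FALSE]
    }
    rows[[r]] <- data.frame(region = r, rank = seq_len(nrow(df)),
                            condition = df$condition, count = df$count,
                            proportion = df$count / n_r,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(region = character(0), rank = integer(0),
               condition = character(0), count = integer(0),
               proportion = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("condition_region_table", "data.frame")
  out
}

#' Write a condition-by-region table as CSV
#'
#' @param table A `condition_region_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(table, path) {
  stopifnot(inherits(table, "condition_region_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
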