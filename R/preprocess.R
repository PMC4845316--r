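# OTU filtering, genus aggregation, relative abundance, rare-genus
# exclusion and per-child sample selection near age six months.

#' Filter OTUs by read support
#'
#' Keeps exactly the OTUs observed with at least `min_reads` reads in
#' at least `min_samples` samples; the sample set is unchanged. The
#' default thresholds (>= 50 reads in >= 10 samples) guard against
#' sequencing artifacts.
#'
#' @param table OTU-level `count_table`.
#' @param min_reads minimal read count per qualifying sample.
#' @param min_samples minimal number of qualifying samples.
#' @return Filtered `count_table` (warning, not error, when empty).
#' @export
filter_otus <- function(table, min_reads = 50, min_samples = 10) {
  stopifnot(inherits(table, "count_table"))
  keep <- rowSums(table$counts >= min_reads) >= min_samples
  if (!any(keep)) warning("filter_otus: no OTU passes the filter")
  count_table(table$counts[keep, , drop = FALSE],
              feature_ids = table$feature_ids[keep],
              sample_ids = table$sample_ids,
              lineages = if (!is.null(table$lineages))
                table$lineages[keep])
}

#' Aggregate an OTU table to genus level
#'
#' Sums counts of OTUs sharing a genus name; OTUs unclassified at genus
#' are dropped. The number of classified OTUs aggregated is attached as
#' attribute `n_classified` and reported via `message()`.
#'
#' @param table OTU-level `count_table` with lineages.
#' @return Genus-level `count_table` (one representative lineage kept
#'   per genus).
#' @export
aggregate_to_genus <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$lineages))
    stop("aggregate_to_genus: lineages required")
  genus <- vapply(table$lineages, lineage_genus, character(1))
  classified <- !is.na(genus)
  if (!any(classified))
    stop("aggregate_to_genus: no OTU classified at genus level")
  message(sprintf("aggregate_to_genus: %d of %d OTUs classified at genus",
                  sum(classified), length(genus)))
  genus <- genus[classified]
  counts <- table$counts[classified, , drop = FALSE]
  lin <- table$lineages[classified]
  levels <- unique(genus)
  agg <- rowsum(counts, group = factor(genus, levels = levels),
                reorder = FALSE)
  out <- count_table(agg, feature_ids = levels,
                     sample_ids = table$sample_ids,
                     lineages = lin[match(levels, genus)])
  attr(out, "n_classified") <- sum(classified)
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param table `count_table` with positive column sums.
#' @return An `abundance_table`: same layout, each column divided by
#'   its sum (columns sum to one).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "count_table"))
  cs <- colSums(table$counts)
  if (any(cs == 0))
    stop("relative_abundance: all-zero sample(s): ",
         paste(table$sample_ids[cs == 0], collapse = ", "))
  values <- sweep(table$counts, 2, cs, "/")
  structure(list(genus_ids = table$feature_ids,
                 sample_ids = table$sample_ids,
                 values = values, lineages = table$lineages),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d genera x %d samples\n",
              length(x$genus_ids), length(x$sample_ids)))
  invisible(x)
}

#' Drop rare genera
#'
#' Removes genera whose total reads are strictly less than `frac` of
#' the grand total (default 0.01 %); a genus at exactly the threshold
#' is kept.
#'
#' @param table genus-level `count_table`.
#' @param frac removal threshold as a fraction of total reads.
#' @return Filtered `count_table`.
#' @export
filter_rare_genera <- function(table, frac = 1e-4) {
  stopifnot(inherits(table, "count_table"))
  total <- sum(table$counts)
  if (total == 0) return(table)
  keep <- rowSums(table$counts) / total >= frac
  count_table(table$counts[keep, , drop = FALSE],
              feature_ids = table$feature_ids[keep],
              sample_ids = table$sample_ids,
              lineages = if (!is.null(table$lineages))
                table$lineages[keep])
}

#' Select one sample per child near age six months
#'
#' Children with at least one sample inside the closed age window
#' (default 3-9 months = 91 to 275 days) are retained; per child the
#' sample minimizing `|age - target|` (target 183 days = 6 months) is
#' chosen, ties broken toward the younger sample.
#'
#' @param records metadata data.frame (see [read_metadata()]).
#' @param window_days closed window `c(lo, hi)` in days.
#' @param target_days target age in days.
#' @return Named character vector: `child_id -> sample_id`.
#' @export
select_window_samples <- function(records, window_days = c(91, 275),
                                  target_days = 183) {
  stopifnot(all(c("child_id", "sample_id", "sample_age_days") %in%
                  colnames(records)))
  inwin <- records$sample_age_days >= window_days[1] &
    records$sample_age_days <= window_days[2]
  rec <- records[inwin, , drop = FALSE]
  if (nrow(rec) == 0) return(stats::setNames(character(0), character(0)))
  picks <- vapply(split(rec, rec$child_id), function(r) {
    d <- abs(r$sample_age_days - target_days)
    cand <- which(d == min(d))
    # tie toward the younger sample
    r$sample_id[cand[which.min(r$sample_age_days[cand])]]
  }, character(1))
  picks
}
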