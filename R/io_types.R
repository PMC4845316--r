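# Core record types and readers for count tables, lineages, metadata,
# trees and KEGG-ortholog tables.

RANK_PREFIXES <- c("k", "p", "c", "o", "f", "g", "s")
RANK_NAMES <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

#' Construct a feature-by-sample count table
#'
#' A `count_table` holds nonnegative feature-by-sample counts (OTU or
#' genus level) with optional per-feature lineages. OTU-level tables
#' must be integer-valued; genus-level tables derived after
#' normalization may be real-valued.
#'
#' @param counts numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids unique identifiers; default to dimnames.
#' @param lineages optional list of `lineage` objects, one per feature.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, feature_ids = rownames(counts),
                        sample_ids = colnames(counts), lineages = NULL) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("count_table: feature and sample ids are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(feature_ids))
    stop("count_table: duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("count_table: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(counts) != length(feature_ids) ||
      ncol(counts) != length(sample_ids))
    stop("count_table: dimension mismatch")
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0))
    stop("count_table: counts must be nonnegative numbers")
  if (!is.null(lineages)) {
    if (length(lineages) != length(feature_ids))
      stop("count_table: one lineage per feature required")
    stopifnot(all(vapply(lineages, inherits, logical(1), "lineage")))
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  structure(list(feature_ids = feature_ids, sample_ids = sample_ids,
                 counts = counts, lineages = lineages),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (%s lineages)\n",
              length(x$feature_ids), length(x$sample_ids),
              if (is.null(x$lineages)) "no" else "with"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Parse a Greengenes-style lineage string
#'
#' Accepts semicolon-separated rank tokens prefixed `k__` .. `g__`
#' (optionally `s__`), whitespace-tolerant. A missing or empty `g__`
#' token marks the feature as unclassified at genus level. Prefixes
#' must appear in canonical kingdom-to-species order.
#'
#' @param text lineage string, e.g. `"k__Bacteria; ...; g__Bacteroides"`.
#' @return A `lineage` object: named character vector over ranks
#'   kingdom..species, `""` where unnamed.
#' @export
parse_lineage <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  ranks <- stats::setNames(rep("", 7), RANK_NAMES)
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  last <- 0L
  for (tok in tokens) {
    if (!grepl("^[kpcofgs]__", tok))
      stop("parse_lineage: malformed rank token '", tok, "'")
    pos <- match(substr(tok, 1, 1), RANK_PREFIXES)
    if (pos <= last)
      stop("parse_lineage: rank prefixes out of order at '", tok, "'")
    last <- pos
    ranks[pos] <- trimws(substring(tok, 4))
  }
  structure(ranks, class = "lineage")
}

#' Genus name of a lineage (NA if unclassified)
#' @param lin a `lineage` object.
#' @return genus name, or `NA_character_` when unclassified at genus.
#' @export
lineage_genus <- function(lin) {
  g <- unclass(lin)[["genus"]]
  if (is.null(g) || !nzchar(g)) NA_character_ else g
}

#' Rank name of a lineage at a given level
#' @param lin a `lineage` object.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return name at that rank or `NA_character_`.
#' @export
lineage_rank <- function(lin, rank = c("order", "phylum", "kingdom", "class",
                                       "family", "genus", "species")) {
  rank <- match.arg(rank)
  v <- unclass(lin)[[rank]]
  if (is.null(v) || !nzchar(v)) NA_character_ else v
}

#' Format a lineage back to Greengenes notation
#' @param x a `lineage` object.
#' @param ... unused.
#' @export
format.lineage <- function(x, ...) {
  v <- unclass(x)
  keep <- seq_len(max(c(6L, which(nzchar(v)))))  # always emit through g__
  paste(paste0(RANK_PREFIXES[keep], "__", v[keep]), collapse = "; ")
}

#' Read a feature-by-sample count table from TSV
#'
#' Expected layout: header `#FeatureID<TAB>sample1...<TAB>taxonomy`,
#' one feature per row, an optional final taxonomy column (any of
#' `taxonomy`, `lineage`, `Taxon`, case-insensitive).
#'
#' @param path file path.
#' @param integer_counts require integer counts (OTU-level tables).
#' @return A validated `count_table`.
#' @export
read_count_table <- function(path, integer_counts = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_count_table: need at least one sample column")
  cn <- colnames(df)
  if (anyDuplicated(cn))
    stop("read_count_table: duplicated column header: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  tax_col <- which(tolower(cn) %in% c("taxonomy", "lineage", "taxon"))
  lineages <- NULL
  if (length(tax_col) == 1) {
    lineages <- lapply(as.character(df[[tax_col]]), parse_lineage)
    df <- df[, -tax_col, drop = FALSE]
  }
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("read_count_table: non-numeric count in columns ",
         paste(colnames(mat)[!apply(mat, 2, is.numeric)], collapse = ", "))
  bad <- which(mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("read_count_table: negative count at row '", ids[bad[1, 1]],
         "', column '", colnames(mat)[bad[1, 2]], "'")
  if (integer_counts && any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)
    stop("read_count_table: non-integer count at row '", ids[bad[1, 1]],
         "', column '", colnames(mat)[bad[1, 2]], "'")
  }
  rownames(mat) <- ids
  count_table(mat, feature_ids = ids, sample_ids = colnames(mat),
              lineages = lineages)
}

#' Write a count table to TSV
#' @param table a `count_table`.
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  header <- c("#FeatureID", table$sample_ids)
  if (!is.null(table$lineages)) header <- c(header, "taxonomy")
  lines <- paste(header, collapse = "\t")
  for (i in seq_along(table$feature_ids)) {
    row <- c(table$feature_ids[i],
             format(table$counts[i, ], trim = TRUE, scientific = FALSE))
    if (!is.null(table$lineages)) row <- c(row, format(table$lineages[[i]]))
    lines <- c(lines, paste(row, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read subject/sample metadata
#'
#' CSV columns: `child_id, sample_id, sample_age_days, breastfeeding`
#' (1/0/empty = yes/no/unknown), `intro_potato_days, intro_meat_days,
#' intro_vegetables_days, intro_fruit_days, intro_formula_days`
#' (empty = not yet introduced), `outcome_age_days, event`.
#' Unknown breast-feeding status is retained, coded `"unknown"`.
#'
#' @param path CSV file path.
#' @return data.frame of subject records, one row per (child, sample);
#'   `breastfeeding_at_sample` is a factor yes/no/unknown and `event`
#'   logical.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("child_id", "sample_id", "sample_age_days", "breastfeeding",
                 INTRO_COLS, "outcome_age_days", "event")
  miss <- setdiff(mandatory, colnames(df))
  if (length(miss) > 0)
    stop("read_metadata: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyNA(df$child_id) || any(!nzchar(as.character(df$child_id))))
    stop("read_metadata: missing child_id")
  bf <- as.character(df$breastfeeding)
  df$breastfeeding_at_sample <-
    factor(ifelse(is.na(bf) | !nzchar(bf), "unknown",
                  ifelse(bf %in% c("1", "yes"), "yes", "no")),
           levels = c("yes", "no", "unknown"))
  df$event <- as.logical(as.integer(df$event))
  if (any(df$event & (is.na(df$outcome_age_days))))
    stop("read_metadata: event flagged without outcome_age_days for child ",
         df$child_id[which(df$event & is.na(df$outcome_age_days))[1]])
  if (any(df$outcome_age_days <= 0, na.rm = TRUE))
    stop("read_metadata: outcome_age_days must be positive")
  for (col in INTRO_COLS)
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("read_metadata: negative introduction age in ", col)
  df
}

INTRO_COLS <- c("intro_potato_days", "intro_meat_days",
                "intro_vegetables_days", "intro_fruit_days",
                "intro_formula_days")

#' Read a rooted tree from a newick file
#'
#' Absent branch lengths are replaced by 1.0. Leaf labels (genus names)
#' must be unique.
#'
#' @param path newick file path.
#' @return An `ape::phylo` tree, rooted, with branch lengths.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("read_newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("read_newick: could not parse '", path, "'")
  if (anyDuplicated(tree$tip.label))
    stop("read_newick: duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0))
    stop("read_newick: negative branch length")
  tree
}

#' Read a KEGG-ortholog abundance table from TSV
#'
#' Layout: header `#KO<TAB>sample1...`; rows are KO ids (e.g. K01034),
#' values are nonnegative relative abundances.
#'
#' @param path TSV path.
#' @return A `ko_table`: list with `ko_ids`, `sample_ids`, `abundances`.
#' @export
read_ko_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  ko_table(mat, ko_ids = ids, sample_ids = colnames(mat))
}

#' Construct a KO-by-sample abundance table
#' @param abundances nonnegative matrix, KOs in rows.
#' @param ko_ids,sample_ids identifiers; default to dimnames.
#' @return A `ko_table` object.
#' @export
ko_table <- function(abundances, ko_ids = rownames(abundances),
                     sample_ids = colnames(abundances)) {
  abundances <- as.matrix(abundances)
  ko_ids <- as.character(ko_ids)
  if (anyDuplicated(ko_ids))
    stop("ko_table: duplicate KO ids")
  if (!is.numeric(abundances) || anyNA(abundances) || any(abundances < 0))
    stop("ko_table: abundances must be nonnegative numbers")
  dimnames(abundances) <- list(ko_ids, as.character(sample_ids))
  structure(list(ko_ids = ko_ids, sample_ids = as.character(sample_ids),
                 abundances = abundances), class = "ko_table")
}

#' Write a KO table to TSV
#' @param ko a `ko_table`.
#' @param path output path.
#' @export
write_ko_table <- function(ko, path) {
  lines <- paste(c("#KO", ko$sample_ids), collapse = "\t")
  for (i in seq_along(ko$ko_ids))
    lines <- c(lines, paste(c(ko$ko_ids[i],
                              format(ko$abundances[i, ], trim = TRUE)),
                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Age conventions: ages are stored in days throughout. One month is
# 30.44 days; "6 months" is rendered as 183 days, "3-9 months" as the
# closed window [91, 275] days.
DAYS_PER_MONTH <- 30.44

#' Convert months to days (1 month = 30.44 days)
#' @param months numeric.
#' @export
months_to_days <- function(months) months * DAYS_PER_MONTH
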