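# Butyrate-pathway ratio: terminal genes of the
# butyryl-CoA:acetate CoA-transferase route (but: K01034, K01035)
# versus the phosphotransbutyrylase + butyrate kinase route
# (buk: K00634, K00929).

BUT_KOS <- c("K01034", "K01035")
BUK_KOS <- c("K00634", "K00929")

#' Per-sample but/buk butyrate-pathway ratio
#'
#' `but = K01034 + K01035`, `buk = K00634 + K00929`, ratio =
#' `but / buk`. A zero denominator is replaced by half the smallest
#' nonzero buk abundance across samples (reported via `message()`);
#' samples with positive buk are never altered.
#'
#' @param ko a `ko_table` containing all four KO rows.
#' @return data.frame: `sample_id, but_abundance, buk_abundance,
#'   ratio`.
#' @export
but_buk_ratio <- function(ko) {
  stopifnot(inherits(ko, "ko_table"))
  need <- c(BUT_KOS, BUK_KOS)
  missing <- setdiff(need, ko$ko_ids)
  if (length(missing) > 0)
    stop("but_buk_ratio: missing KO row(s): ",
         paste(missing, collapse = ", "))
  but <- colSums(ko$abundances[BUT_KOS, , drop = FALSE])
  buk <- colSums(ko$abundances[BUK_KOS, , drop = FALSE])
  if (all(buk == 0))
    stop("but_buk_ratio: buk abundance is zero in every sample")
  if (any(buk == 0)) {
    pseudo <- min(buk[buk > 0]) / 2
    message("but_buk_ratio: ", sum(buk == 0),
            " zero-buk sample(s); pseudocount ", signif(pseudo, 4),
            " applied")
    buk[buk == 0] <- pseudo
  }
  data.frame(sample_id = ko$sample_ids, but_abundance = unname(but),
             buk_abundance = unname(buk), ratio = unname(but / buk),
             stringsAsFactors = FALSE)
}

#' Compare the but/buk ratio between two subject groups
#'
#' Two-sided Wilcoxon rank-sum on the per-sample ratios (exact for
#' small groups), with group medians and the direction of the shift.
#'
#' @param ratios data.frame from [but_buk_ratio()].
#' @param group_labels named vector `sample_id -> group` (two levels).
#' @return list: `p`, `medians` (per group), `direction` (which group
#'   has the lower median).
#' @export
compare_ratio <- function(ratios, group_labels) {
  g <- group_labels[ratios$sample_id]
  if (anyNA(g))
    stop("compare_ratio: group label missing for sample(s): ",
         paste(ratios$sample_id[is.na(g)], collapse = ", "))
  res <- group_abundance_test(ratios$ratio, g)
  med <- res$medians
  list(p = res$p, medians = med,
       direction = names(med)[which.min(med)])
}
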