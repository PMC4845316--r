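# Dietary covariates, exact contingency tests, per-community taxon
# enrichment, Kaplan-Meier / proportional-hazards seroconversion
# comparison, and rank-based abundance comparisons.

#' Food-complexity status at the sampled age
#'
#' Counts the distinct ingredients among potato, meat, vegetables,
#' fruit and formula milk introduced at or before the sample age, and
#' dichotomizes at >3 vs <=3 (exactly three introduced is `"<=3"`).
#'
#' @param record one metadata row (see [read_metadata()]).
#' @return list: `child_id`, `breastfed_at_sample`, `n_ingredients`
#'   (0-5), `complexity_class` (`">3"` or `"<=3"`).
#' @export
food_complexity <- function(record) {
  intro <- unlist(record[INTRO_COLS])
  n <- sum(!is.na(intro) & intro <= record$sample_age_days)
  list(child_id = record$child_id,
       breastfed_at_sample = as.character(record$breastfeeding_at_sample),
       n_ingredients = as.integer(n),
       complexity_class = if (n >= 4) ">3" else "<=3")
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric exact test at fixed margins. The two-sided p-value
#' sums the probabilities of all tables at the observed margins that
#' are no more probable than the observed one; one-sided alternatives
#' refer to the (1,1) cell.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two_sided"` (default), `"greater"` or
#'   `"less"`.
#' @return p-value; degenerate margins (a zero row or column sum)
#'   return 1 with a warning.
#' @export
fisher_exact <- function(table,
                         alternative = c("two_sided", "greater",
                                         "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    warning("fisher_exact: degenerate margins, p = 1")
    return(1)
  }
  m <- rs[1]                     # white balls (row 1)
  n <- rs[2]
  k <- cs[1]                     # drawn (column 1)
  x <- table[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  if (alternative == "greater") {
    sum(probs[support >= x])
  } else if (alternative == "less") {
    sum(probs[support <= x])
  } else {
    p0 <- stats::dhyper(x, m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
  }
}

#' Breast-feeding 2x2 table between two subject groups
#'
#' Counts still-breast-fed vs no-longer-breast-fed children per group;
#' unknown-status children are excluded (the margins equal the counts
#' of known-status children).
#'
#' @param status data.frame with columns `group` and
#'   `breastfed_at_sample` (yes/no/unknown).
#' @return 2x2 integer matrix (rows = groups, columns = yes/no).
#' @export
breastfeeding_table <- function(status) {
  known <- status[status$breastfed_at_sample %in% c("yes", "no"), ,
                  drop = FALSE]
  tab <- table(factor(known$group),
               factor(known$breastfed_at_sample,
                      levels = c("yes", "no")))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Taxon composition and enrichment per community
#'
#' For each community and each taxon at the requested rank, reports
#' the percentage of the community's genera carrying that taxon and a
#' two-sided Fisher p-value against the pooled other communities.
#' Genera lacking the rank count as `"unclassified"`.
#'
#' @param assignment named community labeling (NA = unassigned,
#'   dropped).
#' @param lineages named list of `lineage` objects (names = genus).
#' @param rank `"order"` (default) or `"phylum"`.
#' @return data.frame: `community, taxon, n, n_community, percent, p`.
#' @export
taxon_enrichment <- function(assignment, lineages,
                             rank = c("order", "phylum")) {
  rank <- match.arg(rank)
  assigned <- assignment[!is.na(assignment)]
  if (length(assigned) == 0) stop("taxon_enrichment: nothing assigned")
  taxon <- vapply(names(assigned), function(g) {
    l <- lineages[[g]]
    v <- if (is.null(l)) NA_character_ else lineage_rank(l, rank)
    if (is.na(v)) "unclassified" else v
  }, character(1))
  out <- list()
  for (comm in sort(unique(assigned))) {
    inside <- assigned == comm
    n_comm <- sum(inside)
    for (tx in sort(unique(taxon))) {
      a <- sum(inside & taxon == tx)
      b <- n_comm - a
      c_ <- sum(!inside & taxon == tx)
      d <- sum(!inside) - c_
      p <- fisher_exact(matrix(c(a, c_, b, d), 2), "two_sided")
      out[[length(out) + 1]] <- data.frame(
        community = comm, taxon = tx, n = a, n_community = n_comm,
        percent = 100 * a / n_comm, p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`.
#' A censoring tied with an event at the same time leaves the risk set
#' after the event is counted.
#'
#' @param time event or censoring times (positive).
#' @param event logical event indicator.
#' @param group group labels.
#' @return data.frame per group and event time: `group, time, n_risk,
#'   n_event, survival` (right-continuous step values).
#' @export
km_curve <- function(time, event, group = rep("all", length(time))) {
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.logical(event)
  out <- lapply(split(seq_along(time), group), function(idx) {
    tt <- time[idx]
    ev <- event[idx]
    times <- sort(unique(tt[ev]))
    s <- 1
    rows <- lapply(times, function(t0) {
      n_risk <- sum(tt >= t0)               # censored at t0 still at risk
      d <- sum(ev & tt == t0)
      s <<- s * (1 - d / n_risk)
      data.frame(time = t0, n_risk = n_risk, n_event = d, survival = s)
    })
    if (length(rows) == 0)
      return(data.frame(group = character(0), time = numeric(0),
                        n_risk = integer(0), n_event = integer(0),
                        survival = numeric(0)))
    cbind(group = group[idx][1], do.call(rbind, rows))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hazard ratio between two groups
#'
#' Single-covariate proportional-hazards fit (Efron tie handling) with
#' a Wald confidence interval, reported alongside the log-rank test.
#' When every event falls in one group the partial likelihood is
#' monotone and the HR is reported as `Inf` (or 0) with a warning.
#'
#' @param time event/censoring times.
#' @param event logical event indicator (at least one event required).
#' @param group two-level group labels.
#' @param reference_group label taken as HR reference (denominator).
#' @return list: `hr`, `ci` (95% Wald), `p_wald`, `p_logrank`,
#'   `n_events`.
#' @export
hazard_ratio <- function(time, event, group, reference_group = NULL) {
  event <- as.logical(event)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("hazard_ratio: exactly two groups required")
  if (!any(event)) stop("hazard_ratio: no events in the data")
  if (!is.null(reference_group))
    group <- stats::relevel(group, ref = as.character(reference_group))
  ev_by_group <- table(group[event])
  monotone <- any(ev_by_group == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "efron"))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  if (monotone) {
    warning("hazard_ratio: all events in one group; HR unbounded")
    hr <- if (ev_by_group[1] == 0) Inf else 0
    ci <- c(NA_real_, NA_real_)
    p_wald <- NA_real_
  } else {
    hr <- exp(beta)
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
    p_wald <- 2 * stats::pnorm(-abs(beta / se))
  }
  lr <- survival::survdiff(survival::Surv(time, event) ~ group)
  p_logrank <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  list(hr = hr, ci = ci, p_wald = p_wald, p_logrank = p_logrank,
       n_events = sum(event))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null when both groups have at
#' most `exact_max` observations (ties handled by enumerating the
#' observed tied ranks); otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact_max exact-enumeration size limit per group.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0 || ny == 0) stop("rank_sum_test: empty group")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    splits <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[splits], nrow = nx))
    ge <- mean(sums >= w - 1e-9)
    le <- mean(sums <= w + 1e-9)
    return(min(1, 2 * min(ge, le)))
  }
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Compare one genus's abundance between two groups
#'
#' @param values abundance values (one genus across samples).
#' @param groups two-level labels aligned with `values`.
#' @return list: `p` (two-sided rank-sum), per-group `medians`.
#' @export
group_abundance_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("group_abundance_test: exactly two groups required")
  parts <- split(values, groups)
  if (any(lengths(parts) == 0))
    stop("group_abundance_test: empty group")
  list(p = rank_sum_test(parts[[1]], parts[[2]]),
       medians = vapply(parts, stats::median, numeric(1)))
}

#' Group means of a genus's abundance per age bin
#'
#' @param values abundance values across longitudinal samples.
#' @param ages sample ages (days), aligned with `values`.
#' @param groups group labels, aligned with `values`.
#' @param age_bins increasing bin edges in days (left-closed,
#'   right-open; last bin right-closed).
#' @return data.frame: `bin, group, n, mean, sd` (n = 0 rows kept).
#' @export
abundance_trajectory <- function(values, ages, groups, age_bins) {
  stopifnot(length(values) == length(ages),
            length(values) == length(groups), !is.unsorted(age_bins))
  bins <- cut(ages, breaks = age_bins, right = FALSE,
              include.lowest = TRUE)
  out <- expand.grid(bin = levels(bins), group = unique(groups),
                     stringsAsFactors = FALSE)
  out$n <- 0L
  out$mean <- NA_real_
  out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- !is.na(bins) & bins == out$bin[i] & groups == out$group[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) {
      out$mean[i] <- mean(values[sel])
      out$sd[i] <- stats::sd(values[sel])
    }
  }
  out
}
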