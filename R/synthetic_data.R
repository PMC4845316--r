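# Synthetic-cohort generator: genus/OTU count tables with planted
# co-varying communities, subject metadata with diet-community
# coupling and an elevated-hazard subgroup, a KO table with a planted
# but/buk shift, and a random genus tree. Ground-truth labels are
# returned for recovery testing.

#' Simulate a cohort count table with planted communities
#'
#' Per community c and child s a latent factor `f_cs`; genus i in c
#' has log-expected abundance `mu_i + lambda_i * f_cs + N(0, sigma)`
#' noise (heterogeneous loadings `lambda_i`), background genera evolve
#' independently with larger noise. Expected proportions feed a
#' multinomial draw of the stated depth, so column sums equal `depth`
#' exactly.
#'
#' Factors of communities 1..(n-1) are standard normal, weakly coupled
#' through a shared per-child component. The last community's factor
#' is trimodal -- its modes are the planted subject subgroups (the
#' high mode is the elevated-hazard subgroup) -- and each subgroup
#' additionally favors its own "signature" third of that community's
#' genera, so the subgroups are compositionally distinct under
#' normalized UniFrac while the community remains one positively
#' correlated block. A few low-abundance generalist bridge genera
#' keep the inferred network connected. The methods vignette explains
#' each choice and its calibration.
#'
#' @param n_children number of children.
#' @param n_genera total genera (communities plus background).
#' @param n_communities number of planted communities.
#' @param genera_per_community genera per planted community.
#' @param depth sequencing depth per sample.
#' @param lambda base community-factor loading on log abundance;
#'   per-genus loadings are `lambda * U(0.8, 1.5)` (last community
#'   `lambda * U(1, 2.2)`).
#' @param sigma per-genus log-normal noise sd for community genera
#'   (background uses 1.0, the last community `0.45 * sigma`).
#' @param samples_per_child columns per child (first one is the
#'   six-month window sample; factors are constant within child).
#' @param subgroup_sizes sizes of the planted subject subgroups (NULL:
#'   roughly equal thirds)
#'   (must sum to `n_children`); the last is the risk subgroup.
#' @param factor_cor correlation of community factors through the
#'   shared per-child component.
#' @param n_bridge number of generalist bridge genera.
#' @param otu_level split each genus into 2-40 OTUs with Dirichlet
#'   weights (exercises OTU filtering/aggregation).
#' @param seed integer seed.
#' @return list: `table` (a `count_table`, genus- or OTU-level, with
#'   lineages) and `truth` (genus -> community or NA, child ->
#'   subgroup, per-child factors, sample -> child map, seed).
#' @export
simulate_counts <- function(n_children = 40, n_genera = 60,
                            n_communities = 3,
                            genera_per_community = 12,
                            depth = 50000, lambda = 1, sigma = 0.8,
                            samples_per_child = 1,
                            subgroup_sizes = NULL,
                            factor_cor = 0.2, n_bridge = 3,
                            otu_level = FALSE, seed = 1) {
  stopifnot(n_children > 0, depth > 0, n_communities >= 1,
            genera_per_community * n_communities <= n_genera)
  if (is.null(subgroup_sizes)) {
    # default split mirrors the cohort scale: ~1/3 each, the risk
    # subgroup (last) about 13 of 40
    a <- max(1L, as.integer(round(n_children * 0.325)))
    subgroup_sizes <- c(n_children - 2L * a, a, a)
  }
  if (sum(subgroup_sizes) != n_children)
    stop("simulate_counts: subgroup_sizes must sum to n_children")
  set.seed(seed)
  genus_names <- sprintf("Genus%02d", seq_len(n_genera))
  community <- rep(NA_integer_, n_genera)
  community[seq_len(genera_per_community * n_communities)] <-
    rep(seq_len(n_communities), each = genera_per_community)
  # generalist "bridge" genera load on two communities each and keep
  # the inferred network connected without blurring the blocks; they
  # carry no planted community label.
  pairs <- utils::combn(n_communities, 2)
  bridge_of <- matrix(NA_integer_, 2, n_genera)
  n_planted <- genera_per_community * n_communities
  if (n_bridge > 0) {
    if (n_planted + n_bridge > n_genera)
      stop("simulate_counts: not enough genera for bridges")
    for (b in seq_len(n_bridge))
      bridge_of[, n_planted + b] <- pairs[, ((b - 1) %% ncol(pairs)) + 1]
  }

  subgroup <- rep(seq_along(subgroup_sizes), subgroup_sizes)
  subgroup <- sample(subgroup)                 # random child order
  children <- sprintf("child%02d", seq_len(n_children))

  # latent factors: a shared per-child component (a "dietary age"
  # axis) couples communities weakly so the inferred network is
  # connected. The last community's factor is trimodal with tight
  # modes: the three modes are the planted subject subgroups (the
  # high mode is the elevated-hazard subgroup).
  shared <- stats::rnorm(n_children)
  own <- matrix(stats::rnorm(n_communities * n_children),
                n_communities, n_children)
  factors <- sqrt(1 - factor_cor) * own +
    sqrt(factor_cor) * matrix(shared, n_communities, n_children,
                              byrow = TRUE)
  mode_centers <- c(-1.6, 0, 1.6)
  factors[n_communities, ] <- mode_centers[subgroup] +
    stats::rnorm(n_children, 0, 0.15)

  # Planted blocks sit at minority abundance over a high, stable
  # background baseline: otherwise the blocks' factor swings dominate
  # the compositional denominator and induce spurious positive
  # correlations among background genera that no null can remove.
  # Background genera get larger independent per-sample noise.
  has_comm <- !is.na(community)
  is_bridge <- !is.na(bridge_of[1, ])
  mu <- ifelse(has_comm, stats::rnorm(n_genera, 0, 0.5),
               stats::rnorm(n_genera, 2, 1))
  # bridges are kept low-abundance: rank correlations (and thus the
  # network) are scale-free, but their mass contribution to the
  # abundance-weighted stratification stays negligible
  mu[is_bridge] <- stats::rnorm(sum(is_bridge), -1.5, 0.3)
  mu[!is.na(community) & community == n_communities] <-
    stats::rnorm(sum(!is.na(community) & community == n_communities),
                 -1, 0.5)
  sigma_bg <- 1
  # heterogeneous factor loadings: taxa differ in how strongly they
  # track their community (hub-like pairs correlate more tightly).
  # The last community's loadings spread widely but stay positive:
  # every pair remains positively correlated (one cohesive block),
  # yet composition shifts along the factor because strongly loading
  # genera swell disproportionately -- so the trimodal factor yields
  # three compositionally distinct subject clusters under normalized
  # UniFrac (a Bacteroides-gradient geometry).
  loading <- lambda * stats::runif(n_genera, 0.8, 1.5)
  last <- which(!is.na(community) & community == n_communities)
  loading[last] <- lambda * stats::runif(length(last), 1, 2.2)
  # a mild subgroup signature on top of the gradient bends the three
  # modes off one axis (each subgroup slightly favors its own third
  # of the community's genera), so the cluster geometry is a
  # triangle, not a line
  signature <- rep(seq_along(subgroup_sizes),
                   length.out = length(last))
  delta <- 1.5 * outer(signature, seq_along(subgroup_sizes), "==")
  sample_ids <- as.vector(t(outer(children, seq_len(samples_per_child),
                                  function(c, k) paste0(c, "_s", k))))
  sample_child <- rep(children, each = samples_per_child)
  counts <- matrix(0L, n_genera, length(sample_ids),
                   dimnames = list(genus_names, sample_ids))
  sigma_vec <- ifelse(has_comm | is_bridge, sigma, sigma_bg)
  # the last community gets tighter residual noise: its subject
  # clusters must stay compositionally distinct after normalization
  sigma_vec[!is.na(community) & community == n_communities] <-
    0.45 * sigma
  for (s in seq_along(sample_ids)) {
    ch <- match(sample_child[s], children)
    logab <- mu + stats::rnorm(n_genera, 0, sigma_vec)
    logab[has_comm] <- logab[has_comm] +
      loading[has_comm] * factors[community[has_comm], ch]
    logab[last] <- logab[last] + delta[, subgroup[ch]]
    if (any(is_bridge))
      logab[is_bridge] <- logab[is_bridge] + 0.75 * lambda *
        (factors[bridge_of[1, is_bridge], ch] +
           factors[bridge_of[2, is_bridge], ch])
    p <- exp(logab)
    counts[, s] <- stats::rmultinom(1, depth, p / sum(p))
  }

  orders <- sprintf("Order%d", ((seq_len(n_genera) - 1) %% 6) + 1)
  phyla <- sprintf("Phylum%d", ((seq_len(n_genera) - 1) %% 3) + 1)
  lineages <- lapply(seq_len(n_genera), function(i)
    parse_lineage(sprintf(
      "k__Bacteria; p__%s; c__Class%s; o__%s; f__Family%02d; g__%s",
      phyla[i], phyla[i], orders[i], i, genus_names[i])))

  truth <- list(genus_community = stats::setNames(community, genus_names),
                bridge_genera = genus_names[is_bridge],
                child_subgroup = stats::setNames(subgroup, children),
                risk_subgroup = length(subgroup_sizes),
                factors = factors, children = children,
                sample_child = stats::setNames(sample_child, sample_ids),
                window_sample = stats::setNames(
                  sample_ids[seq(1, length(sample_ids),
                                 by = samples_per_child)], children),
                lambda = lambda, sigma = sigma, seed = seed)

  if (!otu_level) {
    table <- count_table(counts, lineages = lineages)
  } else {
    n_otus <- sample(2:40, n_genera, replace = TRUE)
    rows <- list(); ids <- character(0); lin <- list()
    for (i in seq_len(n_genera)) {
      w <- stats::rgamma(n_otus[i], 1)            # Dirichlet weights
      w <- w / sum(w)
      split_counts <- vapply(seq_along(sample_ids), function(s)
        stats::rmultinom(1, counts[i, s], w)[, 1],
        integer(n_otus[i]))
      if (n_otus[i] == 1) split_counts <- matrix(split_counts, 1)
      rows[[i]] <- split_counts
      ids <- c(ids, sprintf("OTU_%s_%02d", genus_names[i],
                            seq_len(n_otus[i])))
      lin <- c(lin, rep(lineages[i], n_otus[i]))
    }
    table <- count_table(do.call(rbind, rows), feature_ids = ids,
                         sample_ids = sample_ids, lineages = lin)
  }
  list(table = table, truth = truth)
}

#' Simulate subject metadata coupled to the planted structure
#'
#' Seroconversion times are exponential with hazard
#' `baseline_hazard * hr^{I(child in risk subgroup)}`, censored at
#' `censor_age_days`. Breast-feeding probability at the window sample
#' increases with the community-1 factor; ingredient introduction ages
#' decrease with the community-2 factor. The first sample per child
#' falls uniformly in the 3-9 month window; follow-ups extend to the
#' censoring age.
#'
#' @param truth truth object from [simulate_counts()].
#' @param baseline_hazard events per day in the non-risk group.
#' @param hr hazard ratio of the risk subgroup.
#' @param censor_age_days administrative censoring age.
#' @param diet_coupling logistic/linear coupling strength of the diet
#'   covariates to the community factors.
#' @param seed integer seed.
#' @return metadata data.frame in the [read_metadata()] layout (plus
#'   the derived `breastfeeding_at_sample` factor).
#' @export
simulate_metadata <- function(truth, baseline_hazard = 5e-4, hr = 2.8,
                              censor_age_days = 1100,
                              diet_coupling = 1.5, seed = 1) {
  stopifnot(baseline_hazard > 0, hr > 0)
  set.seed(seed + 1L)
  children <- truth$children
  n <- length(children)
  risk <- truth$child_subgroup == truth$risk_subgroup
  hazard <- baseline_hazard * ifelse(risk, hr, 1)
  t_event <- stats::rexp(n, hazard)
  event <- t_event <= censor_age_days
  outcome <- pmin(t_event, censor_age_days)

  f1 <- truth$factors[1, ]
  f2 <- if (nrow(truth$factors) >= 2) truth$factors[2, ] else f1 * 0
  p_bf <- stats::plogis(diet_coupling * f1)
  # ~10% of children lack breast-feeding records
  bf_known <- stats::runif(n) > 0.1
  base_intro <- c(potato = 150, meat = 210, vegetables = 140,
                  fruit = 160, formula = 120)

  rows <- list()
  for (s in seq_along(truth$sample_child)) {
    ch <- match(truth$sample_child[s], children)
    first <- names(truth$sample_child)[s] == truth$window_sample[ch]
    age <- if (first) stats::runif(1, 91, 275)
           else stats::runif(1, 276, censor_age_days)
    intro <- pmax(30, base_intro - 40 * diet_coupling * f2[ch] +
                    stats::rnorm(5, 0, 15))
    bf <- if (!bf_known[ch]) NA_integer_
          else as.integer(stats::runif(1) < p_bf[ch])
    rows[[s]] <- data.frame(
      child_id = children[ch],
      sample_id = names(truth$sample_child)[s],
      sample_age_days = round(age, 1),
      breastfeeding = bf,
      intro_potato_days = round(intro[1]),
      intro_meat_days = round(intro[2]),
      intro_vegetables_days = round(intro[3]),
      intro_fruit_days = round(intro[4]),
      intro_formula_days = round(intro[5]),
      outcome_age_days = round(outcome[ch], 1),
      event = as.integer(event[ch]),
      stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  bf <- as.character(md$breastfeeding)
  md$breastfeeding_at_sample <-
    factor(ifelse(is.na(bf), "unknown", ifelse(bf == "1", "yes", "no")),
           levels = c("yes", "no", "unknown"))
  md$event <- as.logical(md$event)
  rownames(md) <- NULL
  md
}

#' Simulate a KO table with a planted but/buk shift
#'
#' The four terminal butyrate-pathway KOs are lognormal per sample;
#' the but components (K01034, K01035) are multiplied by `shift` in
#' samples from risk-subgroup children (`shift = 1` plants no
#' difference).
#'
#' @param truth truth object from [simulate_counts()].
#' @param shift multiplicative but-shift in the risk subgroup (> 0).
#' @param seed integer seed.
#' @return A `ko_table` over all simulated samples.
#' @export
simulate_ko <- function(truth, shift = 0.5, seed = 1) {
  stopifnot(shift > 0)
  set.seed(seed + 2L)
  samples <- names(truth$sample_child)
  risk_child <- names(truth$child_subgroup)[
    truth$child_subgroup == truth$risk_subgroup]
  kos <- c(BUT_KOS, BUK_KOS)
  ab <- matrix(stats::rlnorm(length(kos) * length(samples),
                             meanlog = log(1e-3), sdlog = 0.4),
               length(kos), length(samples),
               dimnames = list(kos, samples))
  in_risk <- truth$sample_child[samples] %in% risk_child
  ab[BUT_KOS, in_risk] <- ab[BUT_KOS, in_risk] * shift
  ko_table(ab)
}

#' Simulate a random genus tree
#'
#' Sequential random joins of clusters with exponential branch
#' lengths; `n` names give `n` leaves and `n - 1` internal nodes.
#'
#' @param genus_names unique leaf names (>= 2).
#' @param seed integer seed.
#' @return `ape::phylo`.
#' @export
simulate_tree <- function(genus_names, seed = 1) {
  if (anyDuplicated(genus_names)) stop("simulate_tree: duplicate names")
  n <- length(genus_names)
  stopifnot(n >= 2)
  set.seed(seed + 3L)
  clusters <- genus_names
  while (length(clusters) > 1) {
    pick <- sample(length(clusters), 2)
    len <- stats::rexp(2, 1) + 0.05
    merged <- sprintf("(%s:%.4f,%s:%.4f)", clusters[pick[1]], len[1],
                      clusters[pick[2]], len[2])
    clusters <- c(clusters[-pick], merged)
  }
  ape::read.tree(text = paste0(clusters, ";"))
}

#' Write a complete synthetic input bundle to disk
#'
#' Writes `counts.tsv`, `metadata.csv`, `tree.nwk`, `ko.tsv` and
#' `truth.json` so the pipeline can be exercised from files.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed (single source of randomness).
#' @param ... passed to [simulate_counts()].
#' @return Invisibly, the truth object.
#' @export
simulate_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(seed = seed, ...)
  md <- simulate_metadata(sim$truth, seed = seed)
  ko <- simulate_ko(sim$truth, seed = seed)
  # tree over genus names, not OTU ids
  genus_names <- unique(stats::na.omit(
    vapply(sim$table$lineages, lineage_genus, character(1))))
  tree <- simulate_tree(genus_names, seed = seed)
  write_count_table(sim$table, file.path(dir, "counts.tsv"))
  utils::write.csv(md[, setdiff(colnames(md), "breastfeeding_at_sample")],
                   file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  write_ko_table(ko, file.path(dir, "ko.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(genus_community = as.list(truth$genus_community),
         child_subgroup = as.list(truth$child_subgroup),
         risk_subgroup = truth$risk_subgroup, seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null")
  invisible(truth)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (pairs with `NA` in either
#'   labeling are dropped).
#' @return ARI value.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}
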