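# Orchestration: configuration, the full preprocess -> network ->
# communities -> stratification -> associations -> butyrate analysis,
# and report serialization.

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard defaults:
#' OTU filter (>= 50 reads in >= 10 samples), rare-genus fraction
#' (0.01 %), edge rule (rho > 0.4, p < 0.05), sampling window
#' (3-9 months = 91-275 days, target 183 days) and candidate cluster
#' numbers 2..6.
#'
#' @param ... overrides of individual fields.
#' @return Named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_reads = 50, min_samples = 10, rare_frac = 1e-4,
              rho_min = 0.4, alpha = 0.05, n_perm = 1000, n_boot = 1000,
              window_days = c(91, 275), target_days = 183,
              t_min = 0.01, t_max = 100, n_points = 60, n_restarts = 20,
              k_range = 2:6, unifrac_mode = "weighted_normalized",
              input_level = "auto", seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stop("pipeline_config: unknown setting(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

#' Run the full community analysis
#'
#' Executes preprocessing (OTU filter, genus aggregation, rare-genus
#' exclusion, six-month sample selection), co-occurrence network
#' inference, Markov-stability community detection, per-community
#' subject stratification, diet/outcome association tests, and the
#' but/buk comparison (skipped with a message when no KO table is
#' given). Every stochastic stage derives its seed from
#' `config$seed`; the resolved configuration is embedded in the
#' report.
#'
#' @param counts `count_table` or path to a counts TSV.
#' @param metadata metadata data.frame or path to a CSV.
#' @param tree `ape::phylo`, path to a newick file, or `NULL` (a
#'   taxonomy cladogram is then built from the lineages).
#' @param ko `ko_table`, path to a KO TSV, or `NULL` to skip the
#'   butyrate stage.
#' @param config list from [pipeline_config()].
#' @return A `miconet_report` list with elements `config`,
#'   `preprocess`, `network`, `communities`, `stratification`,
#'   `associations`, `butyrate`.
#' @export
run_pipeline <- function(counts, metadata, tree = NULL, ko = NULL,
                         config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(ko)) ko <- read_ko_table(ko)

  ## ---- preprocess ----
  pre <- stage("preprocess", {
    level <- config$input_level
    if (level == "auto") {
      genus <- if (is.null(counts$lineages)) counts$feature_ids
      else vapply(counts$lineages, lineage_genus, character(1))
      level <- if (anyDuplicated(stats::na.omit(genus)) > 0 ||
                   anyNA(genus)) "otu" else "genus"
    }
    n_before <- length(counts$feature_ids)
    if (level == "otu") {
      filtered <- filter_otus(counts, config$min_reads,
                              config$min_samples)
      genus_tab <- aggregate_to_genus(filtered)
    } else {
      filtered <- counts
      genus_tab <- counts
    }
    genus_tab <- filter_rare_genera(genus_tab, config$rare_frac)
    picks <- select_window_samples(metadata, config$window_days,
                                   config$target_days)
    if (length(picks) < 3)
      stop("fewer than three children have a window sample")
    win <- count_table(genus_tab$counts[, picks, drop = FALSE],
                       feature_ids = genus_tab$feature_ids,
                       sample_ids = picks,
                       lineages = genus_tab$lineages)
    list(level = level, n_otus_before = n_before,
         n_otus_after = length(filtered$feature_ids),
         n_classified = attr(genus_tab, "n_classified"),
         n_genera = length(genus_tab$feature_ids),
         genus_table = genus_tab, window_samples = picks,
         abundance = relative_abundance(win),
         abundance_all = relative_abundance(genus_tab))
  })

  ## ---- network ----
  net <- stage("network", {
    res <- reboot_correlations(pre$abundance, n_perm = config$n_perm,
                               n_boot = config$n_boot,
                               seed = config$seed)
    g <- build_network(res, rho_min = config$rho_min,
                       alpha = config$alpha,
                       nodes = pre$abundance$genus_ids)
    list(correlations = res, graph = g,
         largest = largest_component(g))
  })

  ## ---- communities ----
  comm <- stage("stability", {
    curve <- stability_sweep(net$largest, t_min = config$t_min,
                             t_max = config$t_max,
                             n_points = config$n_points,
                             seed = config$seed,
                             n_restarts = config$n_restarts)
    part <- select_partition(curve)
    assignment <- assign_communities(net$graph, part)
    list(curve = curve, partition = part, k = attr(part, "k"),
         assignment = assignment)
  })

  ## ---- stratification ----
  strat <- stage("stratify", {
    if (is.null(tree)) {
      lin <- pre$genus_table$lineages
      names(lin) <- pre$genus_table$feature_ids
      tree <- taxonomy_cladogram(lin)
    }
    labs <- sort(unique(stats::na.omit(comm$assignment)))
    per_comm <- lapply(labs, function(cm) {
      sub <- community_subtable(pre$abundance, comm$assignment, cm)
      if (length(sub$genus_ids) < 2) return(NULL)
      D <- unifrac_matrix(tree, sub, mode = config$unifrac_mode)
      cl <- choose_k(D, config$k_range)
      list(community = cm, clustering = cl,
           pcoa = pcoa_coordinates(D), dist = D)
    })
    names(per_comm) <- paste0("C", labs + 1)
    per_comm[!vapply(per_comm, is.null, logical(1))]
  })

  ## ---- associations ----
  assoc <- stage("associations", {
    win_md <- metadata[match(pre$window_samples, metadata$sample_id), ,
                       drop = FALSE]
    diet <- do.call(rbind, lapply(seq_len(nrow(win_md)), function(i) {
      as.data.frame(food_complexity(win_md[i, ]),
                    stringsAsFactors = FALSE)
    }))
    lin <- pre$genus_table$lineages
    names(lin) <- pre$genus_table$feature_ids
    enrich <- taxon_enrichment(comm$assignment, lin, rank = "order")
    per_comm <- lapply(names(strat), function(cname) {
      cl <- strat[[cname]]$clustering
      child_of <- win_md$child_id[match(names(cl$labels),
                                        win_md$sample_id)]
      ev <- win_md$event[match(names(cl$labels), win_md$sample_id)]
      tt <- win_md$outcome_age_days[match(names(cl$labels),
                                          win_md$sample_id)]
      tests <- lapply(sort(unique(cl$labels)), function(k) {
        ingrp <- cl$labels == k
        st <- data.frame(
          group = ifelse(ingrp, "in", "out"),
          breastfed_at_sample = diet$breastfed_at_sample[
            match(child_of, diet$child_id)])
        bf_tab <- breastfeeding_table(st)
        p_bf <- if (all(dim(bf_tab) == 2))
          fisher_exact(bf_tab) else NA_real_
        cx <- table(factor(ingrp, levels = c(TRUE, FALSE)),
                    factor(diet$complexity_class[
                      match(child_of, diet$child_id)],
                      levels = c(">3", "<=3")))
        p_cx <- fisher_exact(matrix(as.integer(cx), 2))
        ab <- table(factor(ingrp, levels = c(TRUE, FALSE)),
                    factor(ev, levels = c(TRUE, FALSE)))
        p_ab <- fisher_exact(matrix(as.integer(ab), 2),
                             alternative = "greater")
        list(cluster = k, p_breastfeeding = p_bf,
             p_food_complexity = p_cx,
             p_autoantibody_onesided = p_ab,
             event_rate = mean(ev[ingrp]))
      })
      rates <- vapply(tests, function(x) x$event_rate, numeric(1))
      risk_cluster <- sort(unique(cl$labels))[which.max(rates)]
      surv <- tryCatch(
        hazard_ratio(tt, ev,
                     ifelse(cl$labels == risk_cluster, "risk",
                            "other"), reference_group = "other"),
        error = function(e) NULL)
      km <- km_curve(tt, ev, ifelse(cl$labels == risk_cluster,
                                    "risk", "other"))
      list(community = cname, cluster_tests = tests,
           risk_cluster = risk_cluster, survival = surv, km = km)
    })
    names(per_comm) <- names(strat)
    list(diet = diet, enrichment = enrich, per_community = per_comm)
  })

  ## ---- butyrate ----
  buty <- if (is.null(ko)) {
    message("run_pipeline: no KO table supplied, butyrate stage skipped")
    NULL
  } else {
    stage("butyrate", {
      # compare within the community whose risk cluster has the
      # strongest survival signal
      hrs <- vapply(assoc$per_community, function(pc)
        if (is.null(pc$survival)) NA_real_ else pc$survival$hr,
        numeric(1))
      target <- names(assoc$per_community)[which.max(hrs)]
      pc <- assoc$per_community[[target]]
      cl <- strat[[target]]$clustering
      ratios <- but_buk_ratio(ko)
      ratios <- ratios[ratios$sample_id %in% names(cl$labels), ,
                       drop = FALSE]
      groups <- stats::setNames(
        ifelse(cl$labels == pc$risk_cluster, "risk", "other"),
        names(cl$labels))
      cmp <- compare_ratio(ratios, groups)
      list(community = target, ratios = ratios, comparison = cmp)
    })
  }

  structure(list(config = config, preprocess = pre[c(
    "level", "n_otus_before", "n_otus_after", "n_classified",
    "n_genera", "window_samples")],
    abundance = pre$abundance, genus_table = pre$genus_table,
    network = net, communities = comm, stratification = strat,
    associations = assoc, butyrate = buty),
    class = "miconet_report")
}

#' @export
print.miconet_report <- function(x, ...) {
  cat("miconet pipeline report\n")
  cat(sprintf("  input level: %s (%d -> %d features, %d genera)\n",
              x$preprocess$level, x$preprocess$n_otus_before,
              x$preprocess$n_otus_after, x$preprocess$n_genera))
  cat(sprintf("  window samples: %d children\n",
              length(x$preprocess$window_samples)))
  cat(sprintf("  network: %d nodes, %d edges (largest component %d)\n",
              igraph::vcount(x$network$graph),
              igraph::ecount(x$network$graph),
              igraph::vcount(x$network$largest)))
  cat(sprintf("  communities: k = %d (plateau span %.2f log10 t)\n",
              x$communities$k,
              attr(x$communities$partition, "plateau_span")))
  for (cname in names(x$stratification))
    cat(sprintf("  %s: %d clusters\n", cname,
                x$stratification[[cname]]$clustering$k))
  for (cname in names(x$associations$per_community)) {
    s <- x$associations$per_community[[cname]]$survival
    if (!is.null(s))
      cat(sprintf("  %s risk cluster HR = %.2f (log-rank p = %.3g)\n",
                  cname, s$hr, s$p_logrank))
  }
  if (!is.null(x$butyrate))
    cat(sprintf("  but/buk in %s: p = %.3g (lower in '%s')\n",
                x$butyrate$community, x$butyrate$comparison$p,
                x$butyrate$comparison$direction))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes a machine-readable summary (schema version 1; no
#' timestamps, so reruns under identical seeds are byte-identical)
#' next to the resolved configuration.
#'
#' @param report a `miconet_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  comm_counts <- table(report$communities$assignment, useNA = "no")
  out <- list(
    schema_version = 1,
    config = report$config,
    preprocess = report$preprocess,
    network = list(n_nodes = igraph::vcount(report$network$graph),
                   n_edges = igraph::ecount(report$network$graph),
                   n_largest = igraph::vcount(report$network$largest)),
    communities = list(k = report$communities$k,
                       sizes = as.list(comm_counts),
                       assignment = as.list(report$communities$assignment)),
    stratification = lapply(report$stratification, function(s)
      list(k = s$clustering$k, medoids = s$clustering$medoids,
           labels = as.list(s$clustering$labels))),
    associations = lapply(report$associations$per_community,
                          function(pc)
      list(risk_cluster = pc$risk_cluster,
           survival = pc$survival, cluster_tests = pc$cluster_tests)),
    butyrate = if (is.null(report$butyrate)) NULL else
      list(community = report$butyrate$community,
           p = report$butyrate$comparison$p,
           medians = as.list(report$butyrate$comparison$medians),
           direction = report$butyrate$comparison$direction))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
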