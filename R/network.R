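# Compositionality-corrected Spearman co-occurrence network
# (ReBoot-style permutation/renormalization null) and graph
# construction.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Errors on constant
#' input (the coefficient is undefined there).
#'
#' @param x,y numeric vectors of equal length (>= 4 recommended).
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("spearman_rho: constant input, correlation undefined")
  stats::cor(rank(x), rank(y))
}

#' All-pairs compositionality-corrected correlations
#'
#' For every genus pair the permutation null shuffles the lower-indexed
#' genus's abundances across samples and renormalizes every sample
#' column to unit sum before recomputing Spearman's rho; the bootstrap
#' distribution resamples sample columns with replacement. The reported
#' p-value is the two-sided normal test of the bootstrap mean against
#' the permutation null:
#' `z = (mean_boot - mean_perm) / sqrt(var_perm + var_boot / n_boot)`,
#' i.e. the bootstrap enters through the standard error of its mean
#' (using its full variance would double the null variance and make
#' the test conservative; see the methods vignette).
#'
#' The lower-indexed genus of a pair is the one permuted, which makes
#' the result symmetric in (i, j) by construction. Constant (degenerate)
#' genera yield p = 1 with a warning. Deterministic under a fixed seed.
#'
#' @param abundance an `abundance_table` (columns sum to one).
#' @param n_perm,n_boot number of permutations / bootstrap resamples
#'   (>= 100 each).
#' @param seed integer RNG seed (recorded in the output attributes).
#' @return data.frame with columns `genus_i, genus_j, rho, p`, one row
#'   per unordered pair (i < j by table order).
#' @export
reboot_correlations <- function(abundance, n_perm = 1000, n_boot = 1000,
                                seed = 1) {
  stopifnot(inherits(abundance, "abundance_table"))
  if (n_perm < 100 || n_boot < 100)
    stop("reboot_correlations: n_perm and n_boot must be >= 100")
  V <- abundance$values
  G <- nrow(V)
  if (G < 2) stop("reboot_correlations: need at least two genera")
  if (ncol(V) < 20)
    warning("reboot_correlations: fewer than 20 samples; ",
            "p-values may be unreliable")
  res <- reboot_all_cpp(V, as.integer(n_perm), as.integer(n_boot),
                        as.numeric(seed))
  degen <- apply(V, 1, function(r) length(unique(r)) == 1)
  if (any(degen))
    warning("reboot_correlations: constant genera, p set to 1: ",
            paste(abundance$genus_ids[degen], collapse = ", "))
  idx <- which(upper.tri(res$rho), arr.ind = TRUE)
  # z-test of the bootstrap mean against the permutation null; the
  # bootstrap contributes the variance OF THE MEAN (var/n_boot) --
  # adding the full bootstrap variance would make the test
  # conservative by a factor sqrt(2) under the null
  z <- (res$mean_boot - res$mean_perm) /
    sqrt(res$var_perm + res$var_boot / n_boot)
  p <- 2 * stats::pnorm(-abs(z))
  p[degen, ] <- 1
  p[, degen] <- 1
  out <- data.frame(genus_i = abundance$genus_ids[idx[, 1]],
                    genus_j = abundance$genus_ids[idx[, 2]],
                    rho = res$rho[idx], p = p[idx],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  attr(out, "n_boot") <- n_boot
  out
}

#' Single-pair compositionality-corrected correlation
#'
#' Convenience wrapper around [reboot_correlations()]; with the same
#' seed it reproduces exactly the batch entry for the pair (the
#' permutation stream of a genus depends only on its row index and the
#' seed).
#'
#' @param abundance an `abundance_table`.
#' @param i,j genus names or row indices.
#' @inheritParams reboot_correlations
#' @return list with `genus_i, genus_j, rho, p`.
#' @export
reboot_pvalue <- function(abundance, i, j, n_perm = 1000, n_boot = 1000,
                          seed = 1) {
  if (is.character(i)) i <- match(i, abundance$genus_ids)
  if (is.character(j)) j <- match(j, abundance$genus_ids)
  stopifnot(!is.na(i), !is.na(j), i != j)
  res <- reboot_correlations(abundance, n_perm = n_perm, n_boot = n_boot,
                             seed = seed)
  a <- abundance$genus_ids[min(i, j)]
  b <- abundance$genus_ids[max(i, j)]
  row <- res[res$genus_i == a & res$genus_j == b, ]
  list(genus_i = a, genus_j = b, rho = row$rho, p = row$p)
}

#' Build the co-occurrence network from correlation results
#'
#' An edge joins two genera iff `p < alpha` and `rho > rho_min`
#' (strictly; positive correlations only). Optionally the p-values are
#' Benjamini-Hochberg adjusted first (off by default: the original
#' rule uses raw p-values).
#'
#' @param results data.frame from [reboot_correlations()].
#' @param rho_min minimal correlation (strict).
#' @param alpha significance cutoff (strict).
#' @param nodes optional character vector of node names to include even
#'   when isolated (defaults to all genera appearing in `results`).
#' @param bh_adjust apply Benjamini-Hochberg correction before
#'   thresholding.
#' @return An `igraph` undirected simple graph with edge attributes
#'   `rho` and `p`.
#' @export
build_network <- function(results, rho_min = 0.4, alpha = 0.05,
                          nodes = NULL, bh_adjust = FALSE) {
  p <- if (bh_adjust) stats::p.adjust(results$p, "BH") else results$p
  keep <- !is.na(results$rho) & !is.na(p) &
    results$rho > rho_min & p < alpha
  if (is.null(nodes))
    nodes <- sort(unique(c(results$genus_i, results$genus_j)))
  edges <- results[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("genus_i", "genus_j"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$p <- if (bh_adjust) p[keep] else edges$p
  g
}

#' Largest connected component
#'
#' Induced subgraph on the maximum-cardinality connected node set; a
#' cardinality tie is broken toward the component whose sorted node-name
#' list is lexicographically smallest.
#'
#' @param net an `igraph` graph.
#' @return The induced subgraph.
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0) stop("largest_component: empty graph")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    keys <- vapply(best, function(b) {
      paste(sort(igraph::V(net)$name[comp$membership == b]),
            collapse = "\r")
    }, character(1))
    best <- best[order(keys)[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Write a network edge list as TSV
#' @param net igraph network with `rho`, `p` edge attributes.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  colnames(el)[1:2] <- c("genus_i", "genus_j")
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
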