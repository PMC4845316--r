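# Per-community subject stratification: community-restricted abundance
# tables, UniFrac distances, PAM (k-medoids) clustering,
# Calinski-Harabasz selection of the cluster number, and PCoA
# coordinates for reporting.

#' Restrict an abundance table to one community's genera
#'
#' Rows are the genera carrying the requested community label; columns
#' and values are unchanged (no renormalization: abundances stay
#' relative to the whole-sample composition).
#'
#' @param abundance an `abundance_table`.
#' @param assignment named labeling from [assign_communities()].
#' @param community community label to extract.
#' @param renormalize divide each column by its sum within the
#'   community (off by default).
#' @return An `abundance_table` restricted to the community's genera.
#' @export
community_subtable <- function(abundance, assignment, community,
                               renormalize = FALSE) {
  members <- names(assignment)[!is.na(assignment) &
                                 assignment == community]
  if (length(members) == 0)
    stop("community_subtable: no genera carry community label '",
         community, "'")
  keep <- abundance$genus_ids %in% members
  if (!any(keep))
    stop("community_subtable: community '", community,
         "' has no genera in the abundance table")
  values <- abundance$values[keep, , drop = FALSE]
  if (renormalize) {
    cs <- colSums(values)
    if (any(cs == 0))
      stop("community_subtable: renormalization impossible, all-zero ",
           "sample within community")
    values <- sweep(values, 2, cs, "/")
  }
  structure(list(genus_ids = abundance$genus_ids[keep],
                 sample_ids = abundance$sample_ids,
                 values = values,
                 lineages = if (!is.null(abundance$lineages))
                   abundance$lineages[keep]),
            class = "abundance_table")
}

# Per-branch descendant abundance sums for a vector of tip abundances.
branch_sums <- function(tree, x) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nodesum <- numeric(ntip + tree$Nnode)
  nodesum[seq_len(ntip)] <- x[tree$tip.label]
  for (e in seq_len(nrow(tree$edge)))
    nodesum[tree$edge[e, 1]] <- nodesum[tree$edge[e, 1]] +
      nodesum[tree$edge[e, 2]]
  list(lengths = tree$edge.length, sums = nodesum[tree$edge[, 2]])
}

#' UniFrac distance between two communities
#'
#' Unweighted: shared-vs-unique branch length,
#' `sum(l_b * |I(A_b>0) - I(B_b>0)|) / sum(l_b * I(A_b>0 | B_b>0))`.
#' Weighted normalized: with `a_b`, `b_b` the fractions of each
#' community's total abundance under branch `b`,
#' `sum(l_b * |a_b - b_b|) / sum(l_b * (a_b + b_b))`. Both lie in
#' `[0, 1]`.
#'
#' @param tree `ape::phylo` with branch lengths; tip labels are genus
#'   names.
#' @param x,y nonnegative abundance vectors named by the tree's tips
#'   (every tip must be present), each with at least one positive
#'   entry.
#' @param mode `"weighted_normalized"` (default) or `"unweighted"`.
#' @return distance in `[0, 1]`.
#' @export
unifrac <- function(tree, x, y,
                    mode = c("weighted_normalized", "unweighted")) {
  mode <- match.arg(mode)
  tips <- tree$tip.label
  if (is.null(names(x)) || is.null(names(y)) ||
      !setequal(names(x), tips) || !setequal(names(y), tips))
    stop("unifrac: abundance vectors must be named by exactly the ",
         "tree's tip labels")
  if (sum(x) <= 0 || sum(y) <= 0)
    stop("unifrac: each community needs at least one positive entry")
  bx <- branch_sums(tree, x)
  by <- branch_sums(tree, y)
  l <- bx$lengths
  if (mode == "unweighted") {
    pa <- bx$sums > 0
    pb <- by$sums > 0
    denom <- sum(l * (pa | pb))
    if (denom == 0) return(0)
    sum(l * abs(pa - pb)) / denom
  } else {
    a <- bx$sums / sum(x)
    b <- by$sums / sum(y)
    denom <- sum(l * (a + b))
    if (denom == 0) return(0)
    sum(l * abs(a - b)) / denom
  }
}

#' All-pairs UniFrac distance matrix
#'
#' The tree is pruned to the table's genera (every genus must appear
#' as a leaf); tips absent from the table are dropped.
#'
#' @param tree `ape::phylo`.
#' @param table an `abundance_table` (rows = genera, columns =
#'   samples).
#' @inheritParams unifrac
#' @return Symmetric `dist`-compatible matrix with zero diagonal,
#'   sample ids as dimnames.
#' @export
unifrac_matrix <- function(tree, table,
                           mode = c("weighted_normalized",
                                    "unweighted")) {
  mode <- match.arg(mode)
  missing <- setdiff(table$genus_ids, tree$tip.label)
  if (length(missing) > 0)
    stop("unifrac_matrix: genera absent from tree: ",
         paste(missing, collapse = ", "))
  if (length(table$genus_ids) < 2)
    stop("unifrac_matrix: need at least two genera")
  tree <- ape::keep.tip(tree, table$genus_ids)
  n <- length(table$sample_ids)
  # precompute branch sums per sample
  bs <- lapply(seq_len(n), function(s) {
    x <- stats::setNames(table$values[, s], table$genus_ids)
    if (sum(x) <= 0)
      stop("unifrac_matrix: sample '", table$sample_ids[s],
           "' is all-zero within the table")
    branch_sums(tree, x)
  })
  l <- bs[[1]]$lengths
  D <- matrix(0, n, n, dimnames = list(table$sample_ids,
                                       table$sample_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (mode == "unweighted") {
      pa <- bs[[i]]$sums > 0
      pb <- bs[[j]]$sums > 0
      denom <- sum(l * (pa | pb))
      D[i, j] <- if (denom == 0) 0 else sum(l * abs(pa - pb)) / denom
    } else {
      a <- bs[[i]]$sums / sum(table$values[, i])
      b <- bs[[j]]$sums / sum(table$values[, j])
      denom <- sum(l * (a + b))
      D[i, j] <- if (denom == 0) 0 else sum(l * abs(a - b)) / denom
    }
    D[j, i] <- D[i, j]
  }
  D
}

#' Partitioning Around Medoids (deterministic BUILD + SWAP)
#'
#' BUILD seeds the medoids greedily, then SWAP exchanges a
#' (medoid, non-medoid) pair while any exchange lowers the objective
#' `sum_i d(i, nearest medoid)`. No randomness; ties in BUILD and SWAP
#' are broken toward the smallest sample index.
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param k number of clusters, `1 <= k <= n`.
#' @return A `pam_clustering`: list with `labels` (named, contiguous
#'   1..k ordered by medoid index), `medoids` (sample ids), `k`,
#'   `objective`.
#' @export
pam <- function(dist, k) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (k < 1 || k > n) stop("pam: k must be in 1..n")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  # BUILD
  med <- which.min(colSums(D))          # ties: which.min takes smallest
  while (length(med) < k) {
    near <- apply(D[, med, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% med) return(-Inf)
      sum(pmax(near - D[, j], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
  }
  objective <- function(m) sum(apply(D[, m, drop = FALSE], 1, min))
  obj <- objective(med)
  # SWAP
  repeat {
    best_delta <- 0
    best_swap <- NULL
    for (mi in seq_along(med)) {
      for (h in seq_len(n)) {
        if (h %in% med) next
        cand <- med
        cand[mi] <- h
        delta <- objective(cand) - obj
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    med[best_swap[1]] <- best_swap[2]
    obj <- obj + best_delta
  }
  med <- sort(med)
  lab <- apply(D[, med, drop = FALSE], 1, which.min)
  structure(list(labels = stats::setNames(as.integer(lab), ids),
                 medoids = ids[med], k = k, objective = obj),
            class = "pam_clustering")
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat(sprintf("pam_clustering: k = %d, objective = %.4g, medoids: %s\n",
              x$k, x$objective, paste(x$medoids, collapse = ", ")))
  invisible(x)
}

#' Dissimilarity-based Calinski-Harabasz index
#'
#' With `W = sum_c (1/(2 n_c)) sum_{i,j in c} d_ij^2`,
#' `T = (1/(2n)) sum_{i,j} d_ij^2` and `B = T - W`, the index is
#' `(B / (k-1)) / (W / (n-k))`. Scale-invariant in the distances.
#'
#' @param dist symmetric distance matrix.
#' @param clustering a `pam_clustering` (or named label vector).
#' @return CH value; `+Inf` with a warning when `W = 0` and `k < n`.
#' @export
calinski_harabasz <- function(dist, clustering) {
  D <- as.matrix(dist)
  n <- nrow(D)
  labels <- if (inherits(clustering, "pam_clustering"))
    clustering$labels else clustering
  if (!is.null(names(labels)) && !is.null(rownames(D)))
    labels <- labels[rownames(D)]
  k <- length(unique(labels))
  if (k < 2 || k > n - 1)
    stop("calinski_harabasz: need 2 <= k <= n-1")
  D2 <- D^2
  W <- sum(vapply(split(seq_len(n), labels), function(idx) {
    sum(D2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  Tt <- sum(D2) / (2 * n)
  B <- Tt - W
  if (W <= 0) {
    warning("calinski_harabasz: zero within-cluster dispersion")
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Choose the cluster number by Calinski-Harabasz over PAM solutions
#'
#' Runs [pam()] for each k in `k_range` and returns the clustering
#' maximizing the CH index; ties go to the smaller k.
#'
#' @param dist symmetric distance matrix.
#' @param k_range candidate cluster numbers (default 2..6).
#' @return The selected `pam_clustering`, with attribute `ch` (named
#'   CH values over `k_range`).
#' @export
choose_k <- function(dist, k_range = 2:6) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < max(k_range) + 1)
    stop("choose_k: need at least max(k_range)+1 samples")
  if (sum(D^2) == 0)
    stop("choose_k: degenerate distance matrix (all points identical)")
  fits <- lapply(k_range, function(k) pam(D, k))
  ch <- vapply(fits, function(f) calinski_harabasz(D, f), numeric(1))
  best <- which(ch == max(ch))[1]     # tie -> smaller k (k_range ordered)
  out <- fits[[best]]
  attr(out, "ch") <- stats::setNames(ch, k_range)
  out
}

#' Principal coordinates (classical multidimensional scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes; axes are ordered by
#' eigenvalue and signed so the first nonzero loading on each axis is
#' positive. Negative eigenvalues are truncated (reported via
#' `message()`).
#'
#' @param dist symmetric distance matrix.
#' @param n_axes number of axes to return.
#' @return Matrix samples x axes with attribute `eig` (all
#'   eigenvalues).
#' @export
pcoa_coordinates <- function(dist, n_axes = 2) {
  D <- as.matrix(dist)
  n <- nrow(D)
  fit <- stats::cmdscale(D, k = min(n_axes, n - 1), eig = TRUE)
  if (any(fit$eig < -1e-8))
    message("pcoa_coordinates: negative eigenvalues truncated")
  pts <- fit$points
  for (a in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, a]) > 1e-12)
    if (length(nz) > 0 && pts[nz[1], a] < 0) pts[, a] <- -pts[, a]
  }
  rownames(pts) <- rownames(D)
  attr(pts, "eig") <- fit$eig
  pts
}

#' Build a taxonomy cladogram from lineages
#'
#' Fallback genus tree when no phylogeny is supplied: the
#' kingdom-to-genus classification paths become a rooted cladogram
#' with unit branch lengths. This ignores true phylogenetic distances;
#' the choice is reported loudly.
#'
#' @param lineages list of `lineage` objects with genus names.
#' @return `ape::phylo` with genus names as tips.
#' @export
taxonomy_cladogram <- function(lineages) {
  genus <- vapply(lineages, lineage_genus, character(1))
  keep <- !is.na(genus) & !duplicated(genus)
  lineages <- lineages[keep]
  genus <- genus[keep]
  if (length(genus) < 2)
    stop("taxonomy_cladogram: need at least two classified genera")
  message("taxonomy_cladogram: building unit-branch cladogram from ",
          length(genus), " lineages (no phylogenetic branch lengths)")
  paths <- lapply(lineages, function(l) {
    v <- unclass(l)[1:6]
    v[!nzchar(v)] <- "unnamed"
    v
  })
  build <- function(idx, depth) {
    if (depth > 5) {
      return(vapply(idx, function(i) paste0(genus[i], ":1"),
                    character(1)))
    }
    groups <- split(idx, vapply(idx, function(i) paths[[i]][depth + 1],
                                character(1)))
    vapply(groups, function(g) {
      sub <- build(g, depth + 1)
      if (length(sub) == 1 && depth > 0) sub  # collapse unary chains
      else paste0("(", paste(sub, collapse = ","), "):1")
    }, character(1))
  }
  top <- build(seq_along(genus), 0)
  nwk <- if (length(top) == 1) paste0(sub(":1$", "", top), ";")
         else paste0("(", paste(top, collapse = ","), ");")
  ape::read.tree(text = nwk)
}
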