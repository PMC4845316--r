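# Markov-stability community detection: the stability quality
# function, a Louvain-style optimizer, the Markov-time sweep, and the
# plateau-based selection of the number of communities.
#
# For a connected undirected graph with binary adjacency A, degrees d,
# 2m = sum(d), stationary distribution pi = d / 2m and random-walk
# Laplacian L = I - D^{-1} A, the continuous-time stability of a
# partition P at Markov time t is
#
#   R(t, P) = sum_blocks sum_{i,j in block} [ (Pi exp(-tL))_ij - pi_i pi_j ]
#
# i.e. the probability that a walker at stationarity stays inside its
# block over time t, minus the chance level. L is similar to the
# symmetric normalized Laplacian, so exp(-tL) is computed from one
# eigendecomposition per graph and reused across the time grid.

# Precompute the spectral ingredients of the stability matrix.
# The quality function itself is well defined on disconnected graphs;
# only the sweep/optimizer insist on connectivity.
stability_context <- function(net, check_connected = FALSE) {
  stopifnot(igraph::vcount(net) >= 1)
  if (check_connected && igraph::components(net)$no != 1)
    stop("stability: graph must be connected ",
         "(apply largest_component first)")
  A <- as.matrix(igraph::as_adjacency_matrix(net, type = "both"))
  A[A > 0] <- 1                       # binary adjacency
  diag(A) <- 0
  deg <- rowSums(A)
  if (any(deg == 0) && nrow(A) > 1)
    stop("stability: isolated node in a supposedly connected graph")
  if (nrow(A) == 1)
    return(list(nodes = igraph::V(net)$name, pi = 1,
                U = matrix(1, 1, 1), lam = 1, dsq = 1))
  m2 <- sum(deg)
  dsq <- sqrt(deg)
  N <- A / outer(dsq, dsq)            # symmetric normalized adjacency
  e <- eigen(N, symmetric = TRUE)
  list(nodes = igraph::V(net)$name, pi = deg / m2,
       U = e$vectors, lam = e$values, dsq = dsq)
}

# Stability matrix B(t) = Pi exp(-tL) - pi pi^T (symmetric).
stability_matrix <- function(ctx, t) {
  stopifnot(t >= 0)
  if (length(ctx$pi) == 1) return(matrix(0, 1, 1))
  # exp(-tL) = D^{-1/2} U exp(-t(1-lam)) U^T D^{1/2}
  Et <- ctx$U %*% (exp(-t * (1 - ctx$lam)) * t(ctx$U))
  P <- sweep(sweep(Et, 1, ctx$dsq, "/"), 2, ctx$dsq, "*")
  B <- ctx$pi * P - outer(ctx$pi, ctx$pi)
  (B + t(B)) / 2
}

#' Markov stability of a partition
#'
#' @param net connected undirected `igraph` graph (edge weights are
#'   ignored; the adjacency is binarized).
#' @param partition integer community labels, one per node, in the
#'   vertex order of `net` (or named by node).
#' @param t Markov time, `>= 0` (`t = 0` uses the identity propagator).
#' @return Stability value (a real number `<= 1`).
#' @export
stability <- function(net, partition, t) {
  ctx <- stability_context(net)
  memb <- align_partition(partition, ctx$nodes)
  B <- stability_matrix(ctx, t)
  stability_value(B, memb)
}

align_partition <- function(partition, nodes) {
  if (!is.null(names(partition))) {
    if (!all(nodes %in% names(partition)))
      stop("stability: partition does not cover all nodes")
    partition <- partition[nodes]
  } else if (length(partition) != length(nodes)) {
    stop("stability: partition does not cover all nodes")
  }
  as.integer(factor(partition))
}

stability_value <- function(B, memb) {
  agg <- rowsum(t(rowsum(B, memb)), memb)   # community-level block sums
  sum(diag(as.matrix(agg)))
}

# One greedy pass: Louvain-style node moves to the best community
# (including a fresh singleton), then best-pair community merges,
# repeated until neither improves.
stability_optimize_once <- function(B, order) {
  n <- nrow(B)
  memb <- seq_len(n)
  repeat {
    moved <- FALSE
    repeat {
      any_move <- FALSE
      for (v in order) {
        links <- rowsum(B[, v], memb)           # sum over members per label
        labs <- as.integer(rownames(links))
        a <- memb[v]
        stay <- links[match(a, labs), 1] - B[v, v]
        gain <- links[, 1] - stay               # gain/2 of moving to label
        gain[match(a, labs)] <- 0
        single_gain <- if (sum(memb == a) > 1) -stay else -Inf
        best <- which.max(gain)
        if (gain[best] >= single_gain) {
          if (gain[best] > 1e-12) {
            memb[v] <- labs[best]
            any_move <- TRUE
          }
        } else if (single_gain > 1e-12) {
          memb[v] <- max(memb) + 1L             # split off as singleton
          any_move <- TRUE
        }
      }
      if (!any_move) break
      moved <- TRUE
    }
    # merge phase
    agg <- as.matrix(rowsum(t(rowsum(B, memb)), memb))
    if (nrow(agg) < 2) break
    off <- agg; diag(off) <- -Inf
    best <- which(off == max(off), arr.ind = TRUE)[1, ]
    if (off[best[1], best[2]] > 1e-12) {
      labs <- as.integer(rownames(agg))
      memb[memb == labs[best[2]]] <- labs[best[1]]
      moved <- TRUE
    } else if (!moved) break
  }
  as.integer(factor(memb))
}

#' Optimize the partition at a fixed Markov time
#'
#' Greedy agglomerative node-moving (Louvain-style) maximizing
#' stability at time `t`, taking the best of `n_restarts` random node
#' orders. Deterministic under a fixed seed.
#'
#' @param net connected undirected `igraph` graph.
#' @param t Markov time.
#' @param seed integer seed.
#' @param n_restarts number of random restarts.
#' @return Named integer vector node -> community label (0-based,
#'   contiguous), with attribute `stability`.
#' @export
optimize_partition <- function(net, t, seed = 1, n_restarts = 20) {
  ctx <- stability_context(net, check_connected = TRUE)
  B <- stability_matrix(ctx, t)
  optimize_partition_B(B, ctx$nodes, seed, n_restarts)
}

optimize_partition_B <- function(B, nodes, seed, n_restarts) {
  n <- nrow(B)
  best_val <- -Inf
  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    ord <- if (r == 1) seq_len(n) else sample.int(n)
    memb <- stability_optimize_once(B, ord)
    val <- stability_value(B, memb)
    if (val > best_val + 1e-12) {
      best_val <- val
      best <- memb
    }
  }
  out <- stats::setNames(as.integer(factor(best)) - 1L, nodes)
  attr(out, "stability") <- best_val
  out
}

#' Sweep Markov time and record the best partition per time
#'
#' Optimizes the partition on a log-spaced Markov-time grid. A
#' non-monotone community-number trend is reported via `message()` but
#' not enforced.
#'
#' @param net connected undirected `igraph` graph.
#' @param t_min,t_max grid range (positive).
#' @param n_points grid size.
#' @param seed integer seed.
#' @param n_restarts restarts per grid point.
#' @return A `stability_curve`: data.frame with columns `t, k,
#'   stability` and attribute `partitions` (list of labelings).
#' @export
stability_sweep <- function(net, t_min = 0.01, t_max = 100, n_points = 60,
                            seed = 1, n_restarts = 20) {
  stopifnot(t_min > 0, t_max > t_min, n_points >= 2)
  ctx <- stability_context(net, check_connected = TRUE)
  grid <- 10^seq(log10(t_min), log10(t_max), length.out = n_points)
  partitions <- vector("list", n_points)
  k <- integer(n_points)
  val <- numeric(n_points)
  for (i in seq_along(grid)) {
    B <- stability_matrix(ctx, grid[i])
    p <- optimize_partition_B(B, ctx$nodes, seed = seed + i, n_restarts)
    partitions[[i]] <- p
    k[i] <- length(unique(p))
    val[i] <- attr(p, "stability")
  }
  if (any(diff(k) > 0))
    message("stability_sweep: community number not monotone in t")
  out <- data.frame(t = grid, k = k, stability = val)
  attr(out, "partitions") <- partitions
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' Select the partition with the longest Markov-time plateau
#'
#' Among community numbers strictly greater than `min_k_exclusive`,
#' picks the k whose maximal contiguous run on the log-time grid spans
#' the longest log10(t) interval; ties go to the smaller k (and to the
#' earlier run within a k). Returns the partition at the run's midpoint
#' grid index.
#'
#' Near-trivial partitions -- more communities than `max_k_frac` times
#' the node count, i.e. average community size below two -- are not
#' considered community structure: at very small Markov times the
#' walker has not mixed at all and the optimum is always
#' singleton-dominated, for every graph. Such k values are excluded
#' from plateau candidacy (set `max_k_frac = 1` to disable).
#'
#' @param curve a `stability_curve` from [stability_sweep()].
#' @param min_k_exclusive only `k > min_k_exclusive` qualify.
#' @param max_k_frac only `k <= max_k_frac * n_nodes` qualify.
#' @return The selected partition (named labels) with attributes `k`,
#'   `t`, and `plateau_span`.
#' @export
select_partition <- function(curve, min_k_exclusive = 2,
                             max_k_frac = 0.5) {
  stopifnot(inherits(curve, "stability_curve"))
  k <- curve$k
  n_nodes <- length(attr(curve, "partitions")[[1]])
  lt <- log10(curve$t)
  runs <- rle(k)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$values > min_k_exclusive &
    runs$values <= max_k_frac * n_nodes
  if (!any(ok))
    stop("select_partition: no community number exceeds ",
         min_k_exclusive, " on the grid")
  span <- lt[ends] - lt[starts]
  # longest span; tie -> smaller k; then earlier run
  cand <- which(ok)
  cand <- cand[order(-span[cand], runs$values[cand], starts[cand])]
  sel <- cand[1]
  mid <- starts[sel] + (ends[sel] - starts[sel]) %/% 2
  part <- attr(curve, "partitions")[[mid]]
  attr(part, "k") <- runs$values[sel]
  attr(part, "t") <- curve$t[mid]
  attr(part, "plateau_span") <- span[sel]
  part
}

#' Map a partition of the largest component onto the full network
#'
#' Nodes outside the largest connected component, or with degree <= 1
#' in the full network, are not assigned to a community (`NA`); all
#' other nodes carry their community label.
#'
#' @param full_net the full `igraph` network (before component
#'   extraction).
#' @param partition labeling of the largest component's nodes.
#' @return Named integer vector over all nodes of `full_net`; `NA`
#'   marks unassigned nodes.
#' @export
assign_communities <- function(full_net, partition) {
  nodes <- igraph::V(full_net)$name
  deg <- igraph::degree(full_net)
  lc <- largest_component(full_net)
  inside <- nodes %in% igraph::V(lc)$name
  out <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  lab <- partition[nodes[inside]]
  out[inside] <- as.integer(lab)
  out[deg <= 1] <- NA_integer_
  out
}
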