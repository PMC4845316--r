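# Independent oracles and tiny fixture builders shared across tests.

# All set partitions of n elements as membership vectors (Bell(n)).
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, i, k) {
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (b in seq_len(k + 1)) {
      memb[i] <- b
      recurse(memb, i + 1, max(k, b))
    }
  }
  recurse(integer(n), 1L, 0L)
  out
}

# Stability via the dense matrix exponential (Matrix::expm), computed
# from first principles -- independent of the package's spectral path.
oracle_stability <- function(net, memb, t) {
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  A[A > 0] <- 1
  deg <- rowSums(A)
  pi <- deg / sum(deg)
  L <- diag(nrow(A)) - A / deg
  P <- if (t == 0) diag(nrow(A)) else
    as.matrix(Matrix::expm(-t * L))
  B <- diag(pi) %*% P - outer(pi, pi)
  sum(vapply(split(seq_len(nrow(A)), memb),
             function(idx) sum(B[idx, idx]), numeric(1)))
}

# Exhaustive stability optimum over all partitions.
oracle_best_partition <- function(net, t) {
  parts <- all_set_partitions(igraph::vcount(net))
  vals <- vapply(parts, function(p) oracle_stability(net, p, t),
                 numeric(1))
  list(value = max(vals), partition = parts[[which.max(vals)]])
}

# Brute-force k-medoids: exhaustive search over all medoid sets.
oracle_pam_objective <- function(D, k) {
  n <- nrow(D)
  combos <- utils::combn(n, k)
  min(apply(combos, 2, function(m)
    sum(apply(D[, m, drop = FALSE], 1, min))))
}

# Tiny count-table fixture: counts matrix with named dims + lineages.
toy_counts <- function(mat, lineage_strings = NULL) {
  lin <- if (!is.null(lineage_strings))
    lapply(lineage_strings, parse_lineage)
  count_table(mat, lineages = lin)
}

rand_dist <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  D
}
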