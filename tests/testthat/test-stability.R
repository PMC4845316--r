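two_k4 <- function() {
  igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                     e - f, e - g, e - h, f - g, f - h, g - h, d - e)
}
two_triangles <- function() {
  igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f)
}

test_that("stability matches the expm oracle and closed forms", {
  skip_if_not_installed("Matrix")
  graphs <- list(two_k4(), two_triangles(),
                 igraph::make_full_graph(5),
                 igraph::sample_gnp(7, 0.6, directed = FALSE))
  set.seed(42)
  for (g in graphs) {
    if (igraph::vcount(g) == 0 || any(igraph::degree(g) == 0)) next
    igraph::V(g)$name <- letters[seq_len(igraph::vcount(g))]
    n <- igraph::vcount(g)
    for (t in c(0, 0.5, 2)) {
      memb <- sample(3, n, replace = TRUE)
      expect_equal(stability(g, memb, t), oracle_stability(g, memb, t),
                   tolerance = 1e-10)
      # one-block partition scores exactly zero
      expect_equal(stability(g, rep(1, n), t), 0, tolerance = 1e-12)
    }
    # singleton partition at t = 0: 1 - sum(pi^2)
    pi <- igraph::degree(g) / sum(igraph::degree(g))
    expect_equal(stability(g, seq_len(n), 0), 1 - sum(pi^2),
                 tolerance = 1e-12)
  }
})

test_that("stability is non-increasing in t for a fixed partition", {
  set.seed(9)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(8, 0.5)
    if (igraph::components(g)$no != 1 || any(igraph::degree(g) == 0)) next
    igraph::V(g)$name <- letters[1:8]
    memb <- sample(3, 8, replace = TRUE)
    vals <- vapply(c(0.01, 0.1, 0.5, 1, 3, 10, 50),
                   function(t) stability(g, memb, t), numeric(1))
    expect_true(all(diff(vals) <= 1e-10))
  }
})

test_that("optimizer attains the exhaustive optimum on small graphs", {
  cases <- list(list(g = two_k4(), t = 1),
                list(g = two_triangles(), t = 1),
                list(g = igraph::make_full_graph(5), t = 3))
  for (cs in cases) {
    g <- cs$g
    igraph::V(g)$name <- letters[seq_len(igraph::vcount(g))]
    best <- oracle_best_partition(g, cs$t)
    if (igraph::components(g)$no == 1) {
      p <- optimize_partition(g, cs$t, seed = 1, n_restarts = 50)
      expect_equal(attr(p, "stability"), best$value, tolerance = 1e-9)
    } else {
      # disconnected: check the component partition is optimal
      comp <- igraph::components(g)$membership
      expect_equal(stability(g, comp, cs$t), best$value,
                   tolerance = 1e-9)
    }
  }
  # two joined K4s at t = 1: the optimum is the two cliques
  g <- two_k4()
  p <- optimize_partition(g, 1, seed = 1, n_restarts = 50)
  expect_equal(length(unique(p)), 2)
  expect_equal(unname(p["a"] == p["d"]), TRUE)
  expect_equal(unname(p["e"] == p["h"]), TRUE)
  expect_false(p["a"] == p["e"])
})

test_that("optimizer beats trivial partitions and finds singletons at tiny t", {
  g <- two_k4()
  for (t in c(0.3, 1, 5)) {
    p <- optimize_partition(g, t, seed = 2, n_restarts = 10)
    expect_gte(attr(p, "stability") + 1e-12, stability(g, rep(1, 8), t))
    expect_gte(attr(p, "stability") + 1e-12, stability(g, 1:8, t))
  }
  p <- optimize_partition(g, 0.01, seed = 2, n_restarts = 10)
  expect_equal(length(unique(p)), igraph::vcount(g))   # k = n at small t
})

test_that("stability_sweep is deterministic and needs connectivity", {
  g <- two_k4()
  c1 <- stability_sweep(g, n_points = 8, seed = 3, n_restarts = 5)
  c2 <- stability_sweep(g, n_points = 8, seed = 3, n_restarts = 5)
  expect_identical(c1$k, c2$k)
  expect_identical(c1$stability, c2$stability)
  expect_error(stability_sweep(two_triangles(), n_points = 5),
               "connected")
})

test_that("select_partition picks longest plateau with stated tie-breaks", {
  fake_curve <- function(t, k) {
    parts <- lapply(seq_along(t), function(i)
      stats::setNames(rep(seq_len(k[i]), length.out = 40),
                      paste0("g", 1:40)))
    structure(data.frame(t = t, k = k, stability = 1),
              partitions = parts,
              class = c("stability_curve", "data.frame"))
  }
  t <- 10^seq(-2, 2, length.out = 21)
  # runs: k=5 (span 0.4), k=3 (span 1.2), k=2 (rest)
  k <- c(rep(5, 3), rep(3, 7), rep(2, 11))
  sel <- select_partition(fake_curve(t, k))
  expect_equal(attr(sel, "k"), 3)
  # equal spans for k=3 and k=4 -> smaller k
  k2 <- c(rep(4, 5), rep(3, 5), rep(2, 11))
  expect_equal(attr(select_partition(fake_curve(t, k2)), "k"), 3)
  # only k <= 2 -> error
  expect_error(select_partition(fake_curve(t, rep(2, 21))), "exceeds")
  # near-trivial k (> half the nodes) is not a candidate
  k3 <- c(rep(39, 10), rep(3, 4), rep(2, 7))
  expect_equal(attr(select_partition(fake_curve(t, k3)), "k"), 3)
  expect_equal(attr(select_partition(fake_curve(t, k3),
                                     max_k_frac = 1), "k"), 39)
})

test_that("assign_communities honors the degree rule", {
  # component {a,b,c,d} with d of degree 1, isolated node z, pair x-y
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "a", "c", "x"),
               to = c("b", "c", "c", "d", "y")),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "c", "d", "x", "y", "z")))
  part <- stats::setNames(c(0L, 0L, 0L, 0L), c("a", "b", "c", "d"))
  asg <- assign_communities(g, part)
  expect_equal(unname(asg[c("a", "b", "c")]), c(0L, 0L, 0L))
  expect_true(is.na(asg["d"]))        # degree 1
  expect_true(is.na(asg["z"]))        # isolated
  expect_true(is.na(asg["x"]))        # outside largest component
})

test_that("planted 3-block SBM networks yield a k=3 plateau and recovery", {
  set.seed(21)
  hits <- 0
  for (rep in 1:5) {
    pref <- matrix(0.05, 3, 3); diag(pref) <- 0.8
    g <- igraph::sample_sbm(36, pref, block.sizes = rep(12, 3))
    igraph::V(g)$name <- sprintf("g%02d", 1:36)
    if (igraph::components(g)$no != 1) next
    curve <- suppressMessages(
      stability_sweep(g, n_points = 20, seed = rep, n_restarts = 8))
    part <- tryCatch(select_partition(curve), error = function(e) NULL)
    if (is.null(part)) next
    truth <- rep(1:3, each = 12)
    if (attr(part, "k") == 3 &&
        adjusted_rand_index(part, truth) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
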