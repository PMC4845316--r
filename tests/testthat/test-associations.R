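test_that("food_complexity counts introduced ingredients at sample age", {
  rec <- data.frame(child_id = "c1", sample_age_days = 183,
                    breastfeeding_at_sample = "yes",
                    intro_potato_days = 100, intro_meat_days = 120,
                    intro_vegetables_days = 90, intro_fruit_days = 110,
                    intro_formula_days = 60)
  st <- food_complexity(rec)
  expect_equal(st$n_ingredients, 5L)
  expect_equal(st$complexity_class, ">3")

  rec[paste0("intro_", c("potato", "meat", "vegetables", "fruit",
                         "formula"), "_days")] <- NA
  expect_equal(food_complexity(rec)$n_ingredients, 0L)
  expect_equal(food_complexity(rec)$complexity_class, "<=3")

  rec[c("intro_potato_days", "intro_meat_days",
        "intro_fruit_days")] <- c(50, 60, 183)   # boundary: intro == age
  st3 <- food_complexity(rec)
  expect_equal(st3$n_ingredients, 3L)
  expect_equal(st3$complexity_class, "<=3")      # exactly 3 is <=3
})

test_that("fisher_exact matches closed forms and the reference test", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact(tab, "greater"), 17 / 70)
  expect_equal(fisher_exact(tab, "two_sided"), 34 / 70)
  expect_equal(fisher_exact(matrix(c(0, 5, 5, 0), 2), "two_sided"),
               2 / 252)
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2)),
                 "degenerate")
  expect_equal(p, 1)

  # full agreement with stats::fisher.test over all tables with
  # margins <= 8, every alternative
  alts <- c(two_sided = "two.sided", greater = "greater", less = "less")
  for (a in 0:8) for (b in 0:(8 - a)) for (c_ in 0:8) {
    for (d in 0:(8 - c_)) {
      m <- matrix(c(a, c_, b, d), 2)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      for (alt in names(alts)) {
        expect_equal(fisher_exact(m, alt),
                     stats::fisher.test(m, alternative = alts[[alt]])$p.value,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("breastfeeding_table excludes unknowns and conserves margins", {
  st <- data.frame(
    group = c("in", "in", "in", "out", "out", "out", "out"),
    breastfed_at_sample = c("yes", "no", "unknown", "yes", "yes", "no",
                            "unknown"))
  tab <- breastfeeding_table(st)
  expect_equal(sum(tab), 5)                    # only known-status children
  expect_equal(unname(rowSums(tab)), c(2, 3))
  expect_equal(unname(tab["in", "yes"]), 1)
})

test_that("taxon_enrichment reports percentages and hypergeometric p", {
  lin <- lapply(sprintf("k__B; p__P%d; c__C; o__O%d; f__F; g__G%d",
                        rep(1, 15), c(rep(1, 6), rep(2, 9)), 1:15),
                parse_lineage)
  names(lin) <- paste0("G", 1:15)
  asg <- stats::setNames(c(rep(0L, 10), rep(1L, 5)), paste0("G", 1:15))
  # community 0: 4 of order O1 among 10
  asg[] <- c(rep(0L, 10), rep(1L, 5))
  res <- taxon_enrichment(asg, lin, rank = "order")
  row <- res[res$community == 0 & res$taxon == "O1", ]
  expect_equal(row$percent, 100 * sum(c(rep(1, 6), rep(2, 9))[1:10] == 1) / 10)
  # p equals the 2x2 fisher built from the same counts
  a <- row$n; n_c <- row$n_community
  c_ <- sum(res$n[res$taxon == "O1"]) - a
  other <- sum(!is.na(asg)) - n_c
  expect_equal(row$p, fisher_exact(matrix(c(a, c_, n_c - a, other - c_),
                                          2)))
  # absent taxon -> 0 percent, defined p
  lin2 <- lin
  asg2 <- stats::setNames(c(rep(0L, 6), rep(1L, 9)), paste0("G", 1:15))
  res2 <- taxon_enrichment(asg2, lin2, rank = "order")
  expect_true(all(res2$percent[res2$community == 1 &
                                 res2$taxon == "O1"] == 0))
})

test_that("km_curve reproduces the product-limit estimator", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored -> no drops
  km2 <- km_curve(c(5, 6), c(FALSE, FALSE))
  expect_equal(nrow(km2), 0)
  # censor tied with event stays at risk for that event
  km3 <- km_curve(c(2, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km3$n_risk[1], 3)
  expect_equal(km3$survival, c(2 / 3, 0))
  # agreement with survival::survfit on random data
  set.seed(31)
  for (rep in 1:5) {
    tt <- sample(1:8, 12, replace = TRUE)
    ev <- runif(12) < 0.6
    if (!any(ev)) next
    fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    km4 <- km_curve(tt, ev)
    at <- fit$time %in% km4$time & fit$n.event > 0
    expect_equal(km4$survival, fit$surv[at], tolerance = 1e-12)
  }
})

test_that("hazard_ratio behaves across regimes", {
  set.seed(7)
  tt <- c(rexp(30, 0.1), rexp(30, 0.1))
  grp <- rep(c("a", "b"), each = 30)
  res <- hazard_ratio(tt, rep(TRUE, 60), grp, reference_group = "a")
  expect_lt(abs(log(res$hr)), 0.8)               # HR near 1
  expect_true(res$ci[1] < res$hr && res$hr < res$ci[2])
  # all events in one group -> unbounded with warning
  expect_warning(
    res2 <- hazard_ratio(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                         c("a", "a", "b", "b"), reference_group = "b"),
    "unbounded")
  expect_equal(res2$hr, Inf)
  # single event total: finite everything, no crash
  res3 <- suppressWarnings(
    hazard_ratio(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, FALSE),
                 c("a", "b", "a", "b"), reference_group = "b"))
  expect_true(is.finite(res3$p_logrank))
  expect_error(hazard_ratio(1:4, rep(FALSE, 4), rep(c("a", "b"), 2)),
               "no events")
})

test_that("rank_sum_test matches exact enumeration and handles ties", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5)), 1)
  # agreement with wilcox.test exact p on untied small samples
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(rank_sum_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # heavy ties: normal approximation close to exact enumeration
  x <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6)
  y <- c(2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7)
  p_apx <- rank_sum_test(x, y)                   # n > exact_max path
  p_exact <- rank_sum_test(x, y, exact_max = 11)
  expect_lt(abs(p_apx - p_exact), 0.02)
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("group_abundance_test and abundance_trajectory", {
  res <- group_abundance_test(c(1, 2, 3, 10, 11, 12),
                              rep(c("a", "b"), each = 3))
  expect_equal(res$p, 0.1)
  expect_equal(unname(res$medians), c(2, 11))
  expect_error(group_abundance_test(1:4, rep("a", 4)), "two groups")

  tr <- abundance_trajectory(values = c(0.1, 0.3, 0.2, 0.4),
                             ages = c(100, 120, 400, 420),
                             groups = c("g1", "g1", "g1", "g2"),
                             age_bins = c(0, 200, 500))
  r1 <- tr[tr$bin == "[0,200)" & tr$group == "g1", ]
  expect_equal(r1$n, 2L)
  expect_equal(r1$mean, 0.2)
  expect_equal(r1$sd, sd(c(0.1, 0.3)))
  r_empty <- tr[tr$bin == "[0,200)" & tr$group == "g2", ]
  expect_equal(r_empty$n, 0L)
})
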