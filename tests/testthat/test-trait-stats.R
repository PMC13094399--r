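test_that("chi-squared: perfect independence, 2x2 closed form, degeneracy", {
  r0 <- chi_squared_independence(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # closed form N(ad-bc)^2 / (r1 r2 c1 c2)
  m <- matrix(c(10, 20, 20, 10), 2)
  r1 <- chi_squared_independence(m)
  closed <- 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30)
  expect_equal(r1$statistic, closed)
  expect_equal(r1$df, 1)

  expect_error(chi_squared_independence(matrix(c(1, 2, 0, 0), 2)),
               "degenerate")
  expect_error(chi_squared_independence(matrix(1:3, 1)), "2 rows")
})

test_that("chi-squared is invariant to permutation and transposition", {
  set.seed(15)
  m <- matrix(rpois(15, 8) + 1, 5, 3)
  s0 <- chi_squared_independence(m)$statistic
  expect_equal(chi_squared_independence(m[sample(5), sample(3)])$statistic, s0)
  expect_equal(chi_squared_independence(t(m))$statistic, s0)
})

test_that("Kruskal-Wallis reproduces the direct rank-formula oracle", {
  # {1,2,3} vs {4,5,6}: ranks 1..6, H = 12/(6*7) * sum n_i (rbar_i - 3.5)^2
  h <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(round(h$statistic, 2), 3.86)
  expect_equal(h$statistic, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))

  # identical groups: H = 0, p = 1, not an error
  h0 <- kruskal_wallis(list(a = rep(2, 4), b = rep(2, 5), c = rep(2, 3)))
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)

  # tie-corrected H against a brute-force implementation of the formula
  set.seed(31)
  for (i in 1:5) {
    g <- list(a = sample(1:6, 8, TRUE), b = sample(1:6, 6, TRUE),
              c = sample(1:6, 7, TRUE))
    x <- unlist(g); grp <- rep(names(g), lengths(g))
    N <- length(x); r <- rank(x)
    h_raw <- 12 / (N * (N + 1)) *
      sum(tapply(r, grp, function(z) length(z) * (mean(z) - (N + 1) / 2)^2))
    ties <- table(x)
    h_corr <- h_raw / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(kruskal_wallis(g)$statistic, h_corr)
  }
})

test_that("for 2 untied groups H equals the squared standardised Mann-Whitney z", {
  set.seed(77)
  x <- runif(9); y <- runif(12)   # continuous, no ties
  h <- kruskal_wallis(list(x = x, y = y))$statistic
  U <- sum(outer(x, y, ">"))
  z <- (U - 9 * 12 / 2) / sqrt(9 * 12 * (9 + 12 + 1) / 12)
  expect_equal(h, z^2)
})

test_that("Dunn's test: identical groups, antisymmetry, rank-mean oracle", {
  d0 <- dunn_posthoc(list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4)))
  expect_true(all(d0$z == 0))
  expect_true(all(d0$p_value == 1))

  g <- list(a = c(1, 5, 8), b = c(2, 9, 11, 12), c = c(3, 4, 10))
  d <- dunn_posthoc(g)
  g_swap <- g[c("b", "a", "c")]
  d_swap <- dunn_posthoc(g_swap)
  ab <- d$z[d$group1 == "a" & d$group2 == "b"]
  ba <- d_swap$z[d_swap$group1 == "b" & d_swap$group2 == "a"]
  expect_equal(ba, -ab)  # label swap flips the sign, |z| unchanged
  expect_equal(abs(ba), abs(ab))

  # rank-mean oracle, no ties: z = (Rbar_i - Rbar_j) / sqrt(N(N+1)/12 (1/ni+1/nj))
  x <- unlist(g); r <- rank(x); N <- length(x)
  rb <- tapply(r, rep(names(g), lengths(g)), mean)
  z_ab <- (rb[["a"]] - rb[["b"]]) / sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 4))
  expect_equal(ab, z_ab)
  expect_equal(d$p_value[1], 2 * pnorm(-abs(z_ab)))
})

test_that("Dunn tie correction matches the stated pooled-variance formula", {
  g <- list(a = c(1, 1, 2, 3), b = c(2, 2, 3, 4), c = c(4, 4, 5, 5))
  d <- dunn_posthoc(g)
  x <- unlist(g); r <- rank(x); N <- length(x)
  ties <- table(x)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(r, rep(names(g), lengths(g)), mean)
  z_ac <- (rb[["a"]] - rb[["c"]]) / sqrt(v0 * (1 / 4 + 1 / 4))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], z_ac)
})

test_that("adjusted Dunn p-values never fall below raw ones", {
  set.seed(5)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2), d = rnorm(8))
  for (adj in c("holm", "bonferroni")) {
    d <- dunn_posthoc(g, adjustment = adj)
    expect_true(all(d$p_adj >= d$p_value))
  }
  d_none <- dunn_posthoc(g, adjustment = "none")
  expect_equal(d_none$p_adj, d_none$p_value)
})

test_that("risk crosstabs count, percentage and warn on missing traits", {
  assess <- tibble::tibble(species_id = c("a", "b", "c"),
                           tier = c("high", "high", "low"))
  traits <- tibble::tibble(species_id = c("a", "b", "c"),
                           order = c("Ro", "Ro", "Ch"))
  ct <- risk_crosstab(assess, traits, "order")
  expect_equal(ct$counts["Ro", "high"], 2)
  expect_equal(ct$percent["Ro", "high"], 100)
  expect_equal(unname(rowSums(ct$percent)), rep(100, 2))

  # single-species table: 100% in its tier
  ct1 <- risk_crosstab(assess[1, ], traits, "order")
  expect_equal(ct1$percent["Ro", "high"], 100)

  traits$order[2] <- NA
  expect_warning(ct2 <- risk_crosstab(assess, traits, "order"), "b")
  expect_equal(sum(ct2$counts), 2)
})

test_that("crosstab row percentages use round-half-away-from-zero", {
  assess <- tibble::tibble(species_id = letters[1:8],
                           tier = c(rep("high", 3), rep("moderate", 2),
                                    rep("low", 3)))
  traits <- tibble::tibble(species_id = letters[1:8], order = "Ro")
  ct <- risk_crosstab(assess, traits, "order")
  # 3/8 = 37.5 rounds half away from zero to 38
  expect_equal(ct$percent["Ro", "high"], 38)
})

test_that("review tallies per-tier study effort and test for bias", {
  counts <- tibble::tibble(species_id = letters[1:6],
                           n_studies = c(5, 3, 0, 8, 2, 4))
  assess <- tibble::tibble(species_id = letters[1:6],
                           tier = c("high", "high", "high",
                                    "low", "low", "low"))
  rt <- review_tally(counts, assess)
  expect_equal(rt$summary$mean_studies[rt$summary$tier == "high"],
               mean(c(5, 3, 0)))
  expect_equal(rt$summary$median_studies[rt$summary$tier == "low"], 4)
  expect_s3_class(rt$test, "heat_test")

  # all-zero counts: means 0 and H = 0
  rt0 <- review_tally(dplyr::mutate(counts, n_studies = 0), assess)
  expect_true(all(rt0$summary$mean_studies == 0))
  expect_equal(rt0$test$statistic, 0)

  # random counts match the arithmetic oracle
  set.seed(21)
  for (i in 1:3) {
    cn <- dplyr::mutate(counts, n_studies = rpois(6, 4))
    rt2 <- review_tally(cn, assess)
    expect_equal(rt2$summary$mean_studies[rt2$summary$tier == "high"],
                 sum(cn$n_studies[1:3]) / 3)
  }
})

test_that("tidy methods return one-row test summaries", {
  h <- kruskal_wallis(list(a = 1:3, b = 4:6))
  td <- tidy(h)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "df", "p_value", "method"))
  expect_equal(nrow(td), 1)
})
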