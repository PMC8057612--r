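test_that("necrotic-core area counts strictly halved intima cells", {
  g <- small_annulus(n = 40)
  init_s <- matrix(0, 40, 40); init_s[g$active] <- 1
  ## unchanged SMCs: no core
  expect_equal(nc_area(init_s, init_s, g), 0)
  ## a cell at exactly half its initial value is not counted
  s <- init_s
  idx <- which(g$intima)[1:3]
  s[idx] <- 0.5
  expect_equal(nc_area(s, init_s, g), 0)
  s[idx] <- 0.5 - 1e-12
  expect_equal(nc_area(s, init_s, g), 3 * g$h^2)
  ## counting oracle: 40 intima cells at 40% of initial
  s2 <- init_s
  s2[which(g$intima)[1:40]] <- 0.4
  expect_equal(nc_area(s2, init_s, g), 40 * g$h^2)
  ## media cells never count
  s3 <- init_s
  s3[g$media] <- 0
  expect_equal(nc_area(s3, init_s, g), 0)
  ## monotone: pointwise lower SMC never shrinks the core
  set.seed(8)
  sa <- init_s; sa[g$intima] <- stats::runif(sum(g$intima))
  sb <- sa * 0.9
  expect_gte(nc_area(sb, init_s, g), nc_area(sa, init_s, g))
})

test_that("NC growth rate is the ratio series against baseline area", {
  traj <- structure(list(time = 0:5, nc_area = c(10, 12, 15, 15, 18, 20) * 1e4,
                         N0 = 1e5), class = "plaque_trajectory")
  expect_equal(nc_growth_rate(traj, 0), 1.0)
  expect_equal(nc_growth_rate(traj, 5), 2.0)
  ## elementwise division oracle over the whole series
  expect_equal(vapply(0:5, function(t) nc_growth_rate(traj, t), numeric(1)),
               traj$nc_area / traj$N0)
  traj$N0 <- 0
  expect_error(nc_growth_rate(traj, 1), "undefined-growth")
})

test_that("min-max-thirds grading reproduces the published grade columns", {
  ## LDL (higher worse) and WSS (lower worse) columns of the four-patient scale
  expect_equal(score_factor(c(138.4, 157.8, 70.4, 144.4), "higher_worse"),
               c(3L, 3L, 1L, 3L))
  expect_equal(score_factor(c(140.07, 129.9, 85.8, 77.11), "lower_worse"),
               c(1L, 1L, 3L, 3L))
  ## degenerate rule and boundary-to-milder behaviour
  expect_equal(score_factor(c(5, 5, 5), "higher_worse"), c(2L, 2L, 2L))
  ## cuts at 1 and 2: values on the cut take the milder grade
  expect_equal(score_factor(c(0, 1, 2, 3), "higher_worse"), c(1L, 1L, 2L, 3L))
  expect_equal(score_factor(c(0, 1, 2, 3), "lower_worse"), c(3L, 2L, 1L, 1L))
  expect_error(score_factor(7, "higher_worse"), "2 patients")
})

test_that("total score and fate classification follow the scale", {
  ## published per-patient grade rows
  expect_equal(total_score(c(3, 2, 3, 1, 1, 1, 2, 2)), 15L)  # P1
  expect_equal(total_score(c(3, 3, 3, 3, 1, 1, 3, 3)), 20L)  # P2
  expect_equal(total_score(c(1, 3, 1, 1, 3, 3, 1, 2)), 15L)  # P3
  expect_equal(total_score(c(2, 2, 3, 3, 3, 3, 2, 2)), 20L)  # P4
  expect_equal(total_score(rep(1, 8)), 8L)
  expect_error(total_score(c(3, 2, 3)), "eight grades")
  expect_error(total_score(c(3, 2, 3, 1, 1, 1, 2, 4)), "input error")
  ## permutation invariance
  gr <- c(3, 2, 3, 1, 1, 1, 2, 2)
  expect_equal(total_score(sample(gr)), total_score(gr))
  ## classification threshold and monotonicity
  expect_equal(classify_plaque(20), "vulnerable")
  expect_equal(classify_plaque(15), "stable")
  expect_equal(classify_plaque(15, composition = "macrocalcification"),
               "stable (macrocalcification)")
  labels <- vapply(8:24, classify_plaque, character(1))
  expect_true(!is.unsorted(labels == "vulnerable"))
})

test_that("cohort scoring assembles grades, totals and fates", {
  factors <- data.frame(
    id = paste0("P", 1:4),
    PB = c(0.8, 0.7, 0.5, 0.6), EI = c(0.5, 0.7, 0.7, 0.5),
    LDL = c(138.4, 157.8, 70.4, 144.4), HDL = c(38, 19, 31, 19),
    WSS = c(140.07, 129.9, 85.8, 77.11),
    MPhi = c(0.2, 0.3, 0.9, 0.8), SMC = c(0.6, 0.3, 0.8, 0.5),
    oxLDL = c(0.5, 0.6, 0.5, 0.5))
  st <- score_cohort(factors)
  expect_equal(st$LDL, c(3L, 3L, 1L, 3L))
  expect_equal(st$WSS, c(1L, 1L, 3L, 3L))
  expect_equal(st$total, as.integer(rowSums(st[c("PB", "EI", "LDL", "HDL",
                                                 "WSS", "MPhi", "SMC", "oxLDL")])))
  expect_true(all(st$fate %in% c("stable", "vulnerable")))
  expect_error(score_cohort(factors[-3]), "missing factor")
})

test_that("Welch group comparison matches the textbook formula", {
  a <- c(1.1, 0.9, 1.0)
  b <- c(2.0, 2.2, 2.4)
  res <- group_ttest(list(f = a), list(f = b), alpha = 0.01)
  ## closed-form Welch statistic and degrees of freedom
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, p_hand)
  ## identical groups: statistic ~ 0, p ~ 1
  x <- c(1, 2, 3, 4)
  res2 <- group_ttest(list(f = x), list(f = x))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  ## ten pooled standard deviations apart at n = 50: decisive
  set.seed(21)
  res3 <- group_ttest(list(f = rnorm(50, 0, 1)), list(f = rnorm(50, 10, 1)))
  expect_lt(res3$p_value, 0.01)
  expect_true(res3$significant)
  ## zero variance in both groups: degenerate flag, no crash
  res4 <- group_ttest(list(f = c(1, 1, 1)), list(f = c(1, 1, 1)))
  expect_true(res4$degenerate)
})

test_that("Spearman correlation handles monotone series, ties and transforms", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  ## perfect monotone and antitone association
  expect_equal(spearman_nc_correlation(x, x)$r, 1)
  expect_equal(spearman_nc_correlation(x, -x)$r, -1)
  ## tie handling against the brute-force average-rank formula
  set.seed(3)
  y <- round(stats::runif(10, 0, 5))
  res <- spearman_nc_correlation(x, y)
  expect_equal(res$r, spearman_oracle(x, y))
  ## invariance under monotone transforms of either series
  expect_equal(spearman_nc_correlation(exp(x), y)$r, res$r)
  expect_equal(spearman_nc_correlation(x, 3 * y + 2)$r, res$r)
  ## degenerate input
  expect_equal(spearman_nc_correlation(rep(1, 5), 1:5)$flag, "undefined-r")
  expect_error(spearman_nc_correlation(1:3, 1:4), "paired")
  expect_error(spearman_nc_correlation(1:2, 1:2), "3 paired")
})
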