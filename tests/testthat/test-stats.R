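test_that("regression on exact data recovers slope, r2 and a tiny p", {
  x <- 1:10
  # a perfect fit makes summary.lm warn; that is expected here
  r <- suppressWarnings(linreg_slope_test(x, 2 * x + 1))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r2, 1)
  expect_lt(r$p_slope, 1e-10)
  expect_error(linreg_slope_test(rep(3, 10), rnorm(10)), "constant")
})

test_that("r2 is invariant under affine rescaling of x and y", {
  set.seed(2)
  x <- rnorm(15); y <- 0.8 * x + rnorm(15, 0, 0.5)
  r0 <- linreg_slope_test(x, y)
  r1 <- linreg_slope_test(3 * x - 5, -2 * y + 7)
  expect_equal(r1$r2, r0$r2, tolerance = 1e-12)
  expect_equal(r1$p_slope, r0$p_slope, tolerance = 1e-12)
})

test_that("analytic and permutation slope p agree on a seeded fixture", {
  set.seed(14)
  x <- rnorm(11); y <- 0.9 * x + rnorm(11)
  r <- linreg_slope_test(x, y, n_perm = 20000, seed = 3)
  expect_lt(abs(r$p_slope - r$p_perm), 0.01)
  # seeded reproducibility
  r2 <- linreg_slope_test(x, y, n_perm = 20000, seed = 3)
  expect_identical(r$p_perm, r2$p_perm)
})

test_that("two-group comparison behaves at the extremes", {
  expect_equal(two_group_compare(rep(1, 5), rep(1, 5),
                                 method = "permutation", n_perm = 200), 1)
  set.seed(7)
  a <- rnorm(9, 0, 1); b <- rnorm(5, 10, 1)
  expect_lt(two_group_compare(a, b), 0.001)
  expect_lt(two_group_compare(a, b, method = "permutation",
                              n_perm = 5000, seed = 2), 0.001)
})

test_that("Welch and permutation p agree on seeded overlapping groups", {
  set.seed(21)
  a <- rnorm(9, 0, 1); b <- rnorm(7, 0.8, 1.3)
  pw <- two_group_compare(a, b)
  pp <- two_group_compare(a, b, method = "permutation",
                          n_perm = 20000, seed = 5)
  expect_lt(abs(pw - pp), 0.02)
})

test_that("interaction test: identical deltas give p near 1", {
  d <- data.frame(
    subject = rep(sprintf("s%d", 1:8), each = 2),
    group = rep(rep(c("control", "CTEPH"), each = 2), each = 2)[1:16],
    condition = rep(c("rest", "exercise"), 8))
  d$group <- rep(c("control", "CTEPH"), each = 8)
  d$value <- ifelse(d$condition == "exercise", 2, 1)  # same delta everywhere
  r <- interaction_permutation_test(d$value, d$group, d$condition,
                                    d$subject, n_perm = 500, seed = 1)
  expect_gt(r$p, 0.99)
  expect_equal(r$t_obs, 0)
})

test_that("exact interaction enumeration matches a by-hand computation", {
  # 3 vs 3 subjects with known deltas
  subj <- sprintf("s%d", 1:6)
  grp <- rep(c("A", "B"), each = 3)
  deltas <- c(1, 2, 3, 7, 8, 9)
  d <- data.frame(
    subject = rep(subj, each = 2),
    group = rep(grp, each = 2),
    condition = rep(c("rest", "exercise"), 6),
    value = as.vector(rbind(0, deltas)))
  r <- interaction_permutation_test(d$value, d$group, d$condition,
                                    d$subject, exact = TRUE)
  # enumerate all 20 assignments of 3 subjects to group A
  combs <- combn(6, 3)
  ts <- apply(combs, 2, function(i) mean(deltas[-i]) - mean(deltas[i]))
  t_obs <- mean(deltas[4:6]) - mean(deltas[1:3])
  p_manual <- mean(abs(ts) >= abs(t_obs) - 1e-12)
  expect_equal(r$p, p_manual)
  expect_equal(r$t_obs, t_obs)
})

test_that("unpaired subjects are excluded with a message", {
  d <- data.frame(
    subject = c(rep(sprintf("s%d", 1:5), each = 2), "s6"),
    group = c(rep(c("A", "A", "B", "B", "B"), each = 2), "A"),
    condition = c(rep(c("rest", "exercise"), 5), "rest"),
    value = rnorm(11))
  expect_message(r <- interaction_permutation_test(
    d$value, d$group, d$condition, d$subject, n_perm = 200, seed = 1),
    "unpaired")
  expect_equal(r$n_excluded, 1)
})

test_that("permutation p-values are valid under a simulated null", {
  # slope test: rejection rate at alpha = 0.05 over null replicates
  set.seed(33)
  n_rep <- 300
  rej <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(12); y <- rnorm(12)
    rej <- rej + (linreg_slope_test(x, y)$p_slope <= 0.05)
  }
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})
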