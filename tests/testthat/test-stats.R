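test_that("z-scored trial regression returns standardized coefficients", {
  set.seed(81)
  # y = x exactly: coefficient 1
  d <- data.frame(participant = rep(1:3, each = 30),
                  x = rnorm(90))
  d$y <- d$x
  z <- ztrial_regress(d, "y", "x")
  expect_equal(z$estimate, rep(1, 3))
  # single predictor equals the within-participant Pearson correlation
  d$y <- rnorm(90)
  z2 <- ztrial_regress(d, "y", "x")
  r <- vapply(1:3, function(i) {
    sel <- d$participant == i
    cor(d$y[sel], d$x[sel])
  }, numeric(1))
  expect_equal(z2$estimate, r, tolerance = 1e-12)
  # contract violations
  expect_error(ztrial_regress(d[1:5, ], "y", "x"), "fewer than")
  d$c <- 1
  expect_error(ztrial_regress(d, "y", "c"), "constant")
})

test_that("interaction terms are built from z-scored mains and re-scaled", {
  set.seed(82)
  d <- data.frame(participant = 1, a = rnorm(100), b = rnorm(100))
  d$y <- rnorm(100)
  z <- ztrial_regress(d, "y", c("a", "b"),
                      interactions = list(c("a", "b")))
  expect_equal(z$term, c("a", "b", "a:b"))
  # longhand: z-score, form product, z-score, OLS
  zs <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, zs(d$a), zs(d$b), zs(zs(d$a) * zs(d$b)))
  beta <- solve(crossprod(X), crossprod(X, zs(d$y)))
  expect_equal(z$estimate, beta[-1, 1], tolerance = 1e-10)
})

test_that("group t-test matches closed-form arithmetic on a fixed list", {
  v <- c(0.3, -0.1, 0.4, 0.2, 0.05)
  out <- group_ttest(v)
  m <- mean(v); s <- sd(v); n <- 5
  expect_equal(out$t, m / (s / sqrt(n)))
  expect_equal(out$df, 4)
  expect_equal(out$p, 2 * pt(-abs(m / (s / sqrt(n))), 4))
  expect_equal(out$d, m / s)
  expect_error(group_ttest(rep(0.5, 6)), "zero variance")
  expect_error(group_ttest(c(1, 2)), "at least 3")
})

test_that("false-positive rate of group regression tests is near alpha", {
  set.seed(83)
  n_rep <- 1000
  n_sub <- 12
  n_tr <- 40
  # per replicate: per-participant correlations of independent variables,
  # group one-sample t; count p < .05
  hits <- 0
  for (r in seq_len(n_rep)) {
    rr <- vapply(seq_len(n_sub), function(i) {
      cor(rnorm(n_tr), rnorm(n_tr))
    }, numeric(1))
    tt <- t.test(rr)
    if (tt$p.value < 0.05) hits <- hits + 1
  }
  fp <- hits / n_rep
  expect_lt(abs(fp - 0.05), 0.025)
})

test_that("a single-cell grid reduces to a sign-flip permutation t-test", {
  set.seed(84)
  v <- rnorm(14, mean = 1)    # clearly suprathreshold single cell
  cl <- cluster_permutation(matrix(v, ncol = 1), c(1, 1), n_perm = 4000)
  # longhand sign-flip permutation p for the same statistic
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_obs <- abs(tstat(v))
  null <- replicate(4000, abs(tstat(v * sample(c(-1, 1), 14, TRUE))))
  p_ref <- (1 + sum(null >= t_obs)) / 4001
  # the cluster mass of a single suprathreshold cell is its t value
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$mass, tstat(v))
  expect_lt(abs(cl$clusters$p - p_ref), 0.02)
})

test_that("cluster structure respects adjacency, signs and the p floor", {
  set.seed(85)
  n_sub <- 10
  base <- matrix(rnorm(n_sub * 60), n_sub, 60)
  # plant a strong positive block (cells 11..30 = grid columns 2..5 of 6x10)
  maps <- base
  maps[, 11:30] <- maps[, 11:30] + 3
  cl <- cluster_permutation(maps, c(6, 10), n_perm = 1000)
  big <- cl$clusters[which.max(abs(cl$clusters$mass)), ]
  expect_equal(big$sign, 1)
  expect_gte(big$n_cells, 18)
  expect_lte(big$p, 0.01)
  expect_gte(big$p, 1 / 1001)           # permutation floor respected
  # sign-flipped maps give the mirrored decomposition
  cl_neg <- cluster_permutation(-maps, c(6, 10), n_perm = 1000)
  big_neg <- cl_neg$clusters[which.max(abs(cl_neg$clusters$mass)), ]
  expect_equal(big_neg$mass, -big$mass, tolerance = 1e-10)
  # no suprathreshold cells: empty result, not an error
  balanced <- matrix(rep(c(1, -1), each = 5), 10, 10)   # per-cell mean 0
  cl_null <- cluster_permutation(balanced, c(2, 5), n_perm = 100)
  expect_equal(nrow(cl_null$clusters), 0)
})

test_that("separated same-sign regions form distinct clusters", {
  set.seed(86)
  n_sub <- 12
  maps <- matrix(rnorm(n_sub * 50, sd = 0.3), n_sub, 50)
  # two positive islands separated by a negative trench (5x10 grid)
  maps[, 1:10] <- maps[, 1:10] + 2       # columns 1-2
  maps[, 21:25] <- maps[, 21:25] - 2     # column 5 (negative)
  maps[, 41:50] <- maps[, 41:50] + 2     # columns 9-10
  cl <- cluster_permutation(maps, c(5, 10), n_perm = 500)
  pos <- cl$clusters[cl$clusters$sign > 0 & cl$clusters$n_cells >= 5, ]
  neg <- cl$clusters[cl$clusters$sign < 0 & cl$clusters$n_cells >= 4, ]
  expect_gte(nrow(pos), 2)
  expect_gte(nrow(neg), 1)
})

test_that("binned power analysis recovers planted coupling and splits remainders", {
  set.seed(87)
  # decoding = -power exactly: strictly decreasing bins, negative slope
  d <- data.frame(participant = rep(1:5, each = 40),
                  power = rnorm(200))
  d$score <- -d$power
  out <- bin_analysis(d, "power", "score")
  expect_true(all(out$slopes$slope < 0))
  expect_lt(out$tests$p, 1e-4)
  per <- out$bins[out$bins$participant == 1, ]
  expect_equal(per$bin, 1:8)
  expect_true(all(diff(per$mean_power) > 0))
  expect_true(all(diff(per$mean_score) < 0))
  # independent score: slope near zero
  d$score <- rnorm(200)
  out2 <- bin_analysis(d, "power", "score")
  expect_gt(out2$tests$p, 0.001)
  # remainder trials spread across the lowest bins (19 = 3+3+3+2*5)
  d19 <- data.frame(participant = 1, power = 1:19, score = 1:19)
  b19 <- bin_analysis(d19, "power", "score")$bins
  expect_equal(b19$mean_power[1:3], c(2, 5, 8))   # bins of size 3
  expect_equal(b19$mean_power[4], 10.5)           # then size 2
  expect_error(bin_analysis(d19[1:5, ], "power", "score"), "fewer trials")
})

test_that("repeated-measures ANOVA matches longhand sums of squares", {
  # fixed 3 participants x 3 levels table, F computed by hand
  d <- data.frame(
    participant = rep(1:3, each = 3),
    level = rep(c("a", "b", "c"), 3),
    value = c(4, 6, 8, 5, 7, 12, 3, 6, 9)
  )
  out <- rm_anova_1way(d, "value", "level", gg = FALSE)
  # longhand decomposition
  m <- matrix(d$value, 3, 3, byrow = TRUE)
  grand <- mean(m)
  ss_level <- 3 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  f_ref <- (ss_level / 2) / (ss_err / 4)
  expect_equal(out$F, f_ref, tolerance = 1e-10)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 4)
  expect_equal(out$partial_eta2, ss_level / (ss_level + ss_err),
               tolerance = 1e-10)

  # level means equalized on noisy data: F vanishes
  set.seed(90)
  m0 <- matrix(rnorm(12), 4, 3)
  m0 <- sweep(m0, 2, colMeans(m0))        # exactly equal level means
  d0 <- data.frame(participant = rep(1:4, each = 3),
                   level = rep(c("a", "b", "c"), 4),
                   value = as.vector(t(m0)))
  out0 <- rm_anova_1way(d0, "value", "level", gg = FALSE)
  expect_lt(out0$F, 1e-20)

  # two-level case equals the squared paired t
  set.seed(88)
  d2 <- data.frame(participant = rep(1:10, 2),
                   level = rep(c("a", "b"), each = 10),
                   value = rnorm(20))
  out2 <- rm_anova_1way(d2, "value", "level", gg = FALSE)
  tt <- t.test(d2$value[1:10], d2$value[11:20], paired = TRUE)
  expect_equal(out2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out2$p, tt$p.value, tolerance = 1e-10)

  # Greenhouse-Geisser epsilon shrinks the dfs within the legal range
  set.seed(89)
  d3 <- data.frame(participant = rep(1:12, each = 4),
                   level = rep(letters[1:4], 12),
                   value = rnorm(48))
  out3 <- rm_anova_1way(d3, "value", "level", gg = TRUE)
  expect_lte(out3$epsilon, 1)
  expect_gte(out3$epsilon, 1 / 3)
  expect_equal(out3$df1, 3 * out3$epsilon)

  # incomplete tables are rejected
  expect_error(rm_anova_1way(d2[-1, ], "value", "level"), "complete")
})
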