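test_that("Welch t-test handles regular, separated and degenerate data", {
  expect_equal(welch_p(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(1)
  expect_lt(welch_p(rnorm(12), rnorm(9, 5)), 1e-3)
  expect_message(p <- welch_p(c(2, 2, 2), c(2, 2, 2)), "degenerate")
  expect_equal(p, 1)
})

test_that("Welch p agrees with a label-permutation test on a fixed dataset", {
  set.seed(7)
  x <- rnorm(12, 0, 1); y <- rnorm(9, 0.9, 1)
  p_welch <- welch_p(x, y)
  # permutation oracle: exact reference distribution of the Welch statistic
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) +
                                 stats::var(b) / length(b))
  }
  z <- c(x, y); n1 <- length(x)
  t_obs <- abs(welch_t(x, y))
  set.seed(99)
  nperm <- 20000L
  t_perm <- replicate(nperm, {
    idx <- sample.int(length(z), n1)
    abs(welch_t(z[idx], z[-idx]))
  })
  p_perm <- (1 + sum(t_perm >= t_obs)) / (1 + nperm)
  # permutation and t-reference p-values agree up to the small-sample
  # approximation error plus Monte-Carlo noise
  mc_se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(p_welch - p_perm), 0.02 + 3 * mc_se)
})

test_that("Cohen's d matches its definition and invariances", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # groups whose means differ by exactly one pooled SD
  x <- c(-1, 0, 1); y <- x + stats::sd(x)
  expect_equal(cohens_d(x, y), 1)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(8, 1)
  expect_equal(cohens_d(a, b), cohens_d(10 * a, 10 * b))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("rank AUC equals the exhaustive pairwise oracle (with ties)", {
  expect_equal(auc_rank(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_error(auc_rank(1:5, rep(1, 5)), "both classes")
  auc_brute <- function(x, y) {
    pos <- x[y == 1]; neg <- x[y == 0]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  set.seed(31)
  for (k in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.3 * (k %% 2))
    expect_equal(auc_rank(x, y), auc_brute(x, y), tolerance = 1e-12)
  }
})

test_that("1-D 2-means equals the brute-force optimal sorted split", {
  wcss_brute <- function(x) {
    xs <- sort(x); n <- length(x)
    best <- Inf; kb <- 1
    for (k in 1:(n - 1)) {
      w <- sum((xs[1:k] - mean(xs[1:k]))^2) +
        sum((xs[(k + 1):n] - mean(xs[(k + 1):n]))^2)
      if (w < best) { best <- w; kb <- k }
    }
    list(wcss = best, centers = c(mean(xs[1:kb]), mean(xs[(kb + 1):n])))
  }
  set.seed(17)
  for (k in 1:100) {
    n <- sample(3:30, 1)
    x <- if (k %% 2) rnorm(n) else c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 3))
    if (length(unique(x)) < 2) next
    km <- kmeans_1d(x)
    oracle <- wcss_brute(x)
    expect_equal(km$wcss, oracle$wcss, tolerance = 1e-9)
    expect_equal(km$centers, oracle$centers, tolerance = 1e-9)
  }
  expect_error(kmeans_1d(rep(1, 5)), "distinct")
})

test_that("unsupervised evaluation clusters, maps and scores correctly", {
  x <- c(rnorm(10, 0, 0.05), rnorm(8, 1, 0.05))
  y <- rep(c(0, 1), c(10, 8))
  m <- unsupervised_eval(x, y)
  expect_equal(m$ACC, 100)
  expect_equal(m$SE, 100)
  expect_equal(m$SP, 100)
  # flipping the labels swaps sensitivity and specificity
  m2 <- unsupervised_eval(x, 1 - y)
  expect_equal(m2$SE, m$SP)
  expect_equal(m2$SP, m$SE)
})

test_that("threshold is the centroid midpoint, affinely equivariant and consistent", {
  x <- c(0.4, 0.6, 0.8, 1.0)
  expect_equal(threshold_select(x), 0.7)   # centroids 0.5 and 0.9
  set.seed(5)
  z <- rnorm(25)
  t0 <- threshold_select(z)
  expect_equal(threshold_select(3 * z + 2), 3 * t0 + 2, tolerance = 1e-9)
  # classifying by the threshold reproduces the k-means partition
  km <- kmeans_1d(z)
  expect_identical(as.integer(z > t0) + 1L, km$cluster)
})

test_that("DeLong test is sane and agrees with a paired bootstrap", {
  set.seed(12)
  y <- rep(c(0, 1), c(12, 9))
  f1 <- rnorm(21) + y * 1.2
  # identical features: AUC difference 0, p = 1
  d0 <- delong_test(f1, f1, y)
  expect_equal(d0$p, 1)
  f2 <- rnorm(21) + y * 0.4
  d <- delong_test(f1, f2, y)
  expect_true(d$p >= 0 && d$p <= 1)
  # paired bootstrap oracle: normal-approximation p with bootstrap SE
  set.seed(101)
  nboot <- 10000L
  diffs <- replicate(nboot, {
    idx <- c(sample(which(y == 0), replace = TRUE),
             sample(which(y == 1), replace = TRUE))
    auc_rank(f1[idx], y[idx]) - auc_rank(f2[idx], y[idx])
  })
  d_obs <- d$auc1 - d$auc2
  p_boot <- 2 * stats::pnorm(-abs(d_obs) / stats::sd(diffs))
  expect_lt(abs(d$p - p_boot), 0.05)
})

test_that("power_sample_size reproduces the design calculation", {
  # one-tailed, alpha 0.1, power 0.8, d = 1 -> 10 per group
  expect_equal(power_sample_size(0.1, 0.8, 1, tails = 1), 10)
  # enormous effect: minimum group size
  expect_equal(power_sample_size(0.1, 0.8, 10, tails = 1), 2)
  # within 1 of the normal-approximation closed form (with the standard
  # z^2/4 small-sample correction, Lachin)
  for (d in c(0.5, 0.8, 1, 1.2)) {
    n <- power_sample_size(0.05, 0.8, d, tails = 2)
    n_approx <- 2 * (stats::qnorm(0.975) + stats::qnorm(0.8))^2 / d^2 +
      stats::qnorm(0.975)^2 / 4
    expect_lte(abs(n - n_approx), 1)
  }
  expect_error(power_sample_size(0.5, 0.4, 1), "infeasible")
  expect_error(power_sample_size(0.1, 0.8, -1), "effect size")
})

test_that("normalize01 maps to [0,1] preserving order", {
  expect_equal(normalize01(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(3)
  x <- rnorm(40)
  z <- normalize01(x)
  expect_equal(range(z), c(0, 1))
  expect_identical(order(z), order(x))
  expect_error(normalize01(rep(2, 5)), "constant")
})

test_that("supervised evaluation: separation, confusion arithmetic, null behaviour", {
  y <- rep(c(0, 1), c(12, 9))
  x <- y * 10 + rnorm(21, 0, 0.1)
  m <- supervised_eval(x, y, list(seed = 1))
  expect_equal(m$ACC, 100)
  expect_equal(m$SE, 100)
  expect_equal(m$SP, 100)

  # fixed confusion counts TP=8 FN=1 TN=10 FP=2
  pred <- rep(c(1, 0, 0, 1), c(8, 1, 10, 2))
  yy <- rep(c(1, 1, 0, 0), c(8, 1, 10, 2))
  cm <- uteroflow:::confusion_metrics(pred, yy)
  expect_equal(cm$ACC, 100 * 18 / 21, tolerance = 1e-9)   # 85.7
  expect_equal(cm$SE, 100 * 8 / 9, tolerance = 1e-9)      # 88.9
  expect_equal(cm$SP, 100 * 10 / 12, tolerance = 1e-9)    # 83.3

  # label-independent feature: accuracy near the majority-class rate
  set.seed(8)
  accs <- replicate(12, {
    xp <- rnorm(21)
    supervised_eval(xp, y, list(seed = sample.int(1e6, 1),
                                n_repeats = 5))$ACC
  })
  maj <- 100 * 12 / 21
  mc_se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - maj), 3 * mc_se + 8)
})

test_that("feature_report produces the full per-feature metric block", {
  set.seed(21)
  y <- rep(c("NPE", "PE"), c(12, 9))
  feats <- data.frame(good = c(rnorm(12), rnorm(9, 3)), noise = rnorm(21))
  rep <- feature_report(feats, y, list(seed = 2))
  expect_equal(nrow(rep), 2)
  expect_true(all(c("p_ttest", "cohens_d", "sup_ACC", "sup_CI", "sup_SE",
                    "sup_SP", "AUC", "uns_ACC", "uns_SE", "uns_SP",
                    "threshold") %in% names(rep)))
  expect_gt(rep$AUC[rep$feature == "good"], 0.9)
  expect_true(all(rep$sup_ACC >= 0 & rep$sup_ACC <= 100))
  expect_true(all(rep$AUC >= 0 & rep$AUC <= 1))
})
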