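#' Welch two-sample t-test p-value
#'
#' Two-sided Welch test between the NPE and PE values of one feature. If both
#' groups are constant the test is degenerate: p = 1 when the means agree
#' (no evidence of a difference), p = 0 otherwise; both cases are messaged.
#'
#' @param x_npe,x_pe numeric vectors, at least 2 values each
#' @return the p-value
#' @export
welch_p <- function(x_npe, x_pe) {
  if (length(x_npe) < 2 || length(x_pe) < 2)
    stop("welch_p: need at least 2 values per group")
  tryCatch(stats::t.test(x_npe, x_pe)$p.value,
           error = function(e) {
             p <- if (isTRUE(all.equal(mean(x_npe), mean(x_pe)))) 1 else 0
             message("welch_p: degenerate (constant) data, p = ", p, " by convention")
             p
           })
}

#' Cohen's d effect size
#'
#' Absolute standardized mean difference using the pooled standard deviation,
#' `|mean(x_pe) - mean(x_npe)| / s_pooled`.
#'
#' @param x_npe,x_pe numeric vectors, at least 2 values each
#' @return |d|
#' @export
cohens_d <- function(x_npe, x_pe) {
  n1 <- length(x_npe); n2 <- length(x_pe)
  if (n1 < 2 || n2 < 2) stop("cohens_d: need at least 2 values per group")
  sp <- sqrt(((n1 - 1) * stats::var(x_npe) + (n2 - 1) * stats::var(x_pe)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("cohens_d: pooled SD is zero")
  abs(mean(x_pe) - mean(x_npe)) / sp
}

#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen positive (PE) value exceeds a randomly
#' chosen negative (NPE) value, ties counting one half; equivalent to the
#' Mann-Whitney statistic, computed with midranks on all data.
#'
#' @param feature numeric scores
#' @param labels binary labels, PE/1 = positive (accepts 0/1, logical, or
#'   "NPE"/"PE")
#' @return AUC in `[0, 1]`
#' @export
auc_rank <- function(feature, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("auc_rank: both classes must be present")
  r <- rank(feature)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("NPE", "PE"))
    if (length(bad)) stop("labels must be NPE/PE or 0/1; got ", bad[1])
    as.integer(labels == "PE")
  } else {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("labels must be NPE/PE or 0/1")
    y
  }
}

wilson_halfwidth <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  half <- (z / den) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  100 * half
}

confusion_metrics <- function(pred, y) {
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  n <- length(y)
  list(ACC = 100 * (tp + tn) / n,
       CI = wilson_halfwidth(tp + tn, n),
       SE = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       SP = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Supervised single-feature evaluation by repeated holdout
#'
#' Emulates a small-cohort supervised protocol: in each repeat one patient
#' per class is held out, a logistic regression is fitted by maximum
#' likelihood on the remaining training set (with an internal stratified
#' 2-fold cross-validation recorded as a sanity metric), and accuracy,
#' Wilson 95% CI half-width, sensitivity and specificity are computed on the
#' pooled train+test predictions at probability threshold 0.5. Reported
#' metrics are means over the repeats; PE is the positive class.
#'
#' @param feature numeric vector, or a data.frame/matrix of feature columns
#'   for a feature pair
#' @param labels binary labels (PE positive)
#' @param config list with `n_repeats` (default 5), `holdout_size` (default
#'   2), `cv_folds` (default 2), `seed` (default 1)
#' @return list with `ACC`, `CI`, `SE`, `SP` (percent, means over repeats)
#'   and `cv_accuracy` (mean inner-CV accuracy)
#' @export
supervised_eval <- function(feature, labels, config = list()) {
  cfg <- utils::modifyList(list(n_repeats = 5L, holdout_size = 2L,
                                cv_folds = 2L, seed = 1L), config)
  X <- if (is.null(dim(feature))) data.frame(x1 = feature) else as.data.frame(feature)
  names(X) <- paste0("x", seq_along(X))
  y <- as_binary_labels(labels)
  n <- length(y)
  if (cfg$holdout_size >= n) stop("supervised_eval: holdout_size must be < n")
  if (length(unique(y)) < 2) stop("supervised_eval: both classes must be present")
  if (n < 6) stop("supervised_eval: need n >= 6")
  dat <- cbind(X, y = y)
  fit_predict <- function(train_idx) {
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = dat[train_idx, , drop = FALSE]))
    as.integer(suppressWarnings(
      stats::predict(fit, newdata = dat, type = "response")) >= 0.5)
  }
  out <- withr_seed(cfg$seed, {
    res <- matrix(NA_real_, cfg$n_repeats, 4,
                  dimnames = list(NULL, c("ACC", "CI", "SE", "SP")))
    cvacc <- numeric(cfg$n_repeats)
    for (r in seq_len(cfg$n_repeats)) {
      for (attempt in 1:100) {
        hold <- if (cfg$holdout_size == 2L)
          c(sample(which(y == 0), 1), sample(which(y == 1), 1))
        else sample(n, cfg$holdout_size)
        train <- setdiff(seq_len(n), hold)
        if (length(unique(y[train])) == 2) break
        message("supervised_eval: resampled a single-class training fold")
      }
      pred <- fit_predict(train)
      m <- confusion_metrics(pred, y)
      res[r, ] <- c(m$ACC, m$CI, m$SE, m$SP)
      # inner stratified 2-fold CV on the training set, recorded for sanity
      folds <- integer(n); folds[train] <- 0L
      for (cls in 0:1) {
        idx <- sample(intersect(train, which(y == cls)))
        folds[idx] <- rep(seq_len(cfg$cv_folds), length.out = length(idx))
      }
      hits <- 0L
      for (k in seq_len(cfg$cv_folds)) {
        tr <- train[folds[train] != k]; te <- train[folds[train] == k]
        if (length(unique(y[tr])) < 2 || !length(te)) next
        hits <- hits + sum(fit_predict(tr)[te] == y[te])
      }
      cvacc[r] <- 100 * hits / length(train)
    }
    list(res = res, cvacc = cvacc)
  })
  m <- colMeans(out$res)
  list(ACC = m[["ACC"]], CI = m[["CI"]], SE = m[["SE"]], SP = m[["SP"]],
       cv_accuracy = mean(out$cvacc))
}

#' Exact one-dimensional 2-means clustering
#'
#' Minimises the k-means (within-cluster sum of squares) objective exactly:
#' in one dimension every optimal 2-partition is a split of the sorted
#' values, so the optimum is found by scanning all n-1 splits with prefix
#' sums. Deterministic, no initialisation sensitivity.
#'
#' @param x numeric vector with at least 2 distinct values
#' @return list: `cluster` (1 = lower, 2 = upper, in input order), `centers`
#'   (sorted ascending), `wcss`
#' @export
kmeans_1d <- function(x) {
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2)
    stop("kmeans_1d: need at least 2 distinct values")
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  wcss <- ss_left + ss_right
  kbest <- which.min(wcss)
  cl_sorted <- rep(1L, n); cl_sorted[(kbest + 1):n] <- 2L
  cluster <- integer(n); cluster[o] <- cl_sorted
  centers <- c(cs[kbest] / kbest, (cs[n] - cs[kbest]) / (n - kbest))
  list(cluster = cluster, centers = centers, wcss = wcss[kbest])
}

#' Unsupervised single-feature evaluation via k-means
#'
#' Clusters the standardized feature into two groups with exact 1-D k-means,
#' maps each cluster to a label by majority vote (ties resolved by taking
#' the higher-mean cluster as PE, consistent with elevated indices in
#' disease), and reports confusion-matrix metrics in percent.
#'
#' @param feature numeric vector
#' @param labels binary labels (PE positive)
#' @return list with `ACC`, `CI`, `SE`, `SP`, `threshold` (midpoint of the
#'   two centroids on the original scale), `cluster`
#' @export
unsupervised_eval <- function(feature, labels) {
  y <- as_binary_labels(labels)
  z <- (feature - mean(feature)) / stats::sd(feature)
  km <- kmeans_1d(z)
  map <- integer(2)
  for (j in 1:2) {
    yy <- y[km$cluster == j]
    map[j] <- if (!length(yy)) NA_integer_
      else if (mean(yy) > 0.5) 1L
      else if (mean(yy) < 0.5) 0L
      else if (j == 2L) 1L else 0L   # tie: higher-mean cluster = PE
  }
  pred <- map[km$cluster]
  m <- confusion_metrics(pred, y)
  m$threshold <- threshold_select(feature)
  m$cluster <- km$cluster
  m
}

#' Unsupervised decision threshold
#'
#' The midpoint of the two 1-D k-means centroids of the raw feature — the
#' decision boundary of the 2-means partition (equivariant under affine
#' transforms of the feature).
#'
#' @param feature numeric vector with at least 2 distinct values
#' @return the threshold
#' @export
threshold_select <- function(feature) {
  km <- kmeans_1d(feature)
  mean(km$centers)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the ROC AUCs of two features measured on the
#' same patients, using DeLong's structural components; two-sided p-value.
#'
#' @param feature_1,feature_2 paired numeric scores
#' @param labels binary labels (PE positive)
#' @return list with `auc1`, `auc2`, `z`, `p`
#' @export
delong_test <- function(feature_1, feature_2, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("delong_test: both classes must be present")
  if (length(feature_1) != length(y) || length(feature_2) != length(y))
    stop("delong_test: features and labels must have equal length")
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  comp <- function(x) {
    xp <- x[pos]; xn <- x[neg]
    psi <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  c1 <- comp(feature_1); c2 <- comp(feature_2)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- c1$auc - c2$auc
  if (v <= .Machine$double.eps) {
    if (abs(d) > 1e-12)
      warning("delong_test: zero variance with nonzero AUC difference")
    return(list(auc1 = c1$auc, auc2 = c2$auc, z = 0, p = 1))
  }
  z <- d / sqrt(v)
  list(auc1 = c1$auc, auc2 = c2$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sample size for a two-sample t-test
#'
#' Smallest integer n per group (equal sizes) such that a two-sample t-test
#' with effect size `d` attains the requested power, using the noncentral-t
#' power function (noncentrality `d * sqrt(n/2)`, df `2n - 2`).
#'
#' @param alpha significance level
#' @param power target power
#' @param effect_size_d standardized effect size, > 0
#' @param tails 1 or 2
#' @param n_max search cap
#' @return n per group (integer)
#' @export
#' @examples
#' power_sample_size(alpha = 0.1, power = 0.8, effect_size_d = 1, tails = 1)  # 10
power_sample_size <- function(alpha, power, effect_size_d, tails = 1L,
                              n_max = 10000L) {
  if (!(alpha > 0 && alpha < 1)) stop("power_sample_size: alpha must be in (0,1)")
  if (!(power > 0 && power < 1)) stop("power_sample_size: power must be in (0,1)")
  if (!(effect_size_d > 0)) stop("power_sample_size: effect size must be > 0")
  if (power <= alpha) stop("power_sample_size: infeasible (power <= alpha)")
  if (!tails %in% c(1L, 2L)) stop("power_sample_size: tails must be 1 or 2")
  a <- if (tails == 1L) alpha else alpha / 2
  for (n in 2:n_max) {
    df <- 2 * n - 2
    ncp <- effect_size_d * sqrt(n / 2)
    pw <- 1 - stats::pt(stats::qt(1 - a, df), df, ncp)
    if (tails == 2L) pw <- pw + stats::pt(stats::qt(a, df), df, ncp)
    if (pw >= power) return(n)
  }
  stop("power_sample_size: no n <= n_max attains the requested power")
}

#' Min-max normalisation to [0, 1]
#'
#' @param feature numeric vector with at least 2 distinct values
#' @return `(x - min)/(max - min)`
#' @export
normalize01 <- function(feature) {
  rng <- range(feature)
  if (rng[1] == rng[2]) stop("normalize01: feature is constant")
  (feature - rng[1]) / (rng[2] - rng[1])
}

#' Per-feature classification report
#'
#' Applies the full single-feature evaluation battery — Welch t-test p,
#' Cohen's d, supervised repeated-holdout logistic regression metrics, ROC
#' AUC on all data, unsupervised k-means metrics and the k-means decision
#' threshold — to every feature column of a feature matrix.
#'
#' @param features data frame of feature columns (numeric)
#' @param labels binary labels (PE positive)
#' @param config supervised evaluation config, see [supervised_eval()]
#' @return a data.frame, one row per feature
#' @export
feature_report <- function(features, labels, config = list()) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("feature_report: both classes must be present")
  rows <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    sup <- supervised_eval(x, y, config)
    uns <- unsupervised_eval(x, y)
    data.frame(feature = nm,
               p_ttest = welch_p(x[y == 0], x[y == 1]),
               cohens_d = cohens_d(x[y == 0], x[y == 1]),
               sup_ACC = sup$ACC, sup_CI = sup$CI, sup_SE = sup$SE,
               sup_SP = sup$SP, AUC = auc_rank(x, y),
               uns_ACC = uns$ACC, uns_CI = uns$CI, uns_SE = uns$SE,
               uns_SP = uns$SP, threshold = uns$threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
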