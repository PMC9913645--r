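test_that("confusion counts partition samples with ties counted positive", {
  cc <- confusion_counts(c(0.9, 0.4), c(1, 0), 0.5)
  expect_equal(cc, list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  ## score exactly at threshold is predicted positive
  cc2 <- confusion_counts(c(0.5, 0.5), c(1, 0), 0.5)
  expect_equal(cc2$TP, 1L)
  expect_equal(cc2$FP, 1L)
  ## perfect scores
  cc3 <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(cc3$FP + cc3$FN, 0L)
  expect_error(confusion_counts(numeric(0), numeric(0)), "non-empty")
})

test_that("ACC/SEN/SPEC follow their definitions, with NaN for empty classes", {
  m <- classification_metrics(list(TP = 8, FN = 1, TN = 8, FP = 1))
  expect_equal(unname(m), rep(16 / 18, 3), tolerance = 1e-12)
  expect_warning(m0 <- classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1)),
                 "NaN")
  expect_true(is.nan(m0["SEN"]))
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               "no samples")
  mall <- suppressWarnings(classification_metrics(list(TP = 5, FN = 0, TN = 0, FP = 0)))
  expect_equal(unname(mall[c("ACC", "SEN")]), c(1, 1))
})

test_that("AUC equals the tie-corrected concordance probability", {
  ## perfect separation
  expect_equal(auc_score(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  ## null: scores independent of labels
  set.seed(1)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.5)
  expect_lt(abs(auc_score(s, l) - 0.5), 0.03)
  ## 200 random instances vs the O(n^2) pairwise oracle, with ties
  concordance <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(6:30, 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_score(s, l), concordance(s, l), tolerance = 1e-10)
  }
})

test_that("ROC endpoints and monotone-transform invariance hold", {
  set.seed(3)
  s <- runif(50); l <- rbinom(50, 1, 0.4)
  rc <- roc_curve(s, l)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[length(rc$fpr)], 1)
  expect_equal(rc$tpr[length(rc$tpr)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(auc_score(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), l),
               auc_score(s, l), tolerance = 1e-12)
})

test_that("decision curve analysis has its closed-form anchors", {
  set.seed(4)
  l <- rbinom(200, 1, 0.3)
  s <- runif(200)
  dca <- decision_curve(s, l)
  ## treat-none is identically zero
  expect_true(all(dca$none == 0))
  ## treat-all crosses zero exactly at the prevalence
  prev <- mean(l)
  nb_all_at_prev <- prev - (1 - prev) * prev / (1 - prev)
  expect_equal(nb_all_at_prev, 0)
  k <- which.min(abs(dca$threshold - prev))
  expect_lt(abs(dca$all[k]), 0.02)
  ## model never beats prevalence
  expect_true(all(dca$model <= prev + 1e-12))
  ## below every score, model == treat-all
  s2 <- 0.5 + 0.4 * l + runif(200, 0, 0.05)
  dca2 <- decision_curve(s2, l)
  low <- dca2$threshold < min(s2)
  expect_equal(dca2$model[low], dca2$all[low])
  ## perfect classifier attains net benefit == prevalence below the score gap
  sp <- ifelse(l == 1, 0.9, 0.1)
  dcap <- decision_curve(sp, l)
  mid <- dcap$threshold > 0.1 & dcap$threshold <= 0.9
  expect_true(all(abs(dcap$model[mid] - prev) < 1e-12))
  expect_error(decision_curve(s, l, thresholds = c(0, 0.5)), "inside")
})

test_that("Mann-Whitney U reproduces exact and null results", {
  ## complete separation, n = 5 vs 5: U = 25, exact p = 2/252
  r <- mann_whitney_u(c(6, 7, 8, 9, 10), c(1, 2, 3, 4, 5))
  expect_equal(r$U, 25)
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)
  ## identical samples: p near 1
  set.seed(5)
  x <- rnorm(30)
  r2 <- mann_whitney_u(x, x)
  expect_gt(r2$p, 0.9)
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  perm_p <- function(x, y) {
    nx <- length(x)
    pool <- c(x, y)
    U_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    combs <- combn(length(pool), nx)
    Us <- apply(combs, 2, function(ii) {
      xs <- pool[ii]; ys <- pool[-ii]
      sum(outer(xs, ys, ">"))
    })
    mu <- nx * length(y) / 2
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  set.seed(6)
  for (rep in 1:5) {
    x <- round(rnorm(5), 2); y <- round(rnorm(4) + 0.3, 2)
    if (anyDuplicated(c(x, y))) next
    r <- mann_whitney_u(x, y)
    expect_equal(r$p, perm_p(x, y), tolerance = 1e-10)
  }
})

test_that("patient-level aggregation averages each patient's image scores", {
  pid <- c("a", "a", "b", "c", "c", "c")
  sc <- c(0.2, 0.4, 0.9, 0.1, 0.2, 0.3)
  lab <- c(0, 0, 1, 0, 0, 0)
  ps <- patient_scores(sc, pid, lab)
  expect_equal(ps$score[ps$patient_id == "a"], 0.3)
  expect_equal(ps$score[ps$patient_id == "c"], 0.2)
  expect_equal(ps$label, c(0L, 1L, 0L))
  expect_error(patient_scores(sc, pid[-1]), "mismatch")
})
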