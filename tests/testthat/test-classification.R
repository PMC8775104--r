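noise_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("R", seq_len(p))))
}

test_that("a strongly separated region is selected first", {
  x <- noise_matrix(80, 10, seed = 4)
  lab <- rep(c(FALSE, TRUE), each = 40)
  x[lab, "R7"] <- x[lab, "R7"] + 3  # 3-SD separation
  mod <- stepwise_train(x, lab)
  expect_equal(mod$selected[1], "R7")
  expect_equal(unname(mod$signs["R7"]), "up")
  # predicted labels recover the structure
  pred <- predict(mod, x)
  expect_gt(mean((pred == "positive") == lab), 0.9)
})

test_that("degenerate inputs give an empty majority-class model", {
  x <- matrix(rep(c(1, 2, 3), 10), nrow = 10, ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  lab <- rep(c(FALSE, TRUE), 5)
  mod <- stepwise_train(x, c(rep(FALSE, 6), rep(TRUE, 4)))
  expect_length(mod$selected, 0)
  expect_equal(unique(as.character(predict(mod, x))), "negative")
  # pure noise with small n admits no region at p_enter = 1e-6
  xn <- noise_matrix(20, 5, seed = 8)
  modn <- stepwise_train(xn, rep(c(FALSE, TRUE), each = 10), p_enter = 1e-6)
  expect_length(modn$selected, 0)
})

test_that("sign table agrees with group-mean differences", {
  x <- noise_matrix(100, 6, seed = 5)
  lab <- rep(c(FALSE, TRUE), each = 50)
  x[lab, "R2"] <- x[lab, "R2"] + 2
  x[lab, "R5"] <- x[lab, "R5"] - 2
  mod <- stepwise_train(x, lab)
  expect_true(all(c("R2", "R5") %in% mod$selected))
  for (v in mod$selected) {
    md <- mean(x[lab, v]) - mean(x[!lab, v])
    expect_equal(unname(mod$signs[v]), if (md > 0) "up" else "down")
  }
})

test_that("jackknife reaches 100% on perfectly separated toy data", {
  x <- noise_matrix(40, 4, seed = 6)
  lab <- rep(c(FALSE, TRUE), each = 20)
  x[lab, "R1"] <- x[lab, "R1"] + 12
  rep_ <- jackknife_evaluate(x, lab, protocol = "refit")
  expect_equal(rep_$pct_neg, 100)
  expect_equal(rep_$pct_pos, 100)
  expect_equal(unname(rep_$counts), c(20L, 0L, 0L, 20L))
  # fixed protocol agrees here
  repf <- jackknife_evaluate(x, lab, protocol = "fixed")
  expect_equal(repf$pct_pos, 100)
})

test_that("report percentages and combined counts follow the confusion table", {
  truth <- c(rep("negative", 53), rep("positive", 47))
  pred <- c(rep("negative", 45), rep("positive", 8),
            rep("negative", 12), rep("positive", 35))
  rep_ <- classification_report(truth, pred)
  expect_equal(unname(rep_$counts), c(45L, 8L, 12L, 35L))
  expect_equal(round(rep_$pct_neg, 1), 84.9)
  expect_equal(round(rep_$pct_pos, 1), 74.5)
  expect_equal(rep_$right, 80)
  expect_equal(rep_$wrong, 20)
})

test_that("binomial tail matches exact enumeration and is monotone in k", {
  # brute-force enumeration oracle over all 2^n outcomes
  enum_tail <- function(k, n) {
    heads <- rowSums(expand.grid(rep(list(0:1), n)))
    mean(heads >= k)
  }
  for (n in c(5, 8, 10)) {
    for (k in 0:n) {
      expect_equal(binomial_tail_p(k, n), enum_tail(k, n), tolerance = 1e-12)
    }
  }
  expect_equal(binomial_tail_p(5, 10), 0.623046875)
  expect_equal(binomial_tail_p(10, 10), 0.5^10)
  p <- vapply(0:53, binomial_tail_p, 0, n = 53)
  expect_true(all(diff(p) < 0))
  expect_lt(binomial_tail_p(45, 53), 1e-6)
})

test_that("chi-square p-values match the goodness-of-fit oracle", {
  # observed equal to expected: p = 1
  expect_equal(chisq_p(c(25, 25), 1)$p, 1)
  # (45 correct, 8 wrong) against (26.5, 26.5)
  res <- chisq_p(c(45, 8), 1)
  expect_equal(res$statistic, (45 - 26.5)^2 / 26.5 + (8 - 26.5)^2 / 26.5)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_lt(res$p, 1e-6)
  # combined df = 2 statistic for the full confusion table
  comb <- chisq_p(c(45, 8, 12, 35), 2)
  expect_lt(comb$p, 1e-7)
  expect_error(chisq_p(c(0, 0), 1), "zero expected")
})

test_that("planted symptom regions are recovered with high jackknife accuracy", {
  x <- noise_matrix(120, 16, seed = 10)
  lab <- rep(c(FALSE, TRUE), each = 60)
  planted <- paste0("R", c(2, 5, 9, 13))
  for (v in planted) x[lab, v] <- x[lab, v] + 1.5
  rep_ <- jackknife_evaluate(x, lab, protocol = "refit")
  expect_gt(rep_$pct_neg, 75)
  expect_gt(rep_$pct_pos, 75)
  expect_gte(mean(planted %in% rep_$selected), 0.5)
})

test_that("permuted labels give chance accuracy", {
  x <- noise_matrix(60, 10, seed = 11)
  lab <- rep(c(FALSE, TRUE), each = 30)
  accs <- vapply(1:5, function(i) {
    set.seed(100 + i)
    rp <- jackknife_evaluate(x, sample(lab), protocol = "refit")
    rp$right / (rp$right + rp$wrong)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("grouped jackknife leaves whole subjects out", {
  x <- noise_matrix(40, 5, seed = 12)
  lab <- rep(c(FALSE, TRUE), each = 20)
  x[lab, "R3"] <- x[lab, "R3"] + 8
  groups <- rep(1:20, each = 2)  # two rows (sessions) per subject
  rep_ <- jackknife_evaluate(x, lab, protocol = "refit", groups = groups)
  expect_equal(rep_$right + rep_$wrong, 40)
  expect_gt(rep_$pct_pos, 90)
})

test_that("exclusion rounds use disjoint selections and degrade gracefully", {
  x <- noise_matrix(100, 12, seed = 13)
  lab <- rep(c(FALSE, TRUE), each = 50)
  # correlated informative twins: stepwise keeps one representative per
  # cluster, so excluded-region reruns still find signal in the twin —
  # the mechanism behind multi-round cohort separations
  set.seed(99)
  shared <- matrix(rnorm(100 * 3), 100, 3)
  for (k in 1:3) {
    twin_a <- paste0("R", k)
    twin_b <- paste0("R", k + 3)
    x[, twin_a] <- shared[, k] + 0.3 * rnorm(100)
    x[, twin_b] <- shared[, k] + 0.3 * rnorm(100)
    x[lab, c(twin_a, twin_b)] <- x[lab, c(twin_a, twin_b)] + 2.5 - 0.5 * k
  }
  rounds <- cohort_classify_with_exclusion(x, lab, n_rounds = 3,
                                           protocol = "fixed")
  expect_gte(length(rounds), 2)
  sel1 <- rounds[[1]]$model$selected
  sel2 <- rounds[[2]]$model$selected
  expect_length(intersect(sel1, sel2), 0)
  acc <- vapply(rounds, function(r)
    r$report$right / (r$report$right + r$report$wrong), 0)
  # the strongest regions go first; later rounds cannot do better than the
  # first by more than noise
  expect_gte(acc[1] + 0.1, max(acc))
})

test_that("single informative region leaves round 2 at chance", {
  x <- noise_matrix(80, 8, seed = 14)
  lab <- rep(c(FALSE, TRUE), each = 40)
  x[lab, "R4"] <- x[lab, "R4"] + 6
  rounds <- cohort_classify_with_exclusion(x, lab, n_rounds = 2,
                                           protocol = "fixed")
  acc1 <- rounds[[1]]$report$right /
    (rounds[[1]]$report$right + rounds[[1]]$report$wrong)
  expect_gt(acc1, 0.95)
  if (length(rounds) >= 2) {
    acc2 <- rounds[[2]]$report$right /
      (rounds[[2]]$report$right + rounds[[2]]$report$wrong)
    expect_lt(acc2, 0.75)
  }
})
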