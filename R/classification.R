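# Stepwise linear discriminant classification of symptom presence/absence
# from regional z-scores, with jackknifed accuracies and exact p-values.

norm_labels <- function(labels) {
  if (is.logical(labels))
    labels <- ifelse(labels, "positive", "negative")
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes")
  if (all(c("negative", "positive") %in% levels(f)))
    f <- factor(f, levels = c("negative", "positive"))
  f
}

# Wilks' lambda det(W)/det(T) for the column subset `cols`
wilks_lambda <- function(x, f, cols) {
  xs <- x[, cols, drop = FALSE]
  m <- colMeans(xs)
  tot <- crossprod(sweep(xs, 2, m))
  w <- matrix(0, length(cols), length(cols))
  for (lev in levels(f)) {
    xg <- xs[f == lev, , drop = FALSE]
    w <- w + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  dT <- det(tot)
  dW <- det(w)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  max(min(dW / dT, 1), 0)
}

# partial F for the change old-model (q vars) -> new-model (q+1 vars);
# lambda_ratio = lambda_new / lambda_old, df = (g-1, n-g-q) with g = 2
partial_f <- function(lambda_ratio, n, q) {
  if (!is.finite(lambda_ratio) || lambda_ratio <= 0) return(c(NA, NA))
  df2 <- n - 2 - q
  if (df2 < 1) return(c(NA, NA))
  f <- (1 - lambda_ratio) / lambda_ratio * df2
  c(f, stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Stepwise linear discriminant classifier
#'
#' Forward selection with removal on Wilks'-lambda partial F-tests: at each
#' step the candidate region with the largest partial F enters if its
#' p-value is below `p_enter` (ties break to the lowest region id); any
#' included region whose partial p rises above `p_remove` is removed; the
#' loop stops when no change occurs. The final model is a two-class linear
#' discriminant (equal priors) over the selected regions. When no region
#' passes entry the model is empty and predicts the majority class.
#'
#' @param x numeric matrix, observations x regions; column names are region
#'   ids.
#' @param labels two-class labels (logical means positive/negative).
#' @param p_enter,p_remove stepwise thresholds (defaults 0.05 / 0.10).
#' @param max_steps safety bound on selection iterations.
#' @return An object of class `stepwise_lda`: `selected` (ordered column
#'   names), `fit` (the `lda` fit, or NULL), `signs` (named `"up"`/`"down"`:
#'   higher/lower group mean in positives), `weights`, `majority`, `levels`.
#' @export
stepwise_train <- function(x, labels, p_enter = 0.05, p_remove = 0.10,
                           max_steps = 200) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  f <- norm_labels(labels)
  if (min(table(f)) < 2) stop("need at least 2 observations per class")
  if (anyNA(x)) stop("missing values in the feature matrix")
  n <- nrow(x)
  selected <- character(0)
  lambda_cur <- 1
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    candidates <- setdiff(colnames(x), selected)
    if (length(candidates) && (n - 2 - length(selected)) >= 1) {
      best <- NULL
      for (v in candidates) {
        lam <- wilks_lambda(x, f, c(selected, v))
        fp <- partial_f(lam / lambda_cur, n, length(selected))
        if (is.na(fp[1])) next
        if (is.null(best) || fp[1] > best$f + 1e-12) {
          best <- list(v = v, f = fp[1], p = fp[2], lambda = lam)
        }
      }
      if (!is.null(best) && best$p < p_enter) {
        selected <- c(selected, best$v)
        lambda_cur <- best$lambda
        changed <- TRUE
      }
    }
    repeat {
      if (length(selected) < 1) break
      worst <- NULL
      for (v in selected) {
        rest <- setdiff(selected, v)
        lam_rest <- if (length(rest)) wilks_lambda(x, f, rest) else 1
        fp <- partial_f(lambda_cur / lam_rest, n, length(rest))
        if (is.na(fp[1])) next
        if (is.null(worst) || fp[2] > worst$p)
          worst <- list(v = v, p = fp[2], lam_rest = lam_rest)
      }
      if (!is.null(worst) && worst$p > p_remove) {
        selected <- setdiff(selected, worst$v)
        lambda_cur <- worst$lam_rest
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  model <- list(selected = selected, fit = NULL, signs = character(0),
                weights = NULL, majority = names(which.max(table(f))),
                levels = levels(f))
  if (length(selected)) {
    model$fit <- MASS::lda(x[, selected, drop = FALSE], grouping = f,
                           prior = c(0.5, 0.5))
    pos <- f == levels(f)[2]
    md <- colMeans(x[pos, selected, drop = FALSE]) -
      colMeans(x[!pos, selected, drop = FALSE])
    model$signs <- stats::setNames(ifelse(md > 0, "up", "down"), selected)
    model$weights <- model$fit$scaling[, 1]
  }
  structure(model, class = "stepwise_lda")
}

#' @export
predict.stepwise_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (length(object$selected) == 0)
    return(factor(rep(object$majority, nrow(newdata)),
                  levels = object$levels))
  stats::predict(object$fit,
                 newdata[, object$selected, drop = FALSE])$class
}

#' @export
print.stepwise_lda <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("stepwise_lda: empty model (predicts majority class '",
        x$majority, "')\n", sep = "")
  } else {
    cat("stepwise_lda:", length(x$selected), "regions selected\n")
    print(data.frame(region = x$selected, weight = unname(x$weights),
                     sign = unname(x$signs[x$selected])))
  }
  invisible(x)
}

#' Exact binomial tail probability for classification accuracy
#'
#' The probability of at least `k` successes in `n` fair coin flips:
#' `sum_{i=k..n} C(n, i) 0.5^n` — the chance that a no-information
#' classifier would do at least this well on one class.
#'
#' @param k number correct (0 <= k <= n).
#' @param n class size.
#' @return Probability.
#' @export
binomial_tail_p <- function(k, n) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (k == 0) return(1)
  sum(exp(lchoose(n, k:n) - n * log(2)))
}

#' Chi-square p-value for classification counts under the fair null
#'
#' Goodness-of-fit chi-square against the fair-classification null (half
#' right, half wrong per class). With `df = 1`, `counts` is `(correct,
#' wrong)` for one class; with `df = 2`, `counts` is the full confusion
#' `(neg_correct, neg_wrong, pos_wrong, pos_correct)` and the expectation
#' splits each class's row total in half.
#'
#' @param counts integer vector of length 2 (`df = 1`) or 4 (`df = 2`).
#' @param df degrees of freedom, 1 or 2.
#' @return A list with `statistic` and `p`.
#' @export
chisq_p <- function(counts, df) {
  stopifnot(df %in% c(1, 2))
  if (df == 1) {
    stopifnot(length(counts) == 2)
    expected <- rep(sum(counts) / 2, 2)
  } else {
    stopifnot(length(counts) == 4)
    expected <- c(rep(sum(counts[1:2]) / 2, 2), rep(sum(counts[3:4]) / 2, 2))
  }
  if (any(expected == 0)) stop("zero expected count")
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Confusion counts, percentages and p-values from jackknifed predictions
#'
#' @param truth,predicted two-class label vectors of equal length.
#' @return A list of class `classification_report`: confusion counts
#'   (`neg_neg, neg_pos, pos_neg, pos_pos`), per-class percentages,
#'   per-class chi-square (df = 1) and exact binomial p-values, combined
#'   right/wrong counts with the df = 2 chi-square p-value and the combined
#'   binomial p.
#' @export
classification_report <- function(truth, predicted) {
  truth <- norm_labels(truth)
  predicted <- factor(predicted, levels = levels(truth))
  neg <- levels(truth)[1]; pos <- levels(truth)[2]
  nn <- sum(truth == neg & predicted == neg)
  np <- sum(truth == neg & predicted == pos)
  pn <- sum(truth == pos & predicted == neg)
  pp <- sum(truth == pos & predicted == pos)
  pct_neg <- if (nn + np > 0) 100 * nn / (nn + np) else NA_real_
  pct_pos <- if (pn + pp > 0) 100 * pp / (pn + pp) else NA_real_
  chisq_neg <- if (nn + np > 0) chisq_p(c(nn, np), 1)$p else NA_real_
  chisq_pos <- if (pn + pp > 0) chisq_p(c(pp, pn), 1)$p else NA_real_
  chisq_comb <- if (nn + np > 0 && pn + pp > 0)
    chisq_p(c(nn, np, pn, pp), 2)$p else NA_real_
  structure(list(
    counts = c(neg_neg = nn, neg_pos = np, pos_neg = pn, pos_pos = pp),
    pct_neg = pct_neg, pct_pos = pct_pos,
    p_neg_chisq = chisq_neg, p_pos_chisq = chisq_pos,
    p_neg_binom = if (nn + np > 0) binomial_tail_p(nn, nn + np) else NA_real_,
    p_pos_binom = if (pn + pp > 0) binomial_tail_p(pp, pn + pp) else NA_real_,
    right = nn + pp, wrong = np + pn,
    p_combined_chisq = chisq_comb,
    p_combined_binom = binomial_tail_p(nn + pp, nn + np + pn + pp)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("            classified neg  classified pos  percentage\n"))
  cat(sprintf("true neg    %14d  %14d  %9.1f%%  (p < %.2g)\n",
              x$counts["neg_neg"], x$counts["neg_pos"], x$pct_neg,
              x$p_neg_chisq))
  cat(sprintf("true pos    %14d  %14d  %9.1f%%  (p < %.2g)\n",
              x$counts["pos_neg"], x$counts["pos_pos"], x$pct_pos,
              x$p_pos_chisq))
  cat(sprintf("right/wrong %d/%d  (chi-square df = 2, p < %.2g)\n",
              x$right, x$wrong, x$p_combined_chisq))
  invisible(x)
}

#' Jackknifed (leave-one-out) classification accuracy
#'
#' Leave-one-out evaluation of the stepwise classifier. Protocol `"refit"`
#' re-runs stepwise selection inside every fold (honest); `"fixed"` selects
#' regions once on all data and refits only the discriminant weights per
#' fold. With `groups` given (e.g. subject ids), folds leave out whole
#' groups instead of single rows. Folds whose training data contain a
#' single class are skipped and counted.
#'
#' @param x observations x regions matrix.
#' @param labels two-class labels.
#' @param protocol `"refit"` or `"fixed"`.
#' @param groups optional fold grouping vector (length `nrow(x)`).
#' @param p_enter,p_remove stepwise thresholds.
#' @return A `classification_report` with extra fields `skipped_folds` and
#'   `selected` (the all-data selection).
#' @export
jackknife_evaluate <- function(x, labels, protocol = c("refit", "fixed"),
                               groups = NULL, p_enter = 0.05,
                               p_remove = 0.10) {
  protocol <- match.arg(protocol)
  x <- as.matrix(x)
  f <- norm_labels(labels)
  groups <- groups %||% seq_len(nrow(x))
  full <- stepwise_train(x, f, p_enter, p_remove)
  # constant fallback for folds whose stepwise selection is empty: the
  # overall base rate, not the fold's majority — a leave-one-out fold's
  # majority is anti-correlated with the held-out label on balanced data
  # and would anti-learn under the null
  base_rate <- names(which.max(table(f)))
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(f))
  skipped <- 0L
  for (g in unique(groups)) {
    hold <- groups == g
    ftr <- f[!hold]
    if (length(unique(ftr)) < 2 || min(table(ftr)) < 2) {
      skipped <- skipped + 1L
      next
    }
    model <- if (protocol == "refit") {
      m <- stepwise_train(x[!hold, , drop = FALSE], ftr, p_enter, p_remove)
      if (length(m$selected) == 0) m$majority <- base_rate
      m
    } else {
      if (length(full$selected) == 0) full
      else {
        m <- full
        m$fit <- MASS::lda(x[!hold, full$selected, drop = FALSE],
                           grouping = ftr, prior = c(0.5, 0.5))
        m
      }
    }
    pred[hold] <- predict(model, x[hold, , drop = FALSE])
  }
  done <- !is.na(pred)
  rep_ <- classification_report(f[done], pred[done])
  rep_$skipped_folds <- skipped
  rep_$selected <- full$selected
  rep_
}

#' Repeated cohort classification with exclusion of selected regions
#'
#' Round 1 uses all regions; each later round excludes every region
#' selected (on the full data) in prior rounds and re-runs training and
#' jackknifed evaluation on the remaining feature pool. Stops early when a
#' round selects nothing or the pool is exhausted.
#'
#' @param x observations x regions matrix.
#' @param labels two-class labels (e.g. cohort membership).
#' @param n_rounds maximum number of rounds (>= 1).
#' @param protocol,groups,p_enter,p_remove passed to [jackknife_evaluate()].
#' @return A list of rounds, each with `model` (full-data `stepwise_lda`),
#'   `report` (jackknifed `classification_report`), and `excluded`.
#' @export
cohort_classify_with_exclusion <- function(x, labels, n_rounds = 3,
                                           protocol = "refit", groups = NULL,
                                           p_enter = 0.05, p_remove = 0.10) {
  stopifnot(n_rounds >= 1)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  excluded <- character(0)
  rounds <- list()
  for (r in seq_len(n_rounds)) {
    pool <- setdiff(colnames(x), excluded)
    if (length(pool) == 0) break
    xr <- x[, pool, drop = FALSE]
    model <- stepwise_train(xr, labels, p_enter, p_remove)
    report <- jackknife_evaluate(xr, labels, protocol = protocol,
                                 groups = groups, p_enter = p_enter,
                                 p_remove = p_remove)
    rounds[[r]] <- list(model = model, report = report, excluded = excluded)
    excluded <- c(excluded, model$selected)
    if (length(model$selected) == 0) break
  }
  rounds
}
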