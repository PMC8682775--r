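# Intermediate (observed vs not-seen) and final (effect vs no-effect) models,
# median-cutoff relabeling, and the evaluation statistics.

#' Hyperparameter grid for model tuning
#'
#' The grid searched when optimising validation F1 for the intermediate and
#' final models. The PUL-stage column/row subsampling is kept.
#'
#' @param trees,max_depth,eta candidate values.
#' @return data.frame of combinations.
#' @export
model_grid <- function(trees = c(100L, 300L), max_depth = c(4L, 6L),
                       eta = c(0.1, 0.3)) {
  expand.grid(trees = trees, max_depth = max_depth, eta = eta,
              KEEP.OUT.ATTRS = FALSE)
}

#' Split a variant set 9 : 0.5 : 0.5 into train/validation/test
#'
#' @param rows integer vector (catalog rows) to split.
#' @param seed integer seed (memberships are deterministic given the seed).
#' @return list `train`, `val`, `test`; a disjoint cover of `rows` with sizes
#'   within rounding of 90% / 5% / 5%.
#' @export
split_9_05_05 <- function(rows, seed = 1L) {
  n <- length(rows)
  if (n < 20L) stop("set too small to split 9:0.5:0.5 (need >= 20)")
  set.seed(seed)
  rows <- sample(rows)
  n_val <- floor(0.05 * n)
  n_test <- floor(0.05 * n)
  n_train <- n - n_val - n_test
  list(train = sort(rows[seq_len(n_train)]),
       val = sort(rows[n_train + seq_len(n_val)]),
       test = sort(rows[n_train + n_val + seq_len(n_test)]))
}

#' Up-sample a minority set with replacement to a target size
#'
#' @param rows integer vector (the minority set).
#' @param n target size (>= length(rows)).
#' @return integer multiset of length `n` with support in `rows`.
#' @export
upsample_to <- function(rows, n) {
  if (length(rows) == 0L) stop("cannot up-sample an empty set")
  stopifnot(n >= length(rows))
  if (n == length(rows)) return(rows)
  rows[sample.int(length(rows), n, replace = TRUE)]
}

# shared trainer: grid-search validation F1, refit kept implicitly (the
# best grid fit is retained), evaluate on the test rows
.train_binary_stage <- function(X, pos, neg, config, grid, stage, seed) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop(stage, ": degenerate single-class split")
  set.seed(seed)
  sp_pos <- split_9_05_05(pos, seed = seed)
  sp_neg <- split_9_05_05(neg, seed = seed + 1L)
  # balance validation and test by down-sampling the majority class
  bal <- function(a, b) {
    m <- min(length(a), length(b))
    list(pos = sort(sample(a, m)), neg = sort(sample(b, m)))
  }
  val <- bal(sp_pos$val, sp_neg$val)
  test <- bal(sp_pos$test, sp_neg$test)
  # balance training by up-sampling the minority class
  n_tr <- max(length(sp_pos$train), length(sp_neg$train))
  tr_pos <- if (length(sp_pos$train) < n_tr)
    upsample_to(sp_pos$train, n_tr) else sp_pos$train
  tr_neg <- if (length(sp_neg$train) < n_tr)
    upsample_to(sp_neg$train, n_tr) else sp_neg$train
  Xtr <- X[c(tr_pos, tr_neg), , drop = FALSE]
  ytr <- c(rep(1, length(tr_pos)), rep(0, length(tr_neg)))
  Xval <- X[c(val$pos, val$neg), , drop = FALSE]
  yval <- c(rep(1, length(val$pos)), rep(0, length(val$neg)))

  best <- NULL
  for (g in seq_len(nrow(grid))) {
    fit <- .fit_xgb(Xtr, ytr, config, seed = seed + g,
                    trees = grid$trees[g], max_depth = grid$max_depth[g],
                    eta = grid$eta[g])
    f1 <- evaluate_counts(score_counts(.xgb_score(fit, Xval), yval))$f1
    if (is.null(best) || (!is.na(f1) && f1 > best$val_f1)) {
      best <- list(model = fit, params = grid[g, , drop = FALSE],
                   val_f1 = f1)
    }
  }
  Xte <- X[c(test$pos, test$neg), , drop = FALSE]
  yte <- c(rep(1, length(test$pos)), rep(0, length(test$neg)))
  counts <- score_counts(.xgb_score(best$model, Xte), yte)
  list(model = best$model, params = best$params, val_f1 = best$val_f1,
       test_counts = counts, test_metrics = evaluate_counts(counts),
       splits = list(pos = sp_pos, neg = sp_neg, val = val, test = test))
}

#' Train the intermediate observed-vs-not-seen model
#'
#' Observed variants are split 9:0.5:0.5; not-seen validation/test sets are
#' down-sampled to the observed validation/test sizes; training is balanced
#' by up-sampling the smaller class. Hyperparameters are tuned by maximising
#' validation F1 over the declared grid (positive class: not-seen).
#'
#' @param X encoded feature matrix (catalog rows).
#' @param observed_rows,not_seen_rows catalog rows entering training (common
#'   excluded and curated-effect variants must already be removed).
#' @param config `synev_pul_config` (supplies subsampling and threads).
#' @param grid hyperparameter grid ([model_grid()]).
#' @param seed integer seed.
#' @return list with `model`, `params`, `val_f1`, `test_counts`,
#'   `test_metrics`, `splits`.
#' @export
train_intermediate <- function(X, observed_rows, not_seen_rows,
                               config = pul_config(), grid = model_grid(),
                               seed = config$seed) {
  .train_binary_stage(X, pos = not_seen_rows, neg = observed_rows, config,
                      grid, stage = "intermediate", seed = seed)
}

#' Derive the effect / no-effect relabeling cutoffs
#'
#' The lower cutoff is the median intermediate-model score of the excluded
#' common variants (assumed depleted in effect); the upper cutoff is the
#' median score of the curated-effect variants. Even-sized sets use the
#' mean-of-middle-two median.
#'
#' @param common_scores intermediate scores of the excluded common sSNVs.
#' @param curated_scores intermediate scores of the curated-effect sSNVs.
#' @return named numeric vector `c(c_lo=, c_hi=)`; error if `c_lo >= c_hi`
#'   (relabeling impossible).
#' @export
derive_cutoffs <- function(common_scores, curated_scores) {
  stopifnot(length(common_scores) > 0L, length(curated_scores) > 0L)
  c_lo <- median(common_scores)
  c_hi <- median(curated_scores)
  if (c_lo >= c_hi)
    stop("no-effect cutoff (", signif(c_lo, 3),
         ") is not below effect cutoff (", signif(c_hi, 3),
         "); effect labeling impossible")
  c(c_lo = c_lo, c_hi = c_hi)
}

#' Relabel variants by intermediate score
#'
#' Scores strictly below `c_lo` become `no_effect`, strictly above `c_hi`
#' become `effect`; everything in between (including ties with either
#' cutoff) stays `unlabeled` and is dropped from final-model training while
#' still being scored at prediction time.
#'
#' @param scores numeric vector of intermediate-model scores.
#' @param c_lo,c_hi cutoffs from [derive_cutoffs()] (`c_lo < c_hi`).
#' @return character vector in `{"no_effect", "unlabeled", "effect"}`.
#' @export
label_effect <- function(scores, c_lo, c_hi) {
  stopifnot(c_lo < c_hi)
  out <- rep("unlabeled", length(scores))
  out[scores < c_lo] <- "no_effect"
  out[scores > c_hi] <- "effect"
  out
}

#' Train the final effect model
#'
#' Same split/balancing/tuning scheme as the intermediate model, with
#' effect as the positive class; emits scores in [0, 1] with the binary call
#' at 0.5 (scores exactly at 0.5 are called effect).
#'
#' @param X encoded feature matrix.
#' @param effect_rows,no_effect_rows catalog rows labelled by
#'   [label_effect()].
#' @inheritParams train_intermediate
#' @return list as for [train_intermediate()].
#' @export
train_final <- function(X, effect_rows, no_effect_rows,
                        config = pul_config(), grid = model_grid(),
                        seed = config$seed) {
  .train_binary_stage(X, pos = effect_rows, neg = no_effect_rows, config,
                      grid, stage = "final", seed = seed)
}

#' Confusion counts from scores and labels
#' @param scores numeric scores in [0,1].
#' @param labels binary truth (1 = positive class).
#' @param cutoff binary score cutoff; calls at the cutoff are positive.
#' @return named integer vector `c(TP=, TN=, FP=, FN=)`.
#' @export
score_counts <- function(scores, labels, cutoff = 0.5) {
  call <- scores >= cutoff
  c(TP = sum(call & labels == 1), TN = sum(!call & labels == 0),
    FP = sum(call & labels == 0), FN = sum(!call & labels == 1))
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' F1 = 2 * precision * recall / (precision + recall);
#' accuracy = (TP+TN)/(TP+TN+FP+FN). Zero denominators yield NA.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return list `precision`, `recall`, `f1`, `accuracy`.
#' @examples
#' evaluate_counts(c(TP = 9, FP = 1, FN = 3, TN = 7))
#' @export
evaluate_counts <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  acc <- if (tp + tn + fp + fn > 0)
    (tp + tn) / (tp + tn + fp + fn) else NA_real_
  list(precision = prec, recall = rec, f1 = f1, accuracy = acc)
}

#' Fraction of consensus binary predictions
#'
#' The number of variants on which all predictors agree (all 0 or all 1),
#' divided by the number of variants.
#'
#' @param binary_prediction_matrix variants x predictors matrix of 0/1 calls.
#' @return numeric in [0, 1]; a single-predictor matrix returns 1 with a
#'   warning.
#' @export
fcbp <- function(binary_prediction_matrix) {
  m <- as.matrix(binary_prediction_matrix)
  stopifnot(all(m %in% c(0, 1)))
  if (ncol(m) == 1L) {
    warning("FCBP of a single predictor is 1 by definition")
    return(1)
  }
  mean(rowSums(m) %in% c(0L, ncol(m)))
}

#' One-sided permutation test on a difference of means
#'
#' Null hypothesis: mean(group_a) equals mean(group_b); alternative (with
#' `alternative = "less"`): mean(group_a) is lower. The p-value is the
#' plus-one-corrected fraction of label permutations whose mean difference is
#' at least as extreme in the stated direction.
#'
#' @param group_a,group_b numeric vectors.
#' @param n_perm number of permutations.
#' @param alternative "less" or "greater" (direction for mean(a) - mean(b)).
#' @param exact if TRUE and the groups are tiny, enumerate all assignments of
#'   the pooled values to group a (exact test) instead of sampling.
#' @return p-value in (0, 1].
#' @export
permutation_test_one_sided <- function(group_a, group_b, n_perm = 10000L,
                                       alternative = c("less", "greater"),
                                       exact = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) > 0L, length(group_b) > 0L)
  pool <- c(group_a, group_b)
  na <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  stat_of <- function(ia) mean(pool[ia]) - mean(pool[-ia])
  cmp <- if (alternative == "less") function(s) s <= obs else
    function(s) s >= obs
  if (exact) {
    combs <- utils::combn(length(pool), na)
    hits <- sum(apply(combs, 2, function(ia) cmp(stat_of(ia))))
    return(hits / ncol(combs))
  }
  hits <- sum(vapply(seq_len(n_perm), function(i)
    cmp(stat_of(sample.int(length(pool), na))), logical(1)))
  (1 + hits) / (n_perm + 1)
}

#' auROC / auPRC evaluation plumbing
#'
#' Standard curve areas via pROC (not re-derived in this package); provided
#' for comparisons of score sets against binary labels.
#'
#' @param scores numeric scores.
#' @param labels binary truth (1 = positive).
#' @return list `auroc`, `auprc` (auprc by step-interpolated
#'   precision-recall summation).
#' @export
evaluate_scores <- function(scores, labels) {
  if (!requireNamespace("pROC", quietly = TRUE))
    stop("evaluate_scores() needs the pROC package")
  roc <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = as.numeric(pROC::auc(roc)), auprc = auprc)
}
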