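#' Fit the full synonymous-variant effect model
#'
#' Runs the three-stage pipeline on a classified variant catalog and its raw
#' feature table:
#' \enumerate{
#'   \item positive-unlabeled learning splits `generated` variants into
#'     `not_seen` and `unobservable` ([run_pul()]);
#'   \item the intermediate model discriminates observed from not-seen
#'     ([train_intermediate()]); its score medians on a held-out sample of
#'     common variants (MAF > `common_maf`) and on the supplied
#'     curated-effect variants give the relabeling cutoffs
#'     ([derive_cutoffs()], [label_effect()]);
#'   \item the final model discriminates effect from no-effect
#'     ([train_final()]) and scores every non-excluded variant.
#' }
#' Curated-effect and excluded common variants never enter any training set;
#' encoders/scalers are fitted without them. All randomness flows from
#' `seed`.
#'
#' @param catalog classified variant catalog ([classify_status()]).
#' @param features raw 35-slot feature table ([assemble_features()]), rows
#'   aligned with the catalog.
#' @param curated_keys variant keys ([variant_key()]) of the curated-effect
#'   set (experimentally supported effect variants).
#' @param config `synev_pul_config`.
#' @param grid hyperparameter grid ([model_grid()]).
#' @param common_maf MAF threshold defining common variants (default 0.01).
#' @param common_exclude_frac fraction of common variants excluded for cutoff
#'   derivation (default 0.1).
#' @param seed integer seed.
#' @return object of class `synev`; see [predict.synev()],
#'   [summary.synev()], [feature_importance()].
#' @export
synev <- function(catalog, features, curated_keys,
                  config = pul_config(), grid = model_grid(),
                  common_maf = 0.01, common_exclude_frac = 0.1,
                  seed = config$seed) {
  stopifnot(nrow(catalog) == nrow(features))
  set.seed(seed)
  keys <- variant_key(catalog)
  curated_rows <- which(keys %in% curated_keys)
  if (length(curated_rows) == 0L)
    stop("no curated-effect variants found in the catalog")
  common_rows <- which(catalog$status == "observed" &
                         catalog$maf > common_maf)
  n_excl <- max(1L, round(common_exclude_frac * length(common_rows)))
  if (length(common_rows) < 2L)
    stop("no common variants (MAF > ", common_maf, ") to derive cutoffs")
  common_excluded <- sort(sample(common_rows, n_excl))
  eval_rows <- union(curated_rows, common_excluded)

  encoder <- fit_feature_encoder(features,
                                 rows = setdiff(seq_len(nrow(features)),
                                                eval_rows))
  X <- apply_feature_encoder(features, encoder)

  pul <- run_pul(catalog, X, config = config, exclude_rows = eval_rows)
  catalog <- pul$catalog
  usable <- !pul$excluded_flag
  observed_rows <- setdiff(which(catalog$status == "observed" & usable),
                           eval_rows)
  not_seen_rows <- setdiff(which(catalog$status == "not_seen"), eval_rows)

  intermediate <- train_intermediate(X, observed_rows, not_seen_rows,
                                     config = config, grid = grid,
                                     seed = seed + 1000L)
  int_scores <- .xgb_score(intermediate$model, X)
  cutoffs <- derive_cutoffs(int_scores[common_excluded],
                            int_scores[curated_rows])

  label_pool <- setdiff(union(observed_rows, not_seen_rows), eval_rows)
  labels <- rep(NA_character_, nrow(catalog))
  labels[label_pool] <- label_effect(int_scores[label_pool],
                                     cutoffs[["c_lo"]], cutoffs[["c_hi"]])
  effect_rows <- which(!is.na(labels) & labels == "effect")
  no_effect_rows <- which(!is.na(labels) & labels == "no_effect")

  final <- train_final(X, effect_rows, no_effect_rows, config = config,
                       grid = grid, seed = seed + 2000L)
  synev_score <- .xgb_score(final$model, X)

  scores <- data.frame(
    transcript_id = catalog$transcript_id, key = keys,
    synev_score = synev_score,
    binary_call = ifelse(synev_score >= 0.5, "effect", "no_effect"),
    stage_provenance = catalog$status, stringsAsFactors = FALSE)
  scores$binary_call[catalog$status == "unobservable"] <- "unobservable"

  structure(list(catalog = catalog, partition = pul$partition,
                 encoder = encoder, pul = pul, intermediate = intermediate,
                 cutoffs = cutoffs, labels = labels, final = final,
                 scores = scores, curated_rows = curated_rows,
                 common_excluded_rows = common_excluded, config = config,
                 grid = grid, seed = seed),
            class = "synev")
}

#' @export
print.synev <- function(x, ...) {
  cat("synev effect model\n")
  cat("  variants:", nrow(x$catalog), "in",
      length(unique(x$catalog$transcript_id)), "transcripts\n")
  p <- x$partition$sets
  cat("  partition:", paste(sprintf("%s=%d", names(p),
                                    lengths(p)), collapse = ", "), "\n")
  cat(sprintf("  cutoffs: no-effect < %.3f < unlabeled < %.3f < effect\n",
              x$cutoffs[["c_lo"]], x$cutoffs[["c_hi"]]))
  cat(sprintf("  intermediate test F1 = %.3f; final test F1 = %.3f\n",
              x$intermediate$test_metrics$f1, x$final$test_metrics$f1))
  invisible(x)
}

#' Summarise a fitted synev model
#' @param object a `synev` fit.
#' @param ... unused.
#' @return list of class `summary.synev` with partition sizes, PUL trace,
#'   cutoffs, stage test metrics and top features.
#' @export
summary.synev <- function(object, ...) {
  out <- list(
    n_variants = nrow(object$catalog),
    partition = lengths(object$partition$sets),
    pul_epochs = nrow(object$pul$trace),
    pul_heldout_error = object$pul$heldout_error,
    cutoffs = object$cutoffs,
    intermediate = object$intermediate$test_metrics,
    final = object$final$test_metrics,
    top_features = head(feature_importance(object$final$model), 5L))
  class(out) <- "summary.synev"
  out
}

#' @export
print.summary.synev <- function(x, ...) {
  cat("synev fit over", x$n_variants, "variants\n")
  cat("  partition:", paste(sprintf("%s=%d", names(x$partition),
                                    x$partition), collapse = ", "), "\n")
  cat(sprintf("  PUL: %d epoch(s), held-out observed error %.3f\n",
              x$pul_epochs, x$pul_heldout_error))
  cat(sprintf("  cutoffs: c_lo = %.3f, c_hi = %.3f\n",
              x$cutoffs[["c_lo"]], x$cutoffs[["c_hi"]]))
  cat(sprintf("  intermediate test: F1 %.3f, accuracy %.3f\n",
              x$intermediate$f1, x$intermediate$accuracy))
  cat(sprintf("  final test:        F1 %.3f, accuracy %.3f\n",
              x$final$f1, x$final$accuracy))
  cat("  top features:", paste(x$top_features$feature, collapse = ", "),
      "\n")
  invisible(x)
}

#' Score new variants with a fitted synev model
#'
#' @param object a `synev` fit.
#' @param newdata raw feature table for the new variants
#'   ([assemble_features()]); defaults to the training catalog's scores.
#' @param ... unused.
#' @return data.frame `key`, `synev_score`, `binary_call` (effect at
#'   score >= 0.5).
#' @export
predict.synev <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  X <- apply_feature_encoder(newdata, object$encoder)
  s <- .xgb_score(object$final$model, X)
  data.frame(key = newdata$key, synev_score = s,
             binary_call = ifelse(s >= 0.5, "effect", "no_effect"),
             stringsAsFactors = FALSE)
}

#' Plot score distributions of a fitted synev model
#'
#' Histograms of final effect scores per variant class.
#'
#' @param x a `synev` fit.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the score data.frame.
#' @export
plot.synev <- function(x, ...) {
  sc <- x$scores
  classes <- intersect(c("observed", "singleton", "not_seen"),
                       unique(sc$stage_provenance))
  old <- graphics::par(mfrow = c(length(classes), 1),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cl in classes) {
    graphics::hist(sc$synev_score[sc$stage_provenance == cl],
                   breaks = seq(0, 1, 0.05), main = cl,
                   xlab = "effect score", col = "grey70", ...)
    graphics::abline(v = 0.5, lty = 2, col = "red")
  }
  invisible(sc)
}
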