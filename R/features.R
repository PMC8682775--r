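# The 35-slot variant feature pipeline: codon-metric deltas, regulatory
# distances, expression, structure-track joins, encoders and reports.

.DIST_BINS <- c("d=0", "0<d<=3", "3<d<=5", "5<d<=10", "10<d<=20", "d>20")
.PAIRING_LEVELS <- c("strongly_paired", "strongly_upstream_paired",
                     "strongly_downstream_paired", "weakly_paired",
                     "weakly_upstream_paired", "weakly_downstream_paired",
                     "unpaired")
.SS_LEVELS <- c("H", "E", "C")
.SITE_CLASSES <- c("splice", "tfbs", "rbp", "esr")

#' The frozen 35-slot feature schema
#'
#' Slot names, types (continuous/categorical) and groups are frozen in a
#' schema file shipped with the package so that feature matrices are
#' column-stable across runs.
#'
#' @return data.frame with columns `name`, `type`, `group` (35 rows).
#' @export
feature_schema <- function() {
  read.delim(system.file("extdata", "feature_schema.tsv", package = "synev"),
             stringsAsFactors = FALSE)
}

#' Minimum distance from a variant position to a set of sites
#'
#' @param variant_position nucleotide position in the transcript, in the
#'   same 0-based coordinate frame as the intervals.
#' @param interval_set data.frame with `start`, `end` (0-based half-open,
#'   transcript-local) or NULL/empty for "no site".
#' @return integer nucleotide distance (0 inside an interval), or
#'   `NA_integer_` as the "no site" sentinel (binned as `d>20`).
#' @examples
#' min_site_distance(10, data.frame(start = 8, end = 12))
#' min_site_distance(5, data.frame(start = c(10, 30), end = c(12, 40)))
#' @export
min_site_distance <- function(variant_position, interval_set) {
  if (is.null(interval_set) || nrow(interval_set) == 0L) return(NA_integer_)
  p <- variant_position
  inside <- p >= interval_set$start & p < interval_set$end
  if (any(inside)) return(0L)
  gaps <- pmin(abs(p - interval_set$start),
               abs(p - (interval_set$end - 1L)))
  as.integer(min(gaps))
}

#' Bin a site distance into the six distance categories
#'
#' Categories are `d=0`, `0<d<=3`, `3<d<=5`, `5<d<=10`, `10<d<=20` and
#' `d>20`; the sentinel `NA` ("no site") maps to `d>20`.
#'
#' @param d non-negative integer distance(s) or NA sentinel.
#' @return character vector of bin labels.
#' @examples
#' bin_distance(c(0, 3, 4, 25, NA))
#' @export
bin_distance <- function(d) {
  if (any(!is.na(d) & d < 0)) stop("negative distance")
  out <- rep(.DIST_BINS[6], length(d))
  out[!is.na(d) & d == 0] <- .DIST_BINS[1]
  out[!is.na(d) & d > 0 & d <= 3] <- .DIST_BINS[2]
  out[!is.na(d) & d > 3 & d <= 5] <- .DIST_BINS[3]
  out[!is.na(d) & d > 5 & d <= 10] <- .DIST_BINS[4]
  out[!is.na(d) & d > 10 & d <= 20] <- .DIST_BINS[5]
  out
}

#' Per-transcript expression summary features
#'
#' log10 of the minimum, median and maximum per-tissue expression of a
#' transcript, with a pseudocount applied before the log. The expression
#' matrix is expected to hold per-tissue representative values (mean over
#' samples of a tissue after cross-sample standardisation).
#'
#' @param transcript_id transcript identifier.
#' @param expression_matrix numeric matrix transcripts x tissues.
#' @param pseudocount added before log10 (default 1e-3).
#' @return named numeric vector (`expr_log10_min`, `expr_log10_median`,
#'   `expr_log10_max`); all NA when the transcript is missing from the matrix
#'   (imputed downstream by the encoder, flagged with a warning).
#' @export
expression_features <- function(transcript_id, expression_matrix,
                                pseudocount = 1e-3) {
  if (!(transcript_id %in% rownames(expression_matrix))) {
    return(c(expr_log10_min = NA_real_, expr_log10_median = NA_real_,
             expr_log10_max = NA_real_))
  }
  x <- as.numeric(expression_matrix[transcript_id, ])
  c(expr_log10_min = log10(min(x) + pseudocount),
    expr_log10_median = log10(median(x) + pseudocount),
    expr_log10_max = log10(max(x) + pseudocount))
}

#' RNAsnp parameter rule
#'
#' Mode and folding window size for local-structure-change prediction as a
#' function of sequence length L: mode 1 / window 100 for L <= 200, mode 1 /
#' window 200 for 200 < L <= 500, mode 2 / window 500 for L > 500.
#'
#' @param L sequence length in nucleotides (>= 1).
#' @return named integer vector `c(mode=, window=)`.
#' @export
rnasnp_params <- function(L) {
  stopifnot(L >= 1)
  if (L <= 200) c(mode = 1L, window = 100L)
  else if (L <= 500) c(mode = 1L, window = 200L)
  else c(mode = 2L, window = 500L)
}

# ---- fast per-transcript metric state ------------------------------------
# Incremental forms of the delta measures; equivalent to recomputing the
# metric on the mutated sequence (property-tested against delta_metric()).

.fam_codons <- function(a) names(.GENETIC_CODE)[.GENETIC_CODE == a]

.tpi_family_term <- function(fam) {
  n <- length(fam)
  if (n < 2L) return(c(0, 0))
  counts <- table(fam)
  r <- sum(fam[-1] == fam[-n])
  e_r <- sum(counts * (counts - 1)) / n
  r_max <- n - length(counts)
  if (r_max - e_r <= 0) return(c(0, 0))
  c((n - 1) * (r - e_r) / (r_max - e_r), n - 1)
}

.icdi_family <- function(counts, k) {
  rscu <- k * counts / sum(counts)
  sum((rscu - 1)^2) / (k * (k - 1))
}

.scuo_family <- function(counts, k) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  (log(k) + sum(p * log(p))) / log(k)
}

.cub_family <- function(counts, ref_counts) {
  rc <- ref_counts
  rc[rc == 0] <- 0.5
  sum(abs(counts / sum(counts) - rc / sum(rc)))
}

.transcript_metric_state <- function(transcript, reference) {
  codons <- transcript$codons
  aa <- translate_codons(codons)
  deg <- !(aa %in% c(.SINGLE_CODON_AA, "*"))
  sense <- aa != "*"
  fam_aa <- unique(aa[deg])
  fams <- lapply(fam_aa, function(a) {
    fam <- .fam_codons(a)
    occ <- codons[aa == a]
    counts <- as.numeric(table(factor(occ, levels = fam)))
    names(counts) <- fam
    ref_counts <- reference$table$count[match(fam, reference$table$codon)]
    tpi_term <- .tpi_family_term(occ)
    list(aa = a, fam = fam, occ = occ, counts = counts, k = length(fam),
         ref_counts = ref_counts,
         s_icdi = .icdi_family(counts, length(fam)),
         o_scuo = .scuo_family(counts, length(fam)),
         d_cub = .cub_family(counts, ref_counts),
         tpi_contrib = tpi_term[1], tpi_weight = tpi_term[2])
  })
  names(fams) <- fam_aa
  m_deg <- sum(deg)
  n_aa <- vapply(fams, function(f) sum(f$counts), numeric(1))
  opt <- unlist(reference$optimal, use.names = FALSE)
  list(codons = codons, aa = aa, fams = fams, m_deg = m_deg,
       m_sense = sum(sense),
       logw_sum = sum(log(reference$weights[codons[deg]])),
       logt_sum = sum(log(reference$trna_weights[codons[sense]])),
       n_opt = sum(codons[deg] %in% opt),
       n_fam = length(fams), n_aa = n_aa,
       tpi_num = sum(vapply(fams, function(f) f$tpi_contrib, numeric(1))),
       tpi_den = sum(vapply(fams, function(f) f$tpi_weight, numeric(1))),
       opt = opt, reference = reference)
}

# All ten codon-bias/autocorrelation feature slots for a transcript's
# variants, via the incremental state (one row per variant).
.variant_metric_features <- function(state, variants) {
  ref <- state$reference
  n_var <- nrow(variants)
  out <- matrix(NA_real_, n_var, 10,
                dimnames = list(NULL, c("cai", "cai_delta", "fracopt_delta",
                                        "cub_delta", "icdi_delta",
                                        "scuo_delta", "tai_delta",
                                        "tpi_delta", "cam", "cf")))
  cai0 <- exp(state$logw_sum / state$m_deg)
  tai0 <- exp(state$logt_sum / state$m_sense)
  tpi0 <- if (state$tpi_den == 0) 0 else state$tpi_num / state$tpi_den
  for (v in seq_len(n_var)) {
    wt <- variants$wt_codon[v]
    mut <- variants$mut_codon[v]
    i <- variants$codon_index[v]
    a <- state$aa[i]
    f <- state$fams[[a]]
    # CAI / tAI: swap one weight inside the geometric mean
    out[v, "cai"] <- cai0
    out[v, "cai_delta"] <- exp((state$logw_sum - log(ref$weights[[wt]]) +
                                  log(ref$weights[[mut]])) / state$m_deg) -
      cai0
    out[v, "tai_delta"] <-
      exp((state$logt_sum - log(ref$trna_weights[[wt]]) +
             log(ref$trna_weights[[mut]])) / state$m_sense) - tai0
    out[v, "fracopt_delta"] <- ((mut %in% state$opt) - (wt %in% state$opt)) /
      state$m_deg
    cnt <- f$counts
    cnt[wt] <- cnt[wt] - 1
    cnt[mut] <- cnt[mut] + 1
    out[v, "cub_delta"] <- (sum(f$counts) / state$m_deg) *
      (.cub_family(cnt, f$ref_counts) - f$d_cub)
    out[v, "icdi_delta"] <- (.icdi_family(cnt, f$k) - f$s_icdi) / state$n_fam
    out[v, "scuo_delta"] <- (sum(f$counts) / state$m_deg) *
      (.scuo_family(cnt, f$k) - f$o_scuo)
    occ <- f$occ
    occ_pos <- which(state$aa == a)
    occ[occ_pos == i] <- mut
    term <- .tpi_family_term(occ)
    num <- state$tpi_num - f$tpi_contrib + term[1]
    den <- state$tpi_den - f$tpi_weight + term[2]
    out[v, "tpi_delta"] <- (if (den == 0) 0 else num / den) - tpi0
    vr <- list(codon_index = i, wt_codon = wt, mut_codon = mut)
    out[v, "cam"] <- cam(state$codons, vr)
    out[v, "cf"] <- cf_measure(state$codons, vr)
  }
  out
}

# ---- assembly -------------------------------------------------------------

.variant_structure_lookup <- function(keys, tab) {
  cols <- c("rnasnp_local_dissim", "rnasnp_global_dissim",
            "rnasnp_local_p", "rnasnp_global_p")
  out <- matrix(NA_real_, length(keys), 4, dimnames = list(NULL, cols))
  if (!is.null(tab)) {
    idx <- match(keys, tab$key)
    hit <- !is.na(idx)
    out[hit, ] <- as.matrix(tab[idx[hit], cols])
  }
  out
}

#' Assemble the raw 35-slot feature table for a variant catalog
#'
#' One row per catalog variant, columns as in [feature_schema()] plus a
#' leading `key` column. Continuous slots may be NA (missing annotation) and
#' categorical slots take the string "unknown" when no track is available;
#' both are resolved by the encoder ([fit_feature_encoder()]). Structure
#' tracks are consumed from a precomputed annotation bundle; external
#' structure predictors are never invoked.
#'
#' @param catalog variant catalog ([enumerate_catalog()]).
#' @param transcripts named list of `synev_transcript` objects.
#' @param annotations annotation bundle as produced by [gen_annotations()]
#'   or [read_annotations()]; may be NULL for the null-annotation fallback.
#' @param reference `synev_codon_ref`.
#' @param expression_matrix transcripts x tissues matrix (may be NULL).
#' @return data.frame `key` + 35 feature columns, rows aligned with
#'   `catalog`.
#' @export
assemble_features <- function(catalog, transcripts, annotations, reference,
                              expression_matrix = NULL) {
  schema <- feature_schema()
  keys <- variant_key(catalog)
  n <- nrow(catalog)
  feat <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (nm in schema$name)
    feat[[nm]] <- if (schema$type[schema$name == nm] == "continuous")
      NA_real_ else "unknown"

  if (is.null(expression_matrix) && !is.null(annotations))
    expression_matrix <- annotations$expression

  by_tr <- split(seq_len(n), catalog$transcript_id)
  for (tid in names(by_tr)) {
    rows <- by_tr[[tid]]
    tr <- transcripts[[tid]]
    if (is.null(tr)) stop("catalog transcript not supplied: ", tid)
    sub <- catalog[rows, , drop = FALSE]
    state <- .transcript_metric_state(tr, reference)
    vm <- .variant_metric_features(state, sub)
    feat[rows, colnames(vm)] <- vm

    n_codon <- length(tr$codons)
    pos_nt <- (sub$codon_index - 1L) * 3L + sub$offset
    pos_res <- sub$codon_index
    feat$codon_mutation[rows] <- paste0(sub$wt_codon, ">", sub$mut_codon)
    feat$next_codon[rows] <- ifelse(sub$codon_index < n_codon,
                                    tr$codons[pmin(sub$codon_index + 1L,
                                                   n_codon)], "none")
    feat$last_codon[rows] <- ifelse(sub$codon_index > 1L,
                                    tr$codons[pmax(sub$codon_index - 1L, 1L)],
                                    "none")
    feat$offset[rows] <- as.character(sub$offset)
    feat$rel_position[rows] <- sub$codon_index / n_codon
    feat$transcript_length[rows] <- n_codon
    gc <- sum(strsplit(tr$cds, "")[[1]] %in% c("G", "C")) / nchar(tr$cds)
    feat$gc_content[rows] <- gc

    if (!is.null(expression_matrix)) {
      ef <- expression_features(tid, expression_matrix)
      feat$expr_log10_min[rows] <- ef[["expr_log10_min"]]
      feat$expr_log10_median[rows] <- ef[["expr_log10_median"]]
      feat$expr_log10_max[rows] <- ef[["expr_log10_max"]]
    }

    if (!is.null(annotations)) {
      for (cls in .SITE_CLASSES) {
        iv <- annotations$sites[[cls]][[tid]]
        d <- vapply(pos_nt - 1L, min_site_distance, integer(1),
                    interval_set = iv)
        feat[[paste0("dist_", cls, "_bin")]][rows] <- bin_distance(d)
      }
      pt <- annotations$protein_tracks[[tid]]
      if (!is.null(pt)) {
        feat$prot_sec_struct[rows] <- pt$sec_struct[pos_res]
        feat$solvent_acc[rows] <- pt$solvent_acc[pos_res]
        feat$disorder[rows] <- pt$disorder[pos_res]
      }
      mt <- annotations$mrna_tracks[[tid]]
      if (!is.null(mt)) feat$local_pairing[rows] <- mt$pairing[pos_nt]
      fold <- annotations$folding
      if (!is.null(fold) && tid %in% fold$transcript_id) {
        fr <- fold[fold$transcript_id == tid, , drop = FALSE]
        feat$mfe_freq[rows] <- fr$mfe_freq[1]
        feat$centroid_energy[rows] <- fr$centroid_energy[1]
        feat$ensemble_distance[rows] <- fr$ensemble_distance[1]
      }
    }
  }
  if (!is.null(annotations)) {
    vs <- .variant_structure_lookup(keys, annotations$variant_structure)
    feat[, colnames(vs)] <- vs
  }
  feat
}

# ---- encoders -------------------------------------------------------------

#' Fit feature encoders and scalers on a training split
#'
#' Continuous slots get imputation medians and standardisation moments
#' (mean/sd); categorical slots get a lexicographically sorted vocabulary
#' frozen at fit time. Encoders fitted on the training split are reused at
#' prediction time; unseen categories map to a reserved "unknown" code.
#'
#' @param features raw feature table from [assemble_features()].
#' @param rows optional integer rows (the training split) to fit on.
#' @return object of class `synev_encoder`.
#' @export
fit_feature_encoder <- function(features, rows = seq_len(nrow(features))) {
  schema <- feature_schema()
  tr <- features[rows, , drop = FALSE]
  cont <- schema$name[schema$type == "continuous"]
  cat_ <- schema$name[schema$type == "categorical"]
  moments <- lapply(setNames(cont, cont), function(nm) {
    x <- tr[[nm]]
    med <- median(x, na.rm = TRUE)
    if (is.na(med)) med <- 0
    x[is.na(x)] <- med
    s <- sd(x)
    list(median = med, mean = mean(x), sd = if (is.na(s) || s == 0) 1 else s)
  })
  vocab <- lapply(setNames(cat_, cat_), function(nm)
    sort(unique(tr[[nm]])))
  structure(list(schema = schema, moments = moments, vocab = vocab),
            class = "synev_encoder")
}

#' Apply fitted encoders to a raw feature table
#'
#' @param features raw feature table.
#' @param encoder `synev_encoder` from [fit_feature_encoder()].
#' @return numeric matrix (rows = variants, 35 columns in schema order);
#'   continuous columns imputed with the training median and standardised by
#'   training mean/sd, categorical columns integer-coded from the frozen
#'   vocabulary with 0 as the reserved unseen/"unknown" code.
#' @export
apply_feature_encoder <- function(features, encoder) {
  schema <- encoder$schema
  out <- matrix(0, nrow(features), nrow(schema),
                dimnames = list(NULL, schema$name))
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    if (schema$type[j] == "continuous") {
      m <- encoder$moments[[nm]]
      x <- features[[nm]]
      x[is.na(x)] <- m$median
      out[, j] <- (x - m$mean) / m$sd
    } else {
      code <- match(features[[nm]], encoder$vocab[[nm]])
      code[is.na(code)] <- 0L
      out[, j] <- code
    }
  }
  out
}

# ---- reports --------------------------------------------------------------

.cramers_v <- function(x, y) {
  tab <- table(x, y)
  if (min(dim(tab)) < 2L) return(NA_real_)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1L)))
}

.correlation_ratio <- function(cat_x, num_y) {
  if (sd(num_y) == 0) return(NA_real_)
  groups <- split(num_y, cat_x)
  n <- length(num_y)
  gm <- mean(num_y)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - gm)^2, numeric(1)))
  ss_total <- sum((num_y - gm)^2)
  sqrt(ss_between / ss_total)
}

#' Mixed-type feature correlation matrix
#'
#' Pearson correlation for continuous-continuous pairs, Cramer's V for
#' categorical-categorical pairs, and the correlation ratio for
#' continuous-categorical pairs. Zero-variance columns yield NA entries.
#'
#' @param features raw feature table (35 slots; the `key` column is ignored).
#' @return symmetric numeric matrix with unit diagonal.
#' @export
feature_correlation <- function(features) {
  schema <- feature_schema()
  nms <- schema$name
  stopifnot(nrow(features) >= 2L)
  k <- length(nms)
  out <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(out) <- 1
  type <- setNames(schema$type, schema$name)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- features[[nms[i]]]
      xj <- features[[nms[j]]]
      ok <- if (type[i] == "continuous") !is.na(xi) else rep(TRUE, length(xi))
      ok <- ok & (if (type[j] == "continuous") !is.na(xj)
                  else rep(TRUE, length(xj)))
      xi <- xi[ok]; xj <- xj[ok]
      v <- if (type[i] == "continuous" && type[j] == "continuous") {
        if (sd(xi) == 0 || sd(xj) == 0) NA_real_ else cor(xi, xj)
      } else if (type[i] == "categorical" && type[j] == "categorical") {
        .cramers_v(xi, xj)
      } else if (type[i] == "categorical") {
        .correlation_ratio(xi, xj)
      } else {
        .correlation_ratio(xj, xi)
      }
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

#' Feature importance of a boosted-tree model
#'
#' Mean split gain per feature (xgboost "Gain"), reported for the full
#' 35-slot roster with zero gain for unused features, in descending order.
#'
#' @param model an `xgb.Booster` (e.g. `fit$final$model` from [synev()]).
#' @return data.frame `feature`, `gain`, sorted by decreasing gain.
#' @export
feature_importance <- function(model) {
  schema <- feature_schema()
  imp <- xgboost::xgb.importance(feature_names = schema$name, model = model)
  gain <- setNames(rep(0, nrow(schema)), schema$name)
  gain[imp$Feature] <- imp$Gain
  out <- data.frame(feature = names(gain), gain = unname(gain),
                    stringsAsFactors = FALSE)
  out[order(-out$gain), , drop = FALSE]
}
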