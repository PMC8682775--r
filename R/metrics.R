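# Codon usage bias and codon autocorrelation measures.
#
# All measures operate on a vector of codons (or a CDS string). Following the
# usual conventions, the reference-free bias sums (CAI, ICDI, SCUO) skip
# Met, Trp and stop codons; fracOpt and CUB run over codons of degenerate
# amino acids; tAI runs over all sense codons.

.as_codons <- function(seq) {
  if (length(seq) == 1L && nchar(seq[1]) > 3L) split_codons(seq) else seq
}

.degenerate_codons <- function(codons) {
  aa <- translate_codons(codons)
  codons[!(aa %in% c(.SINGLE_CODON_AA, "*"))]
}

.metric_ids <- c("CAI", "fracOpt", "CUB", "ICDI", "SCUO", "tAI", "TPI",
                 "CAM", "CF")

#' Codon usage bias of a sequence
#'
#' Dispatches on `metric_id`:
#' \describe{
#'   \item{CAI}{codon adaptation index: geometric mean over codons of the
#'     relative adaptiveness weight of each codon versus the most frequent
#'     synonymous codon in the reference set.}
#'   \item{fracOpt}{fraction of optimal codons among codons of degenerate
#'     amino acids.}
#'   \item{CUB}{amino-acid-frequency-weighted codon usage difference from the
#'     reference: \eqn{\sum_a p_a \sum_c |f(c|a) - f_{ref}(c|a)|}.}
#'   \item{ICDI}{intrinsic codon deviation index, reference-free: mean over
#'     degenerate amino acids of \eqn{\sum_i (RSCU_i - 1)^2 / (k(k-1))};
#'     0 for uniform usage, 1 when one codon is used exclusively.}
#'   \item{SCUO}{synonymous codon usage order: Shannon-entropy-based bias,
#'     \eqn{\sum_a F_a (H_a^{max} - H_a)/H_a^{max}} with \eqn{F_a} the
#'     amino-acid frequency among degenerate families; 0 for uniform usage.}
#'   \item{tAI}{tRNA adaptation index: geometric mean of per-codon tRNA
#'     availability weights over all sense codons.}
#' }
#'
#' @param seq CDS string or codon vector.
#' @param metric_id one of "CAI", "fracOpt", "CUB", "ICDI", "SCUO", "tAI";
#'   for "TPI", "CAM", "CF" see [tpi()], [cam()], [cf_measure()].
#' @param reference `synev_codon_ref`, required for CAI/fracOpt/CUB/tAI.
#' @return numeric metric value.
#' @export
codon_bias <- function(seq, metric_id, reference = NULL) {
  metric_id <- match.arg(metric_id, .metric_ids)
  codons <- .as_codons(seq)
  needs_ref <- metric_id %in% c("CAI", "fracOpt", "CUB", "tAI")
  if (needs_ref && is.null(reference))
    stop("metric ", metric_id, " requires a codon usage reference")
  switch(metric_id,
         CAI = .cai(codons, reference),
         fracOpt = .frac_opt(codons, reference),
         CUB = .cub(codons, reference),
         ICDI = .icdi(codons),
         SCUO = .scuo(codons),
         tAI = .tai(codons, reference),
         TPI = tpi(codons),
         stop("variant-specific metric ", metric_id,
              " needs a variant; use cam()/cf_measure()"))
}

.cai <- function(codons, reference) {
  cc <- .degenerate_codons(codons)
  if (length(cc) == 0L) return(NA_real_)
  exp(mean(log(reference$weights[cc])))
}

.frac_opt <- function(codons, reference) {
  cc <- .degenerate_codons(codons)
  if (length(cc) == 0L) return(NA_real_)
  opt <- unlist(reference$optimal, use.names = FALSE)
  mean(cc %in% opt)
}

.cub <- function(codons, reference) {
  cc <- .degenerate_codons(codons)
  if (length(cc) == 0L) return(NA_real_)
  aa <- translate_codons(cc)
  ref <- reference$table
  total <- 0
  for (a in unique(aa)) {
    fam_codons <- cc[aa == a]
    fam <- names(.GENETIC_CODE)[.GENETIC_CODE == a]
    f_seq <- table(factor(fam_codons, levels = fam)) / length(fam_codons)
    rc <- ref$count[match(fam, ref$codon)]
    rc[rc == 0] <- 0.5
    f_ref <- rc / sum(rc)
    total <- total + (length(fam_codons) / length(cc)) *
      sum(abs(as.numeric(f_seq) - f_ref))
  }
  total
}

.icdi <- function(codons) {
  cc <- .degenerate_codons(codons)
  if (length(cc) == 0L) return(NA_real_)
  aa <- translate_codons(cc)
  s_vals <- vapply(unique(aa), function(a) {
    fam <- names(.GENETIC_CODE)[.GENETIC_CODE == a]
    k <- length(fam)
    n <- table(factor(cc[aa == a], levels = fam))
    rscu <- k * as.numeric(n) / sum(n)
    sum((rscu - 1)^2) / (k * (k - 1))
  }, numeric(1))
  mean(s_vals)
}

.scuo <- function(codons) {
  cc <- .degenerate_codons(codons)
  if (length(cc) == 0L) return(NA_real_)
  aa <- translate_codons(cc)
  fam_n <- table(aa)
  o_vals <- vapply(names(fam_n), function(a) {
    fam <- names(.GENETIC_CODE)[.GENETIC_CODE == a]
    p <- as.numeric(table(factor(cc[aa == a], levels = fam))) / fam_n[[a]]
    p <- p[p > 0]
    h <- -sum(p * log(p))
    (log(length(fam)) - h) / log(length(fam))
  }, numeric(1))
  sum(as.numeric(fam_n) / length(cc) * o_vals)
}

.tai <- function(codons, reference) {
  cc <- codons[translate_codons(codons) != "*"]
  if (length(cc) == 0L) return(NA_real_)
  exp(mean(log(reference$trna_weights[cc])))
}

#' tRNA pairing index (codon autocorrelation)
#'
#' Measures whether same codons cluster (autocorrelation) or interleave
#' within each isoacceptor family. For each degenerate amino acid with at
#' least two codon occurrences, the ordered list of its codons is scanned for
#' same-codon adjacent pairs (`r`); the family score is
#' `(r - E[r]) / (r_max - E[r])` where `E[r]` is the expectation under a
#' random permutation of the family's codons and `r_max` the maximum
#' attainable. Family scores are averaged weighted by (occurrences - 1).
#' Ranges over [-1, 1]; clustered usage (XXXYYY) scores higher than
#' interleaved usage (XYXYXY) of the same composition. Sequences with no
#' repeated family return the sentinel 0.
#'
#' @param seq CDS string or codon vector.
#' @return numeric TPI in [-1, 1] (0 when undefined).
#' @export
tpi <- function(seq) {
  codons <- .as_codons(seq)
  aa <- translate_codons(codons)
  keep <- !(aa %in% c(.SINGLE_CODON_AA, "*"))
  codons <- codons[keep]
  aa <- aa[keep]
  num <- 0
  den <- 0
  for (a in unique(aa)) {
    fam <- codons[aa == a]
    n <- length(fam)
    if (n < 2L) next
    counts <- table(fam)
    r <- sum(fam[-1] == fam[-n])
    e_r <- sum(counts * (counts - 1)) / n
    r_max <- n - length(counts)
    if (r_max - e_r <= 0) next  # single distinct codon: no signal possible
    num <- num + (n - 1) * (r - e_r) / (r_max - e_r)
    den <- den + (n - 1)
  }
  if (den == 0) 0 else num / den
}

#' Codon autocorrelation measure of a variant (CAM)
#'
#' Variant-specific autocorrelation impact, penalised by the codon distance
#' to the nearest isoaccepting partner: a codon at position `i` earns
#' autocorrelation credit `1/d` where `d` is the codon distance to the
#' nearest other occurrence of the same codon in the transcript (0 when the
#' codon occurs nowhere else). CAM is the credit of the mutant codon minus
#' the credit of the wild-type codon, so `|CAM|` shrinks as the nearest
#' synonymous partner moves away, and CAM is 0 when neither codon has a
#' same-codon partner.
#'
#' @param seq CDS string or codon vector (wild-type).
#' @param variant list or one-row data.frame with `codon_index`, `wt_codon`,
#'   `mut_codon`.
#' @return numeric CAM value.
#' @export
cam <- function(seq, variant) {
  codons <- .as_codons(seq)
  i <- variant$codon_index
  if (codons[i] != variant$wt_codon)
    stop("variant wt_codon does not match sequence at codon ", i)
  credit <- function(codon) {
    pos <- setdiff(which(codons == codon), i)
    if (length(pos) == 0L) return(0)
    1 / min(abs(pos - i))
  }
  credit(variant$mut_codon) - credit(variant$wt_codon)
}

#' Change-of-frequency measure of a variant (CF)
#'
#' Impact of the variant on its codon's frequency within the transcript: the
#' mutation removes one occurrence of the wild-type codon and adds one of the
#' mutant codon among the N codons of the sequence. CF is the frequency of
#' the mutant codon after mutation minus the frequency of the wild-type codon
#' before mutation, `(n_mut + 1)/N - n_wt/N`; positive when the variant moves
#' the sequence toward a codon at least as frequent as the one it replaces.
#'
#' @inheritParams cam
#' @return numeric CF value in [-1, 1].
#' @export
cf_measure <- function(seq, variant) {
  codons <- .as_codons(seq)
  i <- variant$codon_index
  if (codons[i] != variant$wt_codon)
    stop("variant wt_codon does not match sequence at codon ", i)
  n <- length(codons)
  n_wt <- sum(codons == variant$wt_codon)
  n_mut <- sum(codons == variant$mut_codon)
  ((n_mut + 1) - n_wt) / n
}

#' Apply a variant to a codon vector
#' @keywords internal
mutate_codons <- function(codons, variant) {
  i <- variant$codon_index
  if (codons[i] != variant$wt_codon)
    stop("variant wt_codon does not match sequence at codon ", i)
  codons[i] <- variant$mut_codon
  codons
}

#' Delta form of a codon bias measure
#'
#' Difference in measure value after mutation versus before mutation
#' (mutant minus wild-type).
#'
#' @inheritParams cam
#' @param metric_id one of "CAI", "fracOpt", "CUB", "ICDI", "SCUO", "tAI",
#'   "TPI".
#' @param reference `synev_codon_ref` where the measure requires one.
#' @return numeric delta.
#' @export
delta_metric <- function(seq, variant, metric_id, reference = NULL) {
  codons <- .as_codons(seq)
  codon_bias(mutate_codons(codons, variant), metric_id, reference) -
    codon_bias(codons, metric_id, reference)
}
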