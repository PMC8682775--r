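# Synthetic data generator: transcripts, annotation bundles, variant
# catalogs with planted observation/effect structure, and divergence-scaled
# ortholog alignments. Everything the pipeline consumes can be produced here
# at desk scale, with a hidden truth table kept separate from the pipeline
# inputs.

.default_species <- function() {
  data.frame(
    species = c("chimpanzee", "macaque", "mouse", "opossum", "chicken",
                "xenopus", "zebrafish", "fruitfly"),
    divergence = c(6.7, 29, 90, 160, 312, 352, 429, 736),
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defines the study conditions the generator emulates: a gnomAD-like
#' observation structure in which roughly 12% of all possible sSNVs have
#' been reported, a planted latent-effect signal (logistic over a declared
#' subset of the variant features) that depresses the observation
#' probability, a feature-threshold rule defining planted unobservable
#' variants, and divergence-scaled synonymous substitution in ortholog rows.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range CDS length range in codons (incl. start and stop).
#' @param gc_target target GC content of generated CDSs.
#' @param n_tissues tissues in the expression matrix.
#' @param effect_weights named weights over raw feature columns for the
#'   latent-effect linear predictor (standardised internally).
#' @param effect_intercept intercept of the latent-effect logistic.
#' @param seen_target fraction of all variants ever reported (observed +
#'   singleton).
#' @param obs_slope how strongly latent effect depresses observation (log-odds
#'   units per unit effect).
#' @param ac_meanlog,ac_sdlog log-normal allele-count model for seen
#'   variants (counts of carrier individuals; count 1 = singleton).
#' @param an total allele number for MAF.
#' @param noise_rate sequencing-noise rate: fraction of unseen variants
#'   spuriously reported once.
#' @param unobservable_frac fraction of variants planted unobservable.
#' @param unobservable_feature raw feature whose upper tail defines the
#'   planted unobservable rule.
#' @param n_curated size of the synthetic curated-effect set (drawn from the
#'   highest-latent-effect variants).
#' @param species data.frame `species`, `divergence` (million years).
#' @param subst_rate synonymous substitutions per codon per 100 million
#'   years in ortholog rows.
#' @param gap_rate whole-codon gap rate per ortholog row.
#' @param seed integer seed; all generator randomness flows from it.
#' @param preset "default", or "strong_signal" -- the latter doubles the
#'   latent-effect weights and steepens the observation slope, giving a
#'   clearly learnable planted effect (used for end-to-end signal checks;
#'   the matching no-signal control is a label shuffle, not a preset).
#' @return list of class `synev_gen_config`.
#' @export
generator_config <- function(n_transcripts = 200L,
                             length_range = c(40L, 80L),
                             gc_target = 0.45, n_tissues = 8L,
                             effect_weights = c(rnasnp_global_dissim = 1.6,
                                                cam = 1.0, cf = 1.0,
                                                cai_delta = 1.0),
                             effect_intercept = 0,
                             seen_target = 0.12, obs_slope = 2.5,
                             ac_meanlog = 0.5, ac_sdlog = 2.5,
                             an = 20000L, noise_rate = 0.005,
                             unobservable_frac = 0.2,
                             unobservable_feature = "rnasnp_global_dissim",
                             n_curated = 40L,
                             species = .default_species(),
                             subst_rate = 0.08, gap_rate = 0.02,
                             seed = 1L,
                             preset = c("default", "strong_signal")) {
  preset <- match.arg(preset)
  if (preset == "strong_signal") {
    effect_weights <- effect_weights * 2
    obs_slope <- 4
  }
  stopifnot(length_range[1] >= 3L, gc_target > 0, gc_target < 1,
            seen_target > 0, seen_target < 1,
            unobservable_frac >= 0, unobservable_frac < 1,
            all(species$divergence > 0))
  structure(as.list(environment()), class = "synev_gen_config")
}

#' Generate valid coding transcripts
#'
#' Random CDSs with start codon, stop codon, no internal stop, and GC
#' content concentrated around the target. Every output passes
#' [validate_transcript()]; output is deterministic given the seed.
#'
#' @param config `synev_gen_config`.
#' @return named list of `synev_transcript` objects.
#' @export
gen_transcripts <- function(config) {
  set.seed(config$seed)
  p_base <- c(A = (1 - config$gc_target) / 2, C = config$gc_target / 2,
              G = config$gc_target / 2, T = (1 - config$gc_target) / 2)
  out <- vector("list", config$n_transcripts)
  for (i in seq_len(config$n_transcripts)) {
    n_codon <- sample(seq(config$length_range[1], config$length_range[2]),
                      1L)
    n_internal <- n_codon - 2L
    internal <- character(n_internal)
    for (j in seq_len(n_internal)) {
      repeat {
        cd <- paste(sample(names(p_base), 3L, replace = TRUE,
                           prob = p_base), collapse = "")
        if (!(cd %in% .STOP_CODONS)) break
      }
      internal[j] <- cd
    }
    cds <- paste(c("ATG", internal, sample(.STOP_CODONS, 1L)),
                 collapse = "")
    id <- sprintf("T%04d", i)
    tr <- validate_transcript(id, cds)
    if (is_rejection(tr)) stop("generator produced invalid CDS")  # nocov
    out[[i]] <- tr
  }
  names(out) <- vapply(out, function(t) t$transcript_id, character(1))
  out
}

.gen_intervals <- function(L, n, width) {
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  start <- sort(sample.int(max(L - width, 1L), n, replace = TRUE)) - 1L
  data.frame(start = start, end = pmin(start + width, L))
}

#' Generate an annotation bundle and expression matrix
#'
#' Random but seeded regulatory-site intervals per class (splice sites
#' anchored at the CDS ends plus interior sites), length-consistent protein
#' and mRNA structure tracks with fixed category vocabularies, per-transcript
#' folding summaries, a log-normal expression matrix, and (when a catalog is
#' supplied) per-variant mRNA structure-change records emulating
#' local-folding dissimilarity output.
#'
#' @param transcripts named list of `synev_transcript` objects.
#' @param config `synev_gen_config`.
#' @param catalog optional variant catalog; needed for the per-variant
#'   structure-change records.
#' @return annotation bundle: list `sites`, `protein_tracks`, `mrna_tracks`,
#'   `folding`, `expression`, `variant_structure`.
#' @export
gen_annotations <- function(transcripts, config, catalog = NULL) {
  set.seed(config$seed + 1L)
  ids <- names(transcripts)
  sites <- lapply(setNames(.SITE_CLASSES, .SITE_CLASSES), function(cls)
    vector("list", length(ids)))
  protein_tracks <- mrna_tracks <- vector("list", length(ids))
  folding <- NULL
  for (k in seq_along(ids)) {
    tr <- transcripts[[k]]
    L <- nchar(tr$cds)
    n_res <- L / 3L
    sites$splice[[k]] <- rbind(
      data.frame(start = 0L, end = 2L),
      data.frame(start = L - 2L, end = L),
      .gen_intervals(L, rpois(1, L / 400), 2L))
    sites$tfbs[[k]] <- .gen_intervals(L, 1L + rpois(1, L / 250), 10L)
    sites$rbp[[k]] <- .gen_intervals(L, 1L + rpois(1, L / 200), 6L)
    sites$esr[[k]] <- .gen_intervals(L, 1L + rpois(1, L / 200), 6L)
    protein_tracks[[k]] <- list(
      sec_struct = sample(.SS_LEVELS, n_res, replace = TRUE,
                          prob = c(0.35, 0.2, 0.45)),
      solvent_acc = round(runif(n_res), 3),
      disorder = round(runif(n_res), 3))
    mrna_tracks[[k]] <- list(
      pairing = sample(.PAIRING_LEVELS, L, replace = TRUE))
    folding <- rbind(folding, data.frame(
      transcript_id = tr$transcript_id,
      mfe_freq = runif(1, 0.02, 0.6),
      centroid_energy = -runif(1, 0.2, 0.45) * L,
      ensemble_distance = runif(1, 2, 30), stringsAsFactors = FALSE))
  }
  for (cls in .SITE_CLASSES) names(sites[[cls]]) <- ids
  names(protein_tracks) <- names(mrna_tracks) <- ids
  tissues <- paste0("tissue", seq_len(config$n_tissues))
  expression <- matrix(rlnorm(length(ids) * config$n_tissues,
                              meanlog = 1, sdlog = 1),
                       nrow = length(ids),
                       dimnames = list(ids, tissues))
  variant_structure <- NULL
  if (!is.null(catalog)) {
    nv <- nrow(catalog)
    variant_structure <- data.frame(
      key = variant_key(catalog),
      rnasnp_local_dissim = rexp(nv, rate = 4),
      rnasnp_global_dissim = rexp(nv, rate = 4),
      rnasnp_local_p = runif(nv), rnasnp_global_p = runif(nv),
      stringsAsFactors = FALSE)
  }
  list(sites = sites, protein_tracks = protein_tracks,
       mrna_tracks = mrna_tracks, folding = folding,
       expression = expression, variant_structure = variant_structure)
}

# calibrate the observation intercept so the seen fraction hits its target
.calibrate_intercept <- function(lin, target) {
  f <- function(a) mean(plogis(a + lin)) - target
  stats::uniroot(f, c(-20, 20))$root
}

#' Generate a variant catalog with planted observation and effect structure
#'
#' Enumerates every possible sSNV of the transcripts, draws a latent effect
#' from a logistic model over a declared subset of the (visible) variant
#' features, plants an unobservable subset by a feature-threshold rule, and
#' assigns observed/singleton/generated status from an observation model in
#' which the probability of having been reported decreases with latent
#' effect. Allele counts of seen variants are drawn independently of the
#' latent effect (so effect scores should not correlate with allele
#' frequency). The hidden truth is returned separately and is never consumed
#' by the pipeline.
#'
#' @param transcripts named list of `synev_transcript` objects.
#' @param config `synev_gen_config`.
#' @param annotations optional annotation bundle; generated when NULL.
#' @return list of class `synev_gen_data`: `catalog` (classified),
#'   `features` (raw 35-slot table), `annotations`, `reference`
#'   (`synev_codon_ref`), `allele_counts`, `curated_keys`, and `truth`
#'   (data.frame `key`, `latent_effect`, `unobservable`, `p_seen`, `seen`).
#' @export
gen_variant_catalog <- function(transcripts, config, annotations = NULL) {
  catalog <- enumerate_catalog(transcripts)
  if (is.null(annotations))
    annotations <- gen_annotations(transcripts, config, catalog = catalog)
  reference <- build_reference(transcripts, annotations$expression)
  features <- assemble_features(catalog, transcripts, annotations, reference)

  set.seed(config$seed + 2L)
  w <- config$effect_weights
  missing_w <- setdiff(names(w), names(features))
  if (length(missing_w) > 0L)
    stop("effect weights name unknown features: ",
         paste(missing_w, collapse = ", "))
  Z <- vapply(names(w), function(nm) {
    x <- features[[nm]]
    x[is.na(x)] <- median(x, na.rm = TRUE)
    as.numeric(scale(x))
  }, numeric(nrow(features)))
  latent <- plogis(config$effect_intercept + as.numeric(Z %*% w))

  u_feat <- features[[config$unobservable_feature]]
  u_thresh <- quantile(u_feat, 1 - config$unobservable_frac, na.rm = TRUE)
  unobservable <- !is.na(u_feat) & u_feat > u_thresh

  lin <- -config$obs_slope * latent
  a0 <- .calibrate_intercept(lin[!unobservable],
                             config$seen_target / (1 - mean(unobservable)))
  p_seen <- plogis(a0 + lin)
  p_seen[unobservable] <- 0
  seen <- rbinom(length(p_seen), 1L, p_seen) == 1L
  noise <- !seen & runif(length(p_seen)) < config$noise_rate
  ac <- integer(length(p_seen))
  ac[seen] <- pmax(1L, as.integer(round(rlnorm(sum(seen),
                                               config$ac_meanlog,
                                               config$ac_sdlog))))
  ac[noise] <- 1L
  keys <- variant_key(catalog)
  reported <- seen | noise
  allele_counts <- data.frame(
    transcript_id = catalog$transcript_id[reported],
    codon_index = catalog$codon_index[reported],
    offset = catalog$offset[reported],
    alt_nt = catalog$alt_nt[reported],
    count = ac[reported], an = config$an, stringsAsFactors = FALSE)
  catalog <- classify_status(catalog, allele_counts, an_default = config$an)

  eligible <- which(!unobservable)
  top <- eligible[order(latent[eligible], decreasing = TRUE)]
  pool <- top[seq_len(min(length(top), 5L * config$n_curated))]
  curated_keys <- keys[sort(sample(pool, min(config$n_curated,
                                             length(pool))))]

  truth <- data.frame(key = keys, latent_effect = latent,
                      unobservable = unobservable, p_seen = p_seen,
                      seen = reported, stringsAsFactors = FALSE)
  structure(list(catalog = catalog, features = features,
                 annotations = annotations, reference = reference,
                 allele_counts = allele_counts,
                 curated_keys = curated_keys, truth = truth,
                 config = config),
            class = "synev_gen_data")
}

#' @export
print.synev_gen_data <- function(x, ...) {
  cat("<synev_gen_data>", nrow(x$catalog), "variants,",
      length(unique(x$catalog$transcript_id)), "transcripts\n")
  print(table(x$catalog$status))
  invisible(x)
}

#' Generate a divergence-scaled ortholog codon alignment
#'
#' For each species, synonymous single-nucleotide codon substitutions are
#' planted in a copy of the human CDS row with expected count proportional
#' to divergence time, plus whole-codon gaps at a configured rate; the human
#' row always equals the input CDS. In `mode = "monotone"` the substituted
#' variants for each species are drawn from a divergence-rank-dependent
#' quantile band of `site_scores`, so that more diverged species carry
#' higher-scoring variants (used to sanity-check the divergence-trend
#' statistic).
#'
#' @param transcript a `synev_transcript`.
#' @param species_divergences data.frame `species`, `divergence` (My).
#' @param config `synev_gen_config` (supplies `subst_rate`, `gap_rate`).
#' @param mode "uniform" or "monotone".
#' @param site_scores for `mode = "monotone"`: named numeric vector (variant
#'   key -> score) covering this transcript's sSNVs.
#' @return a `synev_alignment`.
#' @export
gen_ortholog_alignments <- function(transcript, species_divergences, config,
                                    mode = c("uniform", "monotone"),
                                    site_scores = NULL) {
  mode <- match.arg(mode)
  human <- transcript$codons
  n <- length(human)
  cat_tr <- enumerate_ssnvs(transcript)
  keys <- variant_key(cat_tr)
  if (mode == "monotone") {
    stopifnot(!is.null(site_scores), all(keys %in% names(site_scores)))
    ranks <- rank(site_scores[keys], ties.method = "first") / length(keys)
  }
  ord <- order(species_divergences$divergence)
  rows <- list(human = transcript$cds)
  S <- nrow(species_divergences)
  for (si in seq_len(S)) {
    sp <- species_divergences$species[ord[si]]
    div <- species_divergences$divergence[ord[si]]
    n_sub <- rpois(1, config$subst_rate * n * div / 100)
    cand <- seq_len(nrow(cat_tr))
    if (mode == "monotone") {
      lo <- (si - 1) / S
      hi <- si / S
      cand <- which(ranks > lo & ranks <= hi)
    }
    row <- human
    if (length(cand) > 0L && n_sub > 0L) {
      pick <- sample(cand, min(n_sub, length(cand)))
      # at most one substitution per codon; later picks at a taken codon drop
      pick <- pick[!duplicated(cat_tr$codon_index[pick])]
      row[cat_tr$codon_index[pick]] <- cat_tr$mut_codon[pick]
    }
    gap_at <- which(runif(n) < config$gap_rate)
    gap_at <- setdiff(gap_at, c(1L, n))
    row[gap_at] <- "---"
    rows[[sp]] <- paste(row, collapse = "")
  }
  codon_alignment(transcript$transcript_id, unlist(rows),
                  human_cds = transcript$cds)
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper: transcripts, annotations, classified catalog,
#' features, curated-effect keys and hidden truth under one seed.
#'
#' @param config `synev_gen_config`.
#' @return `synev_gen_data` with an extra `transcripts` element.
#' @export
gen_dataset <- function(config = generator_config()) {
  transcripts <- gen_transcripts(config)
  out <- gen_variant_catalog(transcripts, config)
  out$transcripts <- transcripts
  out
}
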