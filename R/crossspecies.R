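# Cross-species variation (CSV) analysis from codon-aware ortholog
# alignments: CSV extraction, codon mutation fraction, species-count
# grouping, divergence trends, and constraint-bin analysis.

#' Construct a codon alignment object
#'
#' A codon-aware multiple alignment of one human transcript and its
#' orthologs. Rows must be equal-length, gaps ("-") must occur in whole-codon
#' units, and the human row must reconstruct the CDS when gaps are removed.
#'
#' @param transcript_id human transcript identifier.
#' @param rows named character vector of aligned sequences; one name must be
#'   `"human"`.
#' @param human_cds optional CDS to validate the human row against.
#' @return object of class `synev_alignment` with fields `transcript_id`,
#'   `codons` (species x alignment-column codon matrix), `species` (non-human
#'   row names) and `human_map` (CDS codon index -> alignment column).
#' @export
codon_alignment <- function(transcript_id, rows, human_cds = NULL) {
  stopifnot("human" %in% names(rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length")
  if (widths[1] %% 3L != 0L) stop("alignment length not a multiple of 3")
  codons <- t(vapply(rows, split_codons,
                     character(widths[1] / 3L)))
  if (any(grepl("-", codons) & codons != "---"))
    stop("gaps must occur in whole-codon units")
  human <- codons["human", ]
  if (!is.null(human_cds) &&
      paste(human[human != "---"], collapse = "") != toupper(human_cds))
    stop("human alignment row does not reconstruct the CDS")
  human_map <- which(human != "---")
  structure(list(transcript_id = transcript_id, codons = codons,
                 species = setdiff(names(rows), "human"),
                 human_map = human_map),
            class = "synev_alignment")
}

#' @export
print.synev_alignment <- function(x, ...) {
  cat("<synev_alignment>", x$transcript_id, "-", length(x$species),
      "species,", ncol(x$codons), "codon columns\n")
  invisible(x)
}

#' Codon mutation fraction of a variant in an alignment column
#'
#' How common the variant's (alternative) codon is compared to the human
#' reference codon among the aligned orthologs: the count of ortholog codons
#' equal to the mutant codon divided by the combined count of mutant and
#' reference codons in the column. Gap codons are excluded from all counts.
#' On a column of 10 reference (CCC), 5 mutant (CCT) and 5 other codons the
#' CMF of CCC>CCT is 5/15 = 0.33. Undefined (NA) when the column carries no
#' non-reference codon at all.
#'
#' @param column character vector of ortholog codons at the aligned position
#'   (gaps as "---").
#' @param ref_codon human reference codon.
#' @param mut_codon variant codon.
#' @return numeric CMF in [0, 1], or NA when undefined.
#' @examples
#' cmf(c(rep("CCC", 10), rep("CCT", 5), rep("CCA", 5)), "CCC", "CCT")
#' @export
cmf <- function(column, ref_codon, mut_codon) {
  column <- column[column != "---"]
  if (sum(column != ref_codon) == 0L) return(NA_real_)
  n_mut <- sum(column == mut_codon)
  n_ref <- sum(column == ref_codon)
  n_mut / (n_mut + n_ref)
}

#' Extract cross-species variations for a transcript's sSNVs
#'
#' A human sSNV is a CSV of a species when the species' aligned codon equals
#' the variant's mutant codon (full-codon match); species with a gap codon at
#' the column are excluded from both CSV calls and CMF counts.
#'
#' @param alignment a `synev_alignment`.
#' @param human_ssnvs variant catalog rows for the alignment's transcript.
#' @return data.frame `key`, `n_species`, `unique_flag`, `cmf`, plus a
#'   list-column `species` with the CSV species sets.
#' @export
extract_csvs <- function(alignment, human_ssnvs) {
  stopifnot(all(human_ssnvs$transcript_id == alignment$transcript_id))
  keys <- variant_key(human_ssnvs)
  n <- nrow(human_ssnvs)
  species_sets <- vector("list", n)
  cmf_vals <- numeric(n)
  for (v in seq_len(n)) {
    col_idx <- alignment$human_map[human_ssnvs$codon_index[v]]
    column <- alignment$codons[alignment$species, col_idx]
    ok <- column != "---"
    species_sets[[v]] <-
      alignment$species[ok & column == human_ssnvs$mut_codon[v]]
    cmf_vals[v] <- cmf(column, human_ssnvs$wt_codon[v],
                       human_ssnvs$mut_codon[v])
  }
  out <- data.frame(key = keys, n_species = lengths(species_sets),
                    unique_flag = lengths(species_sets) == 1L,
                    cmf = cmf_vals, stringsAsFactors = FALSE)
  out$species <- species_sets
  out
}

#' Extract CSVs across many alignments
#' @param alignments list of `synev_alignment` objects (named by transcript).
#' @param catalog variant catalog covering the alignments' transcripts.
#' @return combined CSV record data.frame ([extract_csvs()]).
#' @export
extract_csvs_all <- function(alignments, catalog) {
  parts <- lapply(alignments, function(aln)
    extract_csvs(aln, catalog[catalog$transcript_id == aln$transcript_id, ,
                              drop = FALSE]))
  do.call(rbind, parts)
}

#' Species-count group per variant
#'
#' The number of species carrying the variant's mutant codon; 0 for
#' non-CSVs.
#'
#' @param csv_records data.frame from [extract_csvs()].
#' @return named integer vector (variant key -> species count).
#' @export
species_count_group <- function(csv_records) {
  setNames(csv_records$n_species, csv_records$key)
}

#' Median effect score per species versus divergence time
#'
#' Restricted to species-unique CSVs (variants found in exactly one
#' species), reports the median score per species against log2 million years
#' since divergence, plus the Spearman rank correlation. Species without
#' unique CSVs are omitted with a message; constant scores give an NA
#' correlation.
#'
#' @param scores named numeric vector (variant key -> effect score).
#' @param csv_records data.frame from [extract_csvs()].
#' @param divergences data.frame `species`, `divergence` (million years).
#' @return list `table` (species, n, median_score, log2_divergence) and
#'   `spearman`.
#' @export
divergence_trend <- function(scores, csv_records, divergences) {
  stopifnot(all(divergences$divergence > 0))
  uni <- csv_records[csv_records$unique_flag, , drop = FALSE]
  uni$species_one <- vapply(uni$species, `[[`, character(1), 1L)
  tab <- do.call(rbind, lapply(divergences$species, function(sp) {
    k <- uni$key[uni$species_one == sp]
    k <- k[k %in% names(scores)]
    if (length(k) == 0L) return(NULL)
    data.frame(species = sp, n = length(k),
               median_score = median(scores[k]),
               log2_divergence =
                 log2(divergences$divergence[divergences$species == sp]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab) || nrow(tab) < 2L)
    stop("fewer than two species with unique CSVs")
  omitted <- setdiff(divergences$species, tab$species)
  if (length(omitted) > 0L)
    message("species without unique CSVs omitted: ",
            paste(omitted, collapse = ", "))
  rho <- if (sd(tab$median_score) == 0) NA_real_ else
    cor(tab$median_score, tab$log2_divergence, method = "spearman")
  list(table = tab, spearman = rho)
}

#' Constraint-bin analysis of observation sparsity and effect scores
#'
#' Groups variants by constraint percentile bin and reports, per bin, the
#' fraction of observed sSNVs among all possible sSNVs and the median effect
#' score of the observed ones, plus Pearson correlations of both against the
#' bin midpoint. Empty bins are omitted.
#'
#' @param status character vector of variant statuses.
#' @param scores numeric effect scores (same length).
#' @param ccr_percentiles numeric constraint percentiles in [0, 100].
#' @param n_bins number of equal-width percentile bins.
#' @return list `table` (bin midpoint, n, observed_fraction,
#'   median_observed_score) and `cor_fraction`, `cor_score` (Pearson).
#' @export
ccr_bin_analysis <- function(status, scores, ccr_percentiles, n_bins = 10L) {
  stopifnot(length(status) == length(scores),
            length(status) == length(ccr_percentiles))
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  bin <- cut(ccr_percentiles, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  tab <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    in_bin <- which(as.integer(bin) == b)
    if (length(in_bin) == 0L) return(NULL)
    obs <- in_bin[status[in_bin] == "observed"]
    data.frame(percentile_mid = mids[b], n = length(in_bin),
               observed_fraction = length(obs) / length(in_bin),
               median_observed_score =
                 if (length(obs) > 0L) median(scores[obs]) else NA_real_)
  }))
  ok <- !is.na(tab$median_observed_score)
  safe_cor <- function(x, y)
    if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  list(table = tab,
       cor_fraction = safe_cor(tab$percentile_mid, tab$observed_fraction),
       cor_score = safe_cor(tab$percentile_mid[ok],
                            tab$median_observed_score[ok]))
}

#' Read codon-gapped alignment FASTA files
#'
#' One file per transcript; record names are species, one record must be
#' `human`.
#'
#' @param path FASTA path.
#' @param transcript_id transcript identifier (defaults to the file name).
#' @param human_cds optional CDS for validation.
#' @return a `synev_alignment`.
#' @export
read_alignment_fasta <- function(path, transcript_id =
                                   sub("\\.[^.]*$", "", basename(path)),
                                 human_cds = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed alignment FASTA (record 1 has no header)")
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  rows <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  names(rows) <- id
  codon_alignment(transcript_id, rows, human_cds = human_cds)
}

#' Write a codon alignment as gapped FASTA
#' @param alignment a `synev_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in rownames(alignment$codons)) {
    writeLines(paste0(">", sp), con)
    writeLines(paste(alignment$codons[sp, ], collapse = ""), con)
  }
  invisible(path)
}
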