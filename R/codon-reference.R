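#' Build a codon usage reference from highly expressed transcripts
#'
#' Reference-based codon bias measures (CAI, fracOpt, CUB, tAI) need a
#' reference set of codons from highly expressed genes. For each tissue the
#' top `top_fraction` of transcripts by expression (ceiling rule) are
#' selected; the reference set is the union over tissues. Relative
#' adaptiveness weights are codon counts normalised within each synonymous
#' family so the most frequent codon has weight 1; codons never seen in the
#' reference are given a pseudo-count of 0.5 before normalisation so weights
#' stay positive.
#'
#' @param transcripts named list of `synev_transcript` objects.
#' @param expression_matrix numeric matrix, transcripts x tissues (row names
#'   are transcript ids). Transcripts absent from the matrix are excluded from
#'   the reference with a warning.
#' @param top_fraction fraction of transcripts taken per tissue (default 0.01).
#' @param trna_weights optional named numeric vector codon -> tRNA
#'   availability weight in (0,1] for tAI; defaults to the bundled synthetic
#'   proxy table (see [read_trna_weights()]).
#' @return object of class `synev_codon_ref`: list with `table` (data.frame
#'   codon / amino_acid / count / weight / optimal_flag / trna_weight),
#'   `weights` and `trna_weights` (named vectors), `optimal` (named list,
#'   amino acid -> optimal codon set) and `reference_ids`.
#' @export
build_reference <- function(transcripts, expression_matrix,
                            top_fraction = 0.01, trna_weights = NULL) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  in_mat <- ids %in% rownames(expression_matrix)
  if (!all(in_mat)) {
    warning(sum(!in_mat), " transcript(s) absent from expression matrix, ",
            "excluded from reference")
    transcripts <- transcripts[in_mat]
    ids <- ids[in_mat]
  }
  if (length(transcripts) == 0L) stop("empty reference set")
  n_top <- ceiling(top_fraction * length(ids))
  ref_ids <- unique(unlist(lapply(seq_len(ncol(expression_matrix)),
    function(j) {
      expr <- expression_matrix[ids, j]
      ids[order(expr, decreasing = TRUE)[seq_len(n_top)]]
    })))
  counts <- setNames(numeric(length(.GENETIC_CODE)), names(.GENETIC_CODE))
  for (id in ref_ids) {
    tab <- table(transcripts[[id]]$codons)
    counts[names(tab)] <- counts[names(tab)] + tab
  }
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  aa <- .GENETIC_CODE[sense]
  adj <- counts[sense]
  adj[adj == 0] <- 0.5
  weights <- unlist(lapply(split(adj, aa[names(adj)]),
                           function(x) x / max(x)))
  names(weights) <- unlist(lapply(split(names(adj), aa[names(adj)]),
                                  identity))
  weights <- weights[sense]
  optimal <- lapply(split(adj, aa[names(adj)]), function(x) {
    names(x)[x == max(x)]
  })
  if (is.null(trna_weights)) trna_weights <- read_trna_weights()
  trna_weights <- trna_weights[sense]
  tab <- data.frame(
    codon = sense, amino_acid = unname(aa), count = unname(counts[sense]),
    weight = unname(weights),
    optimal_flag = vapply(sense, function(cd)
      cd %in% optimal[[.GENETIC_CODE[[cd]]]], logical(1)),
    trna_weight = unname(trna_weights), stringsAsFactors = FALSE)
  structure(list(table = tab, weights = weights, trna_weights = trna_weights,
                 optimal = optimal, reference_ids = ref_ids),
            class = "synev_codon_ref")
}

#' @export
print.synev_codon_ref <- function(x, ...) {
  cat("<synev_codon_ref> built from", length(x$reference_ids),
      "reference transcript(s)\n")
  invisible(x)
}

#' Read per-codon tRNA availability weights
#'
#' Two-column TSV (codon, trna_weight). The bundled default
#' (`inst/extdata/trna_weights_synthetic.tsv`) is a synthetic proxy table --
#' a seeded draw standing in for genomic tRNA gene-copy-number data -- meant
#' for testing; supply your organism's table for real analyses.
#'
#' @param path TSV path; default is the bundled synthetic table.
#' @return named numeric vector (codon -> weight in (0,1]).
#' @export
read_trna_weights <- function(path = system.file(
  "extdata", "trna_weights_synthetic.tsv", package = "synev")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  w <- setNames(tab$trna_weight, tab$codon)
  if (any(w <= 0 | w > 1)) stop("tRNA weights must lie in (0, 1]")
  w
}

#' Write a codon usage reference to TSV
#' @param reference a `synev_codon_ref`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  write.table(reference$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
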