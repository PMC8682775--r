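#' Canonical variant key
#'
#' One key per (transcript, codon, offset, alternative base); used to join
#' variant catalogs with allele-count tables, feature matrices and scores.
#'
#' @param catalog a variant catalog data.frame (or any data.frame with columns
#'   `transcript_id`, `codon_index`, `offset`, `alt_nt`).
#' @return character vector of keys.
#' @export
variant_key <- function(catalog) {
  paste(catalog$transcript_id, catalog$codon_index, catalog$offset,
        catalog$alt_nt, sep = ":")
}

#' Enumerate all synonymous single-nucleotide variants of a transcript
#'
#' Every single-base substitution of the CDS that leaves the translated
#' protein unchanged is reported, with codon bookkeeping. Output order is
#' deterministic: by codon index, then within-codon offset, then alternative
#' base alphabetically.
#'
#' @param transcript a `synev_transcript`.
#' @param include_stop_codon also enumerate synonymous stop-codon exchanges
#'   (TAA/TAG/TGA); off by default, keeping "synonymous" at protein-sequence
#'   semantics.
#' @return data.frame with columns `transcript_id`, `codon_index` (1-based),
#'   `offset` (1-3 within codon), `ref_nt`, `alt_nt`, `wt_codon`, `mut_codon`,
#'   `status` (initialised `"generated"`), `allele_count` (0), `maf` (0).
#' @examples
#' tr <- validate_transcript("t1", "ATGGGGTAA")
#' enumerate_ssnvs(tr)
#' @export
enumerate_ssnvs <- function(transcript, include_stop_codon = FALSE) {
  stopifnot(inherits(transcript, "synev_transcript"))
  codons <- transcript$codons
  n <- length(codons)
  keep_codon <- if (include_stop_codon) seq_len(n) else seq_len(n - 1L)
  rows <- vector("list", 64L)
  k <- 0L
  for (i in keep_codon) {
    wt <- codons[i]
    aa <- .GENETIC_CODE[[wt]]
    wt_bases <- strsplit(wt, "")[[1]]
    for (off in 1:3) {
      for (alt in .BASES) {
        if (alt == wt_bases[off]) next
        mb <- wt_bases
        mb[off] <- alt
        mut <- paste(mb, collapse = "")
        if (.GENETIC_CODE[[mut]] != aa) next
        k <- k + 1L
        if (k > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[k]] <- list(i, off, wt_bases[off], alt, wt, mut)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(transcript_id = character(), codon_index = integer(),
                      offset = integer(), ref_nt = character(),
                      alt_nt = character(), wt_codon = character(),
                      mut_codon = character(), status = character(),
                      allele_count = integer(), maf = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- rows[seq_len(k)]
  data.frame(
    transcript_id = transcript$transcript_id,
    codon_index = vapply(rows, function(r) r[[1]], integer(1)),
    offset = vapply(rows, function(r) r[[2]], integer(1)),
    ref_nt = vapply(rows, function(r) r[[3]], character(1)),
    alt_nt = vapply(rows, function(r) r[[4]], character(1)),
    wt_codon = vapply(rows, function(r) r[[5]], character(1)),
    mut_codon = vapply(rows, function(r) r[[6]], character(1)),
    status = "generated", allele_count = 0L, maf = 0,
    stringsAsFactors = FALSE)
}

#' Enumerate sSNVs across a transcript set
#' @param transcripts list of `synev_transcript` objects.
#' @inheritParams enumerate_ssnvs
#' @return combined variant catalog data.frame.
#' @export
enumerate_catalog <- function(transcripts, include_stop_codon = FALSE) {
  do.call(rbind, lapply(transcripts, enumerate_ssnvs,
                        include_stop_codon = include_stop_codon))
}

#' Classify catalog variants by allele count
#'
#' Variants carried by two or more individuals are `observed`, by exactly one
#' are `singleton`, and variants absent from the allele-count table remain
#' `generated`. Minor allele frequency is taken from the table when present
#' (`an` column: total allele number) and variants with MAF > `common_maf`
#' can later be treated as common.
#'
#' @param catalog variant catalog from [enumerate_catalog()].
#' @param allele_counts data.frame with columns `transcript_id`,
#'   `codon_index`, `offset`, `alt_nt`, `count` (individuals carrying the
#'   allele) and optionally `an` (total alleles, for MAF).
#' @param an_default total allele number used for MAF when `an` is absent.
#' @return the catalog with `status`, `allele_count` and `maf` filled in, and
#'   attribute `"partition"` holding the [variant_partition()] object.
#' @export
classify_status <- function(catalog, allele_counts, an_default = 20000L) {
  key <- variant_key(catalog)
  ckey <- variant_key(allele_counts)
  miss <- setdiff(ckey, key)
  if (length(miss) > 0L)
    stop("allele-count key(s) not in catalog: ",
         paste(head(miss, 3L), collapse = ", "))
  idx <- match(ckey, key)
  catalog$status <- "generated"
  catalog$allele_count <- 0L
  catalog$allele_count[idx] <- as.integer(allele_counts$count)
  an <- if ("an" %in% names(allele_counts)) allele_counts$an else an_default
  catalog$maf <- 0
  catalog$maf[idx] <- pmin(allele_counts$count / an, 0.5)
  catalog$status[catalog$allele_count == 1L] <- "singleton"
  catalog$status[catalog$allele_count >= 2L] <- "observed"
  attr(catalog, "partition") <- variant_partition(catalog)
  catalog
}

#' Build a variant partition from a catalog
#'
#' The partition tracks the evolving, pairwise-disjoint status sets over the
#' catalog (observed / singleton / generated, later refined to not_seen /
#' unobservable) along with a provenance log of every reassignment.
#'
#' @param catalog a variant catalog with a `status` column.
#' @return object of class `synev_partition`: list with `sets` (named list of
#'   integer row indices), `n` (catalog size) and `log` (data.frame stage /
#'   from / to / n).
#' @export
variant_partition <- function(catalog) {
  sets <- split(seq_len(nrow(catalog)), catalog$status)
  structure(list(sets = sets, n = nrow(catalog),
                 log = data.frame(stage = character(), from = character(),
                                  to = character(), n = integer(),
                                  stringsAsFactors = FALSE)),
            class = "synev_partition")
}

#' Reassign catalog rows between partition sets
#' @param partition a `synev_partition`.
#' @param idx integer row indices to move.
#' @param from,to set names.
#' @param stage provenance label for the log.
#' @return the updated partition.
#' @export
partition_move <- function(partition, idx, from, to, stage) {
  if (length(idx) == 0L) return(partition)
  cur <- partition$sets[[from]]
  if (!all(idx %in% cur))
    stop("rows to move are not all in set '", from, "'")
  partition$sets[[from]] <- setdiff(cur, idx)
  partition$sets[[to]] <- sort(c(partition$sets[[to]], idx))
  partition$log <- rbind(partition$log,
                         data.frame(stage = stage, from = from, to = to,
                                    n = length(idx), stringsAsFactors = FALSE))
  partition
}

#' @export
print.synev_partition <- function(x, ...) {
  cat("<synev_partition> of", x$n, "variants\n")
  for (nm in names(x$sets))
    cat(sprintf("  %-12s %d\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Check partition invariants (disjoint, exhaustive)
#' @param partition a `synev_partition`.
#' @return TRUE, or an error describing the violated invariant.
#' @export
partition_validate <- function(partition) {
  all_idx <- sort(unlist(partition$sets, use.names = FALSE))
  if (anyDuplicated(all_idx)) stop("partition sets are not disjoint")
  if (!identical(all_idx, seq_len(partition$n)))
    stop("partition sets do not cover the catalog")
  TRUE
}
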