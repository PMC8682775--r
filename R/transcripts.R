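#' Validate a coding sequence into a transcript record
#'
#' A transcript is accepted only if its CDS uses the ACGT alphabet, has length
#' a multiple of 3, starts with ATG, ends with a stop codon and carries no
#' internal stop codon. Sequences failing any rule are rejected with a typed
#' reason, mirroring the usual CDS hygiene filters applied before exhaustive
#' variant enumeration.
#'
#' @param raw_id transcript identifier (FASTA header).
#' @param raw_seq nucleotide string; case-insensitive.
#' @param gene_id optional gene identifier (defaults to `raw_id`).
#' @param exon_blocks optional data.frame (chrom, start, end) of genomic
#'   exon intervals, 0-based half-open.
#' @param strand "+" or "-".
#' @param tissue_expression optional named numeric vector of per-tissue
#'   expression (TPM-like).
#' @return an object of class `synev_transcript` (a list with fields
#'   `transcript_id`, `gene_id`, `cds`, `codons`, `exon_blocks`, `strand`,
#'   `tissue_expression`), or, when the sequence violates a rule, an object of
#'   class `synev_rejection` with fields `transcript_id` and `reason` (one of
#'   `"non_acgt"`, `"length_not_multiple_of_3"`, `"missing_start"`,
#'   `"missing_stop"`, `"internal_stop"`).
#' @examples
#' validate_transcript("t1", "ATGGGGTAA")
#' validate_transcript("bad", "ATGNNGTAA")$reason
#' @export
validate_transcript <- function(raw_id, raw_seq, gene_id = raw_id,
                                exon_blocks = NULL, strand = "+",
                                tissue_expression = NULL) {
  stopifnot(is.character(raw_id), length(raw_id) == 1L,
            is.character(raw_seq), length(raw_seq) == 1L, nzchar(raw_seq))
  seq <- toupper(raw_seq)
  reject <- function(reason) {
    structure(list(transcript_id = raw_id, reason = reason),
              class = "synev_rejection")
  }
  if (grepl("[^ACGT]", seq)) return(reject("non_acgt"))
  if (nchar(seq) %% 3L != 0L) return(reject("length_not_multiple_of_3"))
  codons <- split_codons(seq)
  if (codons[1] != "ATG") return(reject("missing_start"))
  n <- length(codons)
  if (!(codons[n] %in% .STOP_CODONS)) return(reject("missing_stop"))
  if (n > 2L && any(codons[2:(n - 1L)] %in% .STOP_CODONS))
    return(reject("internal_stop"))
  structure(list(transcript_id = raw_id, gene_id = gene_id, cds = seq,
                 codons = codons, exon_blocks = exon_blocks, strand = strand,
                 tissue_expression = tissue_expression),
            class = "synev_transcript")
}

#' @export
print.synev_transcript <- function(x, ...) {
  cat("<synev_transcript>", x$transcript_id, "-", length(x$codons),
      "codons\n")
  invisible(x)
}

#' @export
print.synev_rejection <- function(x, ...) {
  cat("<synev_rejection>", x$transcript_id, "-", x$reason, "\n")
  invisible(x)
}

#' Test whether an object is a rejected transcript
#' @param x object returned by [validate_transcript()].
#' @return logical
#' @export
is_rejection <- function(x) inherits(x, "synev_rejection")

#' Read coding sequences from a FASTA file
#'
#' Headers (up to the first whitespace) become transcript identifiers. Each
#' record is passed through [validate_transcript()]; rejected records are
#' dropped with a warning naming the violated rule.
#'
#' @param path FASTA file of CDSs, one record per transcript.
#' @param keep_rejected if TRUE, return a list with both accepted transcripts
#'   and rejections; otherwise return accepted transcripts only.
#' @return named list of `synev_transcript` objects (or a list with elements
#'   `transcripts` and `rejections` when `keep_rejected = TRUE`).
#' @export
read_cds_fasta <- function(path, keep_rejected = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA (record 1 has no header): ", path)
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- unname(vapply(split(lines[!hdr], grp[!hdr]),
                        function(x) paste(x, collapse = ""), character(1)))
  if (length(seqs) != length(id)) stop("FASTA record without sequence: ", path)
  out <- lapply(seq_along(id), function(i) validate_transcript(id[i], seqs[i]))
  names(out) <- id
  rej <- vapply(out, is_rejection, logical(1))
  if (any(rej)) {
    reasons <- vapply(out[rej], function(x) x$reason, character(1))
    warning(sum(rej), " transcript(s) rejected: ",
            paste(paste0(id[rej], " (", reasons, ")"), collapse = ", "))
  }
  if (keep_rejected) list(transcripts = out[!rej], rejections = out[rej])
  else out[!rej]
}

#' Write transcripts to a FASTA file
#' @param transcripts list of `synev_transcript` objects.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in transcripts) {
    writeLines(paste0(">", tr$transcript_id), con)
    s <- tr$cds
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
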