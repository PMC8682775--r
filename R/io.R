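# Lossless readers/writers for the pipeline's file formats, plus the staged
# pipeline driver. All tabular formats are plain TSV; the feature matrix
# carries a JSON sidecar with the schema and fitted encoder parameters.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a variant catalog TSV
#'
#' Columns: transcript_id, codon_index, offset, ref_nt, alt_nt, wt_codon,
#' mut_codon, status, allele_count, maf.
#'
#' @param catalog variant catalog data.frame.
#' @param path file path.
#' @return `write_catalog()`: the path, invisibly; `read_catalog()`: the
#'   catalog data.frame.
#' @export
write_catalog <- function(catalog, path) {
  .write_tsv(catalog[, c("transcript_id", "codon_index", "offset", "ref_nt",
                         "alt_nt", "wt_codon", "mut_codon", "status",
                         "allele_count", "maf")], path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "codon_index", "offset", "ref_nt", "alt_nt",
            "wt_codon", "mut_codon", "status", "allele_count", "maf")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("catalog TSV missing column(s): ", paste(miss, collapse = ", "))
  for (nm in c("transcript_id", "ref_nt", "alt_nt", "wt_codon", "mut_codon",
               "status"))
    df[[nm]] <- as.character(df[[nm]])
  df
}

#' Write / read a feature table with its JSON schema sidecar
#'
#' The sidecar (`<path>.json`) freezes the slot schema and, when an encoder
#' is supplied, its vocabularies and standardisation moments, so matrices
#' round-trip losslessly and prediction-time encoding reuses the training
#' parameters.
#'
#' @param features raw feature table from [assemble_features()].
#' @param path TSV path.
#' @param encoder optional `synev_encoder`.
#' @return `write_features()`: the path, invisibly; `read_features()`: list
#'   `features`, `schema`, `encoder` (NULL when absent from the sidecar).
#' @export
write_features <- function(features, path, encoder = NULL) {
  .write_tsv(features, path)
  sidecar <- list(schema = feature_schema())
  if (!is.null(encoder))
    sidecar$encoder <- list(moments = encoder$moments,
                            vocab = encoder$vocab)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  features <- read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(key = "character"))
  schema <- feature_schema()
  for (nm in schema$name[schema$type == "categorical"])
    features[[nm]] <- as.character(features[[nm]])
  side_path <- paste0(path, ".json")
  encoder <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$encoder)) {
      moments <- lapply(side$encoder$moments, function(m)
        list(median = m$median, mean = m$mean, sd = m$sd))
      encoder <- structure(list(schema = schema, moments = moments,
                                vocab = lapply(side$encoder$vocab,
                                               as.character)),
                           class = "synev_encoder")
    }
  }
  list(features = features, schema = schema, encoder = encoder)
}

#' Write / read BED-like site intervals
#'
#' Transcript-local, 0-based half-open intervals, one row per interval with
#' columns transcript_id, start, end, class.
#'
#' @param sites nested list `sites[[class]][[transcript_id]]` of data.frames
#'   with `start`, `end`.
#' @param path file path.
#' @return `write_bed_sites()`: the path, invisibly; `read_bed_sites()`: the
#'   nested site list.
#' @export
write_bed_sites <- function(sites, path) {
  rows <- list()
  for (cls in names(sites)) {
    for (tid in names(sites[[cls]])) {
      iv <- sites[[cls]][[tid]]
      if (is.null(iv) || nrow(iv) == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(transcript_id = tid, start = iv$start, end = iv$end,
                   class = cls, stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_bed_sites
#' @export
read_bed_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$class), function(d)
    lapply(split(d[, c("start", "end")], d$transcript_id), function(x) {
      rownames(x) <- NULL
      x[order(x$start), , drop = FALSE]
    }))
  out
}

#' Write a PUL trace, score table or truth table as TSV
#' @param df data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_trace <- function(df, path) .write_tsv(df, path)

#' @rdname write_trace
#' @export
read_trace <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Read a VCF-lite variant table onto transcript coordinates
#'
#' Minimal VCF reader (CHROM, POS, REF, ALT columns plus `AC=`/`AN=` INFO
#' keys) that projects genomic positions onto transcript CDS coordinates
#' through each transcript's exon blocks (0-based half-open, strand-aware:
#' minus-strand transcripts read their CDS off the reverse complement).
#' Returns an allele-count table suitable for [classify_status()].
#'
#' @param path VCF(-lite) file; header lines start with `#`.
#' @param transcripts named list of `synev_transcript` objects carrying
#'   `exon_blocks` and `strand`.
#' @return data.frame transcript_id, codon_index, offset, alt_nt, count, an.
#' @export
read_vcf_lite <- function(path, transcripts) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(transcript_id = character(), codon_index = integer(),
                      offset = integer(), alt_nt = character(),
                      count = integer(), an = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (f in fields) {
    chrom <- f[1]; pos <- as.integer(f[2])
    ref <- toupper(f[4]); alt <- toupper(f[5])
    info <- if (length(f) >= 8L) f[8] else ""
    ac <- sub(".*AC=([0-9]+).*", "\\1", info)
    an <- sub(".*AN=([0-9]+).*", "\\1", info)
    ac <- if (grepl("^[0-9]+$", ac)) as.integer(ac) else 1L
    an <- if (grepl("^[0-9]+$", an)) as.integer(an) else NA_integer_
    if (nchar(ref) != 1L || nchar(alt) != 1L) next
    for (tr in transcripts) {
      if (is.null(tr$exon_blocks)) next
      eb <- tr$exon_blocks[tr$exon_blocks$chrom == chrom, , drop = FALSE]
      if (nrow(eb) == 0L) next
      eb <- eb[order(eb$start), , drop = FALSE]
      hit <- which(pos - 1L >= eb$start & pos - 1L < eb$end)
      if (length(hit) == 0L) next
      before <- if (hit > 1L) sum(eb$end[seq_len(hit - 1L)] -
                                    eb$start[seq_len(hit - 1L)]) else 0L
      cds_pos <- before + (pos - 1L - eb$start[hit]) + 1L  # 1-based, + strand
      alt_t <- alt
      if (tr$strand == "-") {
        total <- sum(eb$end - eb$start)
        cds_pos <- total - cds_pos + 1L
        alt_t <- comp[[alt]]
      }
      if (cds_pos < 1L || cds_pos > nchar(tr$cds)) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tr$transcript_id,
        codon_index = (cds_pos - 1L) %/% 3L + 1L,
        offset = (cds_pos - 1L) %% 3L + 1L,
        alt_nt = alt_t, count = ac, an = an, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("no VCF record mapped onto the supplied transcripts")
  do.call(rbind, rows)
}

#' Run the staged pipeline end to end
#'
#' enumerate -> featurize -> pul -> intermediate -> relabel -> final ->
#' predict, writing catalog, features, trace and score TSVs plus a JSON
#' manifest (inputs, seed, package version) under `out_dir`. Inputs can be
#' file paths or in-memory objects from the generator.
#'
#' @param transcripts named list of `synev_transcript` objects, or a CDS
#'   FASTA path.
#' @param allele_counts allele-count data.frame, or a TSV path.
#' @param curated_keys character vector of curated-effect variant keys.
#' @param out_dir output directory (created if needed).
#' @param annotations optional annotation bundle (NULL: null-annotation
#'   fallback -- unknown categories, imputed continuous slots).
#' @param expression_matrix optional transcripts x tissues matrix (required
#'   when `annotations` is NULL, to build the codon usage reference).
#' @param config `synev_pul_config`.
#' @param grid hyperparameter grid.
#' @param seed integer seed.
#' @return the fitted `synev` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(transcripts, allele_counts, curated_keys, out_dir,
                         annotations = NULL, expression_matrix = NULL,
                         config = pul_config(), grid = model_grid(),
                         seed = config$seed) {
  if (is.character(transcripts)) transcripts <- read_cds_fasta(transcripts)
  if (is.character(allele_counts))
    allele_counts <- read.delim(allele_counts, stringsAsFactors = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(expression_matrix)) {
    if (is.null(annotations))
      stop("need an annotation bundle or an expression matrix")
    expression_matrix <- annotations$expression
  }
  catalog <- enumerate_catalog(transcripts)
  catalog <- classify_status(catalog, allele_counts)
  reference <- build_reference(transcripts, expression_matrix)
  features <- assemble_features(catalog, transcripts, annotations, reference,
                                expression_matrix = expression_matrix)
  fit <- synev(catalog, features, curated_keys, config = config,
               grid = grid, seed = seed)
  write_catalog(fit$catalog, file.path(out_dir, "catalog.tsv"))
  write_features(features, file.path(out_dir, "features.tsv"),
                 encoder = fit$encoder)
  write_trace(fit$pul$trace, file.path(out_dir, "pul_trace.tsv"))
  write_trace(fit$scores, file.path(out_dir, "scores.tsv"))
  saveRDS(fit, file.path(out_dir, "model.rds"))
  manifest <- list(
    package = "synev",
    version = as.character(utils::packageVersion("synev")),
    seed = seed, n_transcripts = length(transcripts),
    n_variants = nrow(catalog),
    partition = as.list(lengths(fit$partition$sets)),
    cutoffs = as.list(fit$cutoffs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
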