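# Standard genetic code and codon helpers shared across the package.
# Codons are uppercase DNA triplets; stops translate to "*".

.BASES <- c("A", "C", "G", "T")

.genetic_code_table <- function() {
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  code[sort(names(code))]
}

.GENETIC_CODE <- .genetic_code_table()
.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]

# amino acids encoded by a single codon are skipped by reference-free bias sums
.SINGLE_CODON_AA <- c("M", "W")

#' Split a CDS into codons
#' @param seq coding sequence (single character string, length divisible by 3)
#' @return character vector of codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate codons to amino acids (standard code)
#' @param codons character vector of codons
#' @return character vector of one-letter amino acids, "*" for stop
#' @keywords internal
translate_codons <- function(codons) {
  aa <- .GENETIC_CODE[codons]
  if (anyNA(aa)) stop("unknown codon: ", codons[which(is.na(aa))[1]])
  unname(aa)
}

#' Synonymous codon family of a codon
#' @param codon a codon string
#' @return character vector of all codons encoding the same amino acid
#' @keywords internal
codon_family <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  names(.GENETIC_CODE)[.GENETIC_CODE == aa]
}
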