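# hand-built 3-species toy alignment around the CDS ATG CCC AAA TAA
toy_alignment <- function() {
  codon_alignment("t1", c(
    human = "ATGCCCAAATAA",
    chimp = "ATGCCTAAATAA",   # CCC -> CCT at codon 2
    mouse = "ATG---AAGTAA",   # gap at codon 2, AAA -> AAG at codon 3
    frog  = "ATGCCGAAGTAA"),  # CCC -> CCG, AAA -> AAG
    human_cds = "ATGCCCAAATAA")
}

test_that("codon alignments validate row structure and reconstruct the CDS",
{
  aln <- toy_alignment()
  expect_equal(ncol(aln$codons), 4L)
  expect_setequal(aln$species, c("chimp", "mouse", "frog"))
  expect_error(codon_alignment("x", c(human = "ATGCC", chimp = "ATGCC")),
               "not a multiple of 3")
  expect_error(codon_alignment("x", c(human = "ATGC--CAA", chimp =
                                        "ATGCCCAAA")),
               "whole-codon")
  expect_error(codon_alignment("x", c(human = "ATGCCCAAA"),
                               human_cds = "ATGAAACCC"),
               "reconstruct")
})

test_that("CMF matches the printed worked example and the counting oracle", {
  # 10 reference, 5 mutant, 5 other: 5 / (5 + 10)
  column <- c(rep("CCC", 10), rep("CCT", 5), rep("CCA", 3), rep("CCG", 2))
  expect_equal(round(cmf(column, "CCC", "CCT"), 2), 0.33)
  expect_equal(cmf(column, "CCC", "CCT"), 5 / 15)
  # mutant dominates the column
  expect_equal(cmf(c(rep("CCC", 5), rep("CCT", 15)), "CCC", "CCT"), 0.75)
  # column of only mutant codons: upper bound 1
  expect_equal(cmf(rep("CCT", 12), "CCC", "CCT"), 1)
  # gaps excluded from both counts
  expect_equal(cmf(c("CCC", "CCT", "---", "---"), "CCC", "CCT"), 0.5)
  # no non-reference codons: undefined
  expect_true(is.na(cmf(c("CCC", "CCC", "---"), "CCC", "CCT")))
  # random columns against a plain counting oracle
  set.seed(55)
  fam <- c("CCC", "CCT", "CCA", "CCG", "---")
  for (i in 1:25) {
    col <- sample(fam, 20, replace = TRUE)
    got <- cmf(col, "CCC", "CCT")
    nog <- col[col != "---"]
    nr <- sum(nog != "CCC")
    want <- if (nr == 0) NA_real_ else
      sum(nog == "CCT") / (sum(nog == "CCT") + sum(nog == "CCC"))
    expect_equal(got, want)
    # the most common alternative codon has the largest CMF in the column
    if (nr > 0) {
      alts <- unique(nog[nog != "CCC"])
      vals <- vapply(alts, function(a) cmf(col, "CCC", a), numeric(1))
      counts <- vapply(alts, function(a) sum(nog == a), numeric(1))
      expect_equal(unname(vals[which.max(counts)]), max(vals))
      expect_true(all(vals >= 0 & vals <= 1))
    }
  }
})

test_that("CSV extraction matches the worked example and a column-scan
           oracle, skipping gap codons", {
  aln <- toy_alignment()
  tr <- validate_transcript("t1", "ATGCCCAAATAA")
  cat1 <- enumerate_ssnvs(tr)
  recs <- extract_csvs(aln, cat1)
  expect_equal(nrow(recs), nrow(cat1))
  # CCC>CCT is a chimp-CSV
  cct <- recs[cat1$mut_codon == "CCT", ]
  expect_identical(cct$species[[1]], "chimp")
  expect_true(cct$unique_flag)
  # AAA>AAG found in mouse and frog (mouse gap is at codon 2, not 3)
  aag <- recs[cat1$mut_codon == "AAG", ]
  expect_setequal(aag$species[[1]], c("mouse", "frog"))
  expect_false(aag$unique_flag)
  # mouse never contributes at codon 2 (gap)
  ccg <- recs[cat1$mut_codon == "CCG", ]
  expect_identical(ccg$species[[1]], "frog")
  # all species identical to human: empty CSV sets
  same <- codon_alignment("t1", c(human = "ATGCCCAAATAA",
                                  chimp = "ATGCCCAAATAA"))
  recs0 <- extract_csvs(same, cat1)
  expect_true(all(recs0$n_species == 0L))
  # column-scan oracle over every variant
  for (v in seq_len(nrow(cat1))) {
    col_idx <- cat1$codon_index[v]
    want <- character()
    for (sp in aln$species) {
      cd <- aln$codons[sp, col_idx]
      if (cd != "---" && cd == cat1$mut_codon[v]) want <- c(want, sp)
    }
    expect_setequal(recs$species[[v]], want)
  }
})

test_that("species-count grouping is the CSV set cardinality", {
  aln <- toy_alignment()
  tr <- validate_transcript("t1", "ATGCCCAAATAA")
  cat1 <- enumerate_ssnvs(tr)
  recs <- extract_csvs(aln, cat1)
  grp <- species_count_group(recs)
  expect_identical(unname(grp), lengths(recs$species))
  expect_equal(unname(grp[cat1$mut_codon == "CCT"]), 1L)
  expect_true(any(grp == 0L))
})

test_that("divergence trend recovers a constructed monotone relationship", {
  set.seed(66)
  div <- data.frame(species = c("s1", "s2", "s3", "s4"),
                    divergence = c(10, 50, 200, 600))
  # one unique CSV set per species with scores increasing in divergence
  recs <- data.frame(key = sprintf("k%02d", 1:20),
                     n_species = 1L, unique_flag = TRUE, cmf = 0.5,
                     stringsAsFactors = FALSE)
  recs$species <- as.list(rep(div$species, each = 5))
  scores <- setNames(rep(c(0.1, 0.3, 0.6, 0.9), each = 5) +
                       runif(20, 0, 0.05), recs$key)
  dt <- divergence_trend(scores, recs, div)
  expect_equal(dt$spearman, 1)
  expect_equal(dt$table$log2_divergence, log2(div$divergence))
  # species with no unique CSVs is omitted with a message
  div5 <- rbind(div, data.frame(species = "s5", divergence = 900))
  expect_message(dt5 <- divergence_trend(scores, recs, div5), "omitted")
  expect_equal(nrow(dt5$table), 4L)
  # constant scores: correlation undefined
  const <- setNames(rep(0.5, 20), recs$key)
  expect_true(is.na(divergence_trend(const, recs, div)$spearman))
})

test_that("constraint-bin analysis equals a group-by oracle", {
  set.seed(67)
  n <- 500
  status <- sample(c("observed", "not_seen"), n, TRUE)
  scores <- runif(n)
  pct <- runif(n, 0, 100)
  out <- ccr_bin_analysis(status, scores, pct, n_bins = 5L)
  bins <- cut(pct, seq(0, 100, 20), include.lowest = TRUE)
  for (b in seq_len(5)) {
    rows <- which(as.integer(bins) == b)
    want_frac <- mean(status[rows] == "observed")
    expect_equal(out$table$observed_fraction[b], want_frac)
    obs <- rows[status[rows] == "observed"]
    expect_equal(out$table$median_observed_score[b], median(scores[obs]))
  }
  expect_equal(out$cor_fraction,
               cor(out$table$percentile_mid, out$table$observed_fraction))
  # all variants observed: fraction 1 everywhere
  out1 <- ccr_bin_analysis(rep("observed", n), scores, pct, n_bins = 5L)
  expect_true(all(out1$table$observed_fraction == 1))
})

test_that("alignment FASTA round-trips through disk", {
  aln <- toy_alignment()
  path <- withr::local_tempfile(fileext = ".fa")
  write_alignment_fasta(aln, path)
  back <- read_alignment_fasta(path, transcript_id = "t1",
                               human_cds = "ATGCCCAAATAA")
  expect_identical(back$codons, aln$codons)
  expect_identical(back$species, aln$species)
})
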