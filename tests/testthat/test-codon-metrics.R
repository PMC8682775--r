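# toy reference built from a fixed pool of random CDSs
ref_pool <- lapply(1:6, function(i) random_cds(30, seed = 600 + i))
REF <- toy_reference(ref_pool)

test_that("reference weights are family-normalised with nonempty optima", {
  tab <- REF$table
  for (a in unique(tab$amino_acid)) {
    fam <- tab[tab$amino_acid == a, ]
    expect_equal(max(fam$weight), 1)
    expect_true(all(fam$weight > 0 & fam$weight <= 1))
    expect_true(any(fam$optimal_flag))
  }
  # weights follow direct codon counting on the reference transcripts
  counts <- table(unlist(lapply(ref_pool, oracle_codons)))
  for (a in c("G", "L", "P")) {
    fam <- tab[tab$amino_acid == a, ]
    cnt <- sapply(fam$codon, function(cd)
      if (cd %in% names(counts)) counts[[cd]] else 0.5)
    cnt[cnt == 0] <- 0.5
    expect_equal(fam$weight, as.numeric(cnt / max(cnt)))
  }
})

test_that("reference selection follows the per-tissue top-fraction rule", {
  trs <- lapply(1:100, function(i)
    validate_transcript(paste0("T", i), random_cds(10, seed = 700 + i)))
  names(trs) <- paste0("T", 1:100)
  set.seed(1)
  expr <- matrix(runif(100), ncol = 1, dimnames = list(names(trs), "t1"))
  ref <- build_reference(trs, expr, top_fraction = 0.01)
  expect_length(ref$reference_ids, 1L)  # ceiling(0.01 * 100)
  expect_identical(ref$reference_ids, names(trs)[which.max(expr[, 1])])
  # transcript missing from the matrix is dropped with a warning
  expect_warning(build_reference(trs, expr[1:50, , drop = FALSE]),
                 "absent from expression matrix")
})

test_that("CAI behaves as a geometric mean of reference weights", {
  # sequence made only of optimal (weight-1) codons
  opt <- vapply(REF$optimal, `[[`, character(1), 1L)
  seq_opt <- c("ATG", opt[c("G", "G", "L", "P")], "TAA")
  expect_equal(codon_bias(seq_opt, "CAI", REF), 1.0)
  # two codons with known weights: direct geometric mean
  w <- REF$weights
  two <- names(w[w < 1])[1:2]
  val <- codon_bias(c("ATG", two, "TAA"), "CAI", REF)
  expect_equal(val, sqrt(w[[two[1]]] * w[[two[2]]]))
})

test_that("fracOpt hits its bounds on all-optimal and no-optimal input", {
  opt <- vapply(REF$optimal, `[[`, character(1), 1L)
  expect_equal(codon_bias(c("ATG", opt[c("G", "A", "V")], "TAA"),
                          "fracOpt", REF), 1.0)
  non_opt <- REF$table$codon[!REF$table$optimal_flag &
                               !(REF$table$amino_acid %in% c("M", "W"))]
  expect_equal(codon_bias(c("ATG", non_opt[1:3], "TAA"), "fracOpt", REF), 0)
})

test_that("SCUO gives zero bias for equal two-codon usage and ICDI is 1 at
           maximal bias", {
  # one amino acid (Lys: AAA/AAG) used equally -> entropy maximal, SCUO 0
  expect_equal(codon_bias(c("ATG", "AAA", "AAG", "TAA"), "SCUO", REF), 0)
  # exactly one codon per degenerate amino acid -> ICDI at its maximum, 1
  expect_equal(codon_bias(c("ATG", "AAA", "AAA", "GGC", "GGC", "TAA"),
                          "ICDI", REF), 1)
})

test_that("tAI equals the weighted geometric mean on a 3-codon toy", {
  tw <- REF$trna_weights
  toy <- c("GGG", "AAA", "CCC")
  expect_equal(codon_bias(toy, "tAI", REF),
               (tw[["GGG"]] * tw[["AAA"]] * tw[["CCC"]])^(1 / 3))
})

test_that("reference-requiring metrics fail without a reference", {
  expect_error(codon_bias("ATGGGGTAA", "CAI"), "requires a codon usage")
  expect_error(codon_bias("ATGGGGTAA", "tAI"), "requires a codon usage")
})

test_that("TPI ranks clustered codon usage above interleaved usage", {
  # X = GGA, Y = GGC (synonymous): XXXYYY vs XYXYXY
  clustered <- c(rep("GGA", 3), rep("GGC", 3))
  interleaved <- rep(c("GGA", "GGC"), 3)
  expect_gt(tpi(clustered), tpi(interleaved))
  # no repeated family: sentinel 0
  expect_equal(tpi(c("AAA", "GGG", "CCC")), 0)
})

test_that("CAM decays with distance to the nearest synonymous partner", {
  # partner at distance 2 vs distance 20
  near <- c("ATG", "CCA", "CCG", rep("AAA", 19), "CCG", "TAA")
  variant <- list(codon_index = 2L, wt_codon = "CCA", mut_codon = "CCG")
  far <- near
  far[3] <- "AAA"
  expect_gte(abs(cam(near, variant)), abs(cam(far, variant)))
  # family occurs nowhere else: baseline 0
  lone <- c("ATG", "CCA", "AAA", "TAA")
  expect_equal(cam(lone, list(codon_index = 2L, wt_codon = "CCA",
                              mut_codon = "CCG")), 0)
})

test_that("CF reflects the +1/-1 count change over N codons", {
  codons <- c("ATG", "CCA", rep("AAA", 97), "TAA")  # N = 100
  v <- list(codon_index = 2L, wt_codon = "CCA", mut_codon = "CCG")
  # wt count 1, mut count 0: (0 + 1 - 1) / 100
  expect_equal(cf_measure(codons, v), 0)
  # mutating toward the dominant codon is positive
  codons2 <- c("ATG", rep("AAG", 50), rep("AAA", 49), "TAA")
  expect_equal(cf_measure(codons2, list(codon_index = 52L, wt_codon = "AAA",
                                        mut_codon = "AAG")),
               (51 - 49) / 101)
})

test_that("every metric equals its brute-force oracle on random toys", {
  set.seed(2024)
  for (i in 1:60) {
    cds <- random_cds(sample(8:16, 1))
    codons <- oracle_codons(cds)
    expect_equal(codon_bias(cds, "CAI", REF), oracle_cai(codons, REF),
                 tolerance = 1e-9)
    expect_equal(codon_bias(cds, "fracOpt", REF),
                 oracle_fracopt(codons, REF), tolerance = 1e-9)
    expect_equal(codon_bias(cds, "CUB", REF), oracle_cub(codons, REF),
                 tolerance = 1e-9)
    expect_equal(codon_bias(cds, "ICDI", REF), oracle_icdi(codons),
                 tolerance = 1e-9)
    expect_equal(codon_bias(cds, "SCUO", REF), oracle_scuo(codons),
                 tolerance = 1e-9)
    expect_equal(codon_bias(cds, "tAI", REF), oracle_tai(codons, REF),
                 tolerance = 1e-9)
    expect_equal(tpi(codons), oracle_tpi(codons), tolerance = 1e-9)
  }
})

test_that("variant metrics and delta forms equal oracle recomputation", {
  set.seed(2025)
  metrics <- c("CAI", "fracOpt", "CUB", "ICDI", "SCUO", "tAI", "TPI")
  for (i in 1:50) {
    cds <- random_cds(sample(8:16, 1))
    tr <- validate_transcript("t", cds)
    vs <- enumerate_ssnvs(tr)
    if (nrow(vs) == 0) next
    v <- vs[sample(nrow(vs), 1), ]
    codons <- oracle_codons(cds)
    expect_equal(cam(codons, v),
                 oracle_cam(codons, v$codon_index, v$wt_codon, v$mut_codon),
                 tolerance = 1e-9)
    expect_equal(cf_measure(codons, v),
                 oracle_cf(codons, v$codon_index, v$wt_codon, v$mut_codon),
                 tolerance = 1e-9)
    mut <- codons
    mut[v$codon_index] <- v$mut_codon
    oracles <- list(CAI = oracle_cai, fracOpt = oracle_fracopt,
                    CUB = oracle_cub, ICDI = function(x, r) oracle_icdi(x),
                    SCUO = function(x, r) oracle_scuo(x), tAI = oracle_tai,
                    TPI = function(x, r) oracle_tpi(x))
    for (m in metrics) {
      expect_equal(delta_metric(codons, v, m, REF),
                   oracles[[m]](mut, REF) - oracles[[m]](codons, REF),
                   tolerance = 1e-9)
    }
  }
})

test_that("delta forms are antisymmetric under the reverse variant", {
  set.seed(9)
  for (i in 1:10) {
    cds <- random_cds(12)
    tr <- validate_transcript("t", cds)
    vs <- enumerate_ssnvs(tr)
    if (nrow(vs) == 0) next
    v <- vs[sample(nrow(vs), 1), ]
    mut <- oracle_codons(cds)
    mut[v$codon_index] <- v$mut_codon
    rev_v <- list(codon_index = v$codon_index, wt_codon = v$mut_codon,
                  mut_codon = v$wt_codon)
    for (m in c("CAI", "SCUO", "tAI")) {
      expect_equal(delta_metric(oracle_codons(cds), v, m, REF),
                   -delta_metric(mut, rev_v, m, REF), tolerance = 1e-12)
    }
  }
})

test_that("bounded metrics stay in bounds on many random CDSs", {
  set.seed(31)
  for (i in 1:200) {
    cds <- random_cds(sample(5:40, 1))
    expect_true(codon_bias(cds, "CAI", REF) > 0 &&
                  codon_bias(cds, "CAI", REF) <= 1)
    fo <- codon_bias(cds, "fracOpt", REF)
    expect_true(fo >= 0 && fo <= 1)
    sc <- codon_bias(cds, "SCUO", REF)
    expect_true(sc >= 0 && sc <= 1)
    ta <- codon_bias(cds, "tAI", REF)
    expect_true(ta > 0 && ta <= 1)
    expect_true(is.finite(codon_bias(cds, "ICDI", REF)))
    expect_true(is.finite(codon_bias(cds, "CUB", REF)))
  }
})

test_that("mutating the wrong codon is rejected", {
  v <- list(codon_index = 2L, wt_codon = "CCA", mut_codon = "CCG")
  expect_error(cam(c("ATG", "GGG", "TAA"), v), "does not match")
  expect_error(cf_measure(c("ATG", "GGG", "TAA"), v), "does not match")
})
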