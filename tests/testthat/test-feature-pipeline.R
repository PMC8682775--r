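test_that("distance binning yields exactly the six categories with inclusive
           upper bounds", {
  expect_identical(bin_distance(0), "d=0")
  expect_identical(bin_distance(3), "0<d<=3")
  expect_identical(bin_distance(4), "3<d<=5")
  expect_identical(bin_distance(5), "3<d<=5")
  expect_identical(bin_distance(10), "5<d<=10")
  expect_identical(bin_distance(20), "10<d<=20")
  expect_identical(bin_distance(25), "d>20")
  expect_identical(bin_distance(NA), "d>20")  # "no site" sentinel
  expect_error(bin_distance(-1), "negative")
  # total and single-valued over 0..200 plus sentinel; only the six labels
  labs <- bin_distance(c(0:200, NA))
  expect_setequal(unique(labs),
                  c("d=0", "0<d<=3", "3<d<=5", "5<d<=10", "10<d<=20",
                    "d>20"))
  expect_length(labs, 202L)
})

test_that("minimum site distance handles containment, gaps and empty sets", {
  expect_equal(min_site_distance(10, data.frame(start = 8, end = 12)), 0L)
  iv <- data.frame(start = c(10, 30), end = c(12, 40))
  expect_equal(min_site_distance(5, iv), 5L)
  expect_true(is.na(min_site_distance(5, NULL)))
  expect_true(is.na(min_site_distance(5, data.frame(start = integer(),
                                                    end = integer()))))
  # brute-force check over many positions
  set.seed(8)
  iv2 <- data.frame(start = sort(sample(0:80, 4)), end = 0)
  iv2$end <- iv2$start + sample(2:6, 4, replace = TRUE)
  for (p0 in 0:89) {
    inside <- any(p0 >= iv2$start & p0 < iv2$end)
    want <- if (inside) 0L else
      min(pmin(abs(p0 - iv2$start), abs(p0 - (iv2$end - 1))))
    expect_equal(min_site_distance(p0, iv2), as.integer(want))
  }
})

test_that("expression features are log10 of min/median/max with pseudocount",
{
  m <- matrix(c(10, 10, 10, 1, 10, 100), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(expression_features("a", m)), c(1, 1, 1),
               tolerance = 1e-3)
  expect_equal(unname(expression_features("b", m)), c(0, 1, 2),
               tolerance = 1e-3)
  # zero expression floors at the pseudocount
  z <- matrix(0, 1, 3, dimnames = list("z", NULL))
  expect_equal(unname(expression_features("z", z)), rep(log10(1e-3), 3))
  # missing transcript: all NA (imputed downstream)
  expect_true(all(is.na(expression_features("missing", m))))
})

test_that("RNAsnp parameters follow the length rule exactly", {
  expect_equal(rnasnp_params(150), c(mode = 1L, window = 100L))
  expect_equal(rnasnp_params(200), c(mode = 1L, window = 100L))
  expect_equal(rnasnp_params(400), c(mode = 1L, window = 200L))
  expect_equal(rnasnp_params(500), c(mode = 1L, window = 200L))
  expect_equal(rnasnp_params(600), c(mode = 2L, window = 500L))
})

test_that("assembled features have exactly the 35 schema slots and are
           deterministic", {
  w <- small_world()
  sub <- w$catalog[w$catalog$transcript_id %in% names(w$transcripts)[1:3], ]
  f1 <- assemble_features(sub, w$transcripts, w$annotations, w$reference)
  expect_identical(names(f1), c("key", feature_schema()$name))
  expect_equal(nrow(f1), nrow(sub))
  f2 <- assemble_features(sub, w$transcripts, w$annotations, w$reference)
  expect_identical(f1, f2)
  # null-annotation fallback: unknown categories, NA continuous slots
  f0 <- assemble_features(sub[1:5, ], w$transcripts, NULL, w$reference)
  expect_true(all(f0$local_pairing == "unknown"))
  expect_true(all(is.na(f0$mfe_freq)))
})

test_that("fast metric slots agree with the one-at-a-time delta functions", {
  w <- small_world()
  tid <- names(w$transcripts)[4]
  tr <- w$transcripts[[tid]]
  sub <- w$catalog[w$catalog$transcript_id == tid, ][1:12, ]
  f <- assemble_features(sub, w$transcripts, w$annotations, w$reference)
  for (i in seq_len(nrow(sub))) {
    v <- sub[i, ]
    expect_equal(f$cai_delta[i], delta_metric(tr$codons, v, "CAI",
                                              w$reference),
                 tolerance = 1e-12)
    expect_equal(f$scuo_delta[i], delta_metric(tr$codons, v, "SCUO",
                                               w$reference),
                 tolerance = 1e-12)
    expect_equal(f$tpi_delta[i], delta_metric(tr$codons, v, "TPI",
                                              w$reference),
                 tolerance = 1e-12)
    expect_equal(f$cub_delta[i], delta_metric(tr$codons, v, "CUB",
                                              w$reference),
                 tolerance = 1e-12)
    expect_equal(f$icdi_delta[i], delta_metric(tr$codons, v, "ICDI",
                                               w$reference),
                 tolerance = 1e-12)
    expect_equal(f$fracopt_delta[i], delta_metric(tr$codons, v, "fracOpt",
                                                  w$reference),
                 tolerance = 1e-12)
    expect_equal(f$tai_delta[i], delta_metric(tr$codons, v, "tAI",
                                              w$reference),
                 tolerance = 1e-12)
    expect_equal(f$cam[i], cam(tr$codons, v), tolerance = 1e-12)
    expect_equal(f$cf[i], cf_measure(tr$codons, v), tolerance = 1e-12)
  }
})

test_that("encoders standardise training columns and freeze vocabularies", {
  w <- small_world()
  sub <- w$catalog[seq_len(400), ]
  f <- assemble_features(sub, w$transcripts, w$annotations, w$reference)
  train <- seq_len(300)
  enc <- fit_feature_encoder(f, rows = train)
  X <- apply_feature_encoder(f, enc)
  expect_equal(dim(X), c(400L, 35L))
  expect_false(anyNA(X))
  sch <- feature_schema()
  for (nm in sch$name[sch$type == "continuous"]) {
    expect_equal(mean(X[train, nm]), 0, tolerance = 1e-8)
    s <- sd(X[train, nm])
    expect_true(abs(s - 1) < 1e-8 || s == 0)
  }
  # vocabularies are lexicographic and frozen; unseen categories code to 0
  expect_identical(enc$vocab$offset, sort(enc$vocab$offset))
  f_new <- f[1:2, ]
  f_new$codon_mutation[1] <- "ZZZ>ZZZ"
  Xn <- apply_feature_encoder(f_new, enc)
  expect_equal(unname(Xn[1, "codon_mutation"]), 0)
  # standardisation is invertible on the training split
  nm <- "gc_content"
  m <- enc$moments[[nm]]
  back <- X[train, nm] * m$sd + m$mean
  expect_equal(back, f[[nm]][train], tolerance = 1e-10)
})

test_that("feature matrices round-trip losslessly with their sidecar", {
  w <- small_world()
  f <- assemble_features(w$catalog[1:50, ], w$transcripts, w$annotations,
                         w$reference)
  enc <- fit_feature_encoder(f)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(f, path, encoder = enc)
  back <- read_features(path)
  expect_equal(back$features, f, tolerance = 1e-12)
  expect_identical(back$schema, feature_schema())
  X1 <- apply_feature_encoder(f, enc)
  X2 <- apply_feature_encoder(back$features, back$encoder)
  expect_equal(X1, X2, tolerance = 1e-12)
})

test_that("mixed-type correlations: self is 1, dependence maxes Cramer's V,
           correlation ratio matches the variance formula", {
  w <- small_world()
  f <- assemble_features(w$catalog[1:300, ], w$transcripts, w$annotations,
                         w$reference)
  cm <- feature_correlation(f)
  expect_true(all(diag(cm) == 1))
  expect_true(isSymmetric(cm))
  off <- cm[upper.tri(cm)]
  expect_true(all(is.na(off) | (off >= -1 & off <= 1 + 1e-12)))
  # perfectly dependent 2x2 categorical pair
  expect_equal(synev:::.cramers_v(rep(c("a", "b"), 20),
                                  rep(c("x", "y"), 20)), 1)
  # correlation ratio against the between/total variance formula
  cats <- rep(c("a", "b", "c"), each = 10)
  set.seed(3)
  y <- rnorm(30) + as.integer(factor(cats))
  gm <- mean(y)
  ssb <- sum(sapply(split(y, cats), function(g)
    length(g) * (mean(g) - gm)^2))
  expect_equal(synev:::.correlation_ratio(cats, y),
               sqrt(ssb / sum((y - gm)^2)))
})

test_that("feature importance ranks a planted single informative feature
           first and noise near zero", {
  set.seed(42)
  n <- 600
  sch <- feature_schema()
  X <- matrix(rnorm(n * 35), n, 35, dimnames = list(NULL, sch$name))
  y <- as.integer(X[, "cam"] > 0)
  cfg <- pul_config(seed = 1L)
  fit <- synev:::.fit_xgb(X, y, cfg, trees = 50L)
  imp <- feature_importance(fit)
  expect_identical(imp$feature[1], "cam")
  expect_true(all(imp$gain[imp$feature != "cam"] < 0.1))
  # stable rank order across identical-seed retrains
  fit2 <- synev:::.fit_xgb(X, y, cfg, trees = 50L)
  expect_identical(imp, feature_importance(fit2))
})
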