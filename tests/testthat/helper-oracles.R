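# Independent brute-force oracles, coded from the definitions with plain
# loops; they never share code paths with the package implementations.

GC <- synev:::.GENETIC_CODE
STOPS <- names(GC)[GC == "*"]

oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(GC[codons], collapse = "")
}

# all single-nt substitutions that keep the protein identical
oracle_enumerate <- function(cds, include_stop = FALSE) {
  prot <- oracle_translate(cds)
  L <- nchar(cds)
  last_codon_start <- L - 2
  out <- NULL
  for (p in seq_len(L)) {
    ref <- substr(cds, p, p)
    in_stop <- p >= last_codon_start
    if (in_stop && !include_stop) next
    for (alt in c("A", "C", "G", "T")) {
      if (alt == ref) next
      mut <- cds
      substr(mut, p, p) <- alt
      if (oracle_translate(mut) == prot)
        out <- rbind(out, data.frame(pos = p, ref = ref, alt = alt,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# random valid CDS (start, stop, no internal stop)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(GC)[GC != "*"]
  paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE),
          sample(STOPS, 1)), collapse = "")
}

oracle_codons <- function(cds)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))

.orc_counted <- function(codons) {
  aa <- GC[codons]
  codons[!(aa %in% c("M", "W", "*"))]
}

oracle_cai <- function(codons, ref) {
  cc <- .orc_counted(codons)
  prod(ref$weights[cc])^(1 / length(cc))
}

oracle_fracopt <- function(codons, ref) {
  cc <- .orc_counted(codons)
  opt <- unlist(ref$optimal, use.names = FALSE)
  n_opt <- 0
  for (cd in cc) if (cd %in% opt) n_opt <- n_opt + 1
  n_opt / length(cc)
}

oracle_cub <- function(codons, ref) {
  cc <- .orc_counted(codons)
  aa <- GC[cc]
  total <- 0
  for (a in unique(aa)) {
    fam <- names(GC)[GC == a]
    occ <- cc[aa == a]
    d <- 0
    for (cd in fam) {
      rc <- ref$table$count[ref$table$codon == cd]
      rc_fam <- ref$table$count[ref$table$codon %in% fam]
      rc_fam[rc_fam == 0] <- 0.5
      if (rc == 0) rc <- 0.5
      d <- d + abs(sum(occ == cd) / length(occ) - rc / sum(rc_fam))
    }
    total <- total + length(occ) / length(cc) * d
  }
  total
}

oracle_icdi <- function(codons) {
  cc <- .orc_counted(codons)
  aa <- GC[cc]
  s <- c()
  for (a in unique(aa)) {
    fam <- names(GC)[GC == a]
    occ <- cc[aa == a]
    k <- length(fam)
    tot <- 0
    for (cd in fam) {
      rscu <- k * sum(occ == cd) / length(occ)
      tot <- tot + (rscu - 1)^2
    }
    s <- c(s, tot / (k * (k - 1)))
  }
  mean(s)
}

oracle_scuo <- function(codons) {
  cc <- .orc_counted(codons)
  aa <- GC[cc]
  out <- 0
  for (a in unique(aa)) {
    fam <- names(GC)[GC == a]
    occ <- cc[aa == a]
    h <- 0
    for (cd in fam) {
      p <- sum(occ == cd) / length(occ)
      if (p > 0) h <- h - p * log(p)
    }
    o <- (log(length(fam)) - h) / log(length(fam))
    out <- out + length(occ) / length(cc) * o
  }
  out
}

oracle_tai <- function(codons, ref) {
  cc <- codons[GC[codons] != "*"]
  prod(ref$trna_weights[cc])^(1 / length(cc))
}

# TPI oracle: expectation of same-codon adjacencies taken by exhaustive
# enumeration of the distinct permutations of each family's codon multiset
oracle_tpi <- function(codons) {
  aa <- GC[codons]
  keep <- !(aa %in% c("M", "W", "*"))
  codons <- codons[keep]; aa <- aa[keep]
  num <- 0; den <- 0
  for (a in unique(aa)) {
    occ <- codons[aa == a]
    n <- length(occ)
    if (n < 2 || length(unique(occ)) < 2) next
    r_of <- function(v) sum(v[-1] == v[-length(v)])
    r <- r_of(occ)
    perms <- unique(combinat_perms(occ))
    rs <- vapply(perms, r_of, numeric(1))
    e_r <- mean(rs)
    r_max <- max(rs)
    if (r_max - e_r <= 0) next
    num <- num + (n - 1) * (r - e_r) / (r_max - e_r)
    den <- den + (n - 1)
  }
  if (den == 0) 0 else num / den
}

# all permutations of a small vector (n <= 7)
combinat_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n))
    for (p in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

oracle_cam <- function(codons, i, wt, mut) {
  nearest <- function(cd) {
    best <- Inf
    for (j in seq_along(codons))
      if (j != i && codons[j] == cd) best <- min(best, abs(j - i))
    if (is.infinite(best)) 0 else 1 / best
  }
  nearest(mut) - nearest(wt)
}

oracle_cf <- function(codons, i, wt, mut) {
  n_wt <- 0; n_mut <- 0
  for (cd in codons) {
    if (cd == wt) n_wt <- n_wt + 1
    if (cd == mut) n_mut <- n_mut + 1
  }
  ((n_mut + 1) - n_wt) / length(codons)
}

# reference over a fixed toy transcript set, one tissue
toy_reference <- function(cds_list, seed = 400) {
  set.seed(seed)
  trs <- lapply(seq_along(cds_list), function(i)
    validate_transcript(paste0("R", i), cds_list[[i]]))
  names(trs) <- vapply(trs, function(t) t$transcript_id, character(1))
  expr <- matrix(runif(length(trs)), ncol = 1,
                 dimnames = list(names(trs), "t1"))
  build_reference(trs, expr, top_fraction = 1)
}
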