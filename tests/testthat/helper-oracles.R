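# Independent oracle implementations used to cross-check the package's
# estimators on tiny fixtures.  These deliberately take the slow,
# enumerate-everything route.

# convert a 0/1 haplotype matrix (rows = haploids) into an alignment with
# two synthetic states per column, for sequence-based statistics
haplotypes_to_alignment <- function(H, pops) {
  seqs <- apply(H, 1, function(r) paste(c("A", "C")[r + 1], collapse = ""))
  sequence_alignment(seqs, sprintf("h%03d", seq_len(nrow(H))), pops)
}

# textbook Tajima's D computed with explicit loops and no shared code
oracle_tajima <- function(seq_strings) {
  M <- do.call(rbind, strsplit(seq_strings, ""))
  n <- nrow(M)
  keep <- apply(M, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  M <- M[, keep, drop = FALSE]
  seg <- which(apply(M, 2, function(col) length(unique(col)) > 1))
  S <- length(seg)
  if (S == 0) stop("no segregating sites")
  k_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k_tot <- k_tot + sum(M[i, ] != M[j, ])
  }
  k_bar <- k_tot / (n * (n - 1) / 2)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k_bar - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# brute-force two-level molecular variance decomposition from a pairwise
# (squared) distance matrix; returns sigma_a, sigma_w and the Phi ratio
oracle_two_level_amova <- function(D2, labels) {
  N <- length(labels)
  pops <- unique(labels)
  ss_set <- function(idx) {
    if (length(idx) < 2) return(0)
    tot <- 0
    for (i in idx) for (j in idx) tot <- tot + D2[i, j]
    tot / (2 * length(idx))
  }
  ssw <- sum(sapply(pops, function(p) ss_set(which(labels == p))))
  sst <- ss_set(1:N)
  ssa <- sst - ssw
  n_p <- sapply(pops, function(p) sum(labels == p))
  msw <- ssw / (N - length(pops))
  nc <- (N - sum(n_p^2) / N) / (length(pops) - 1)
  s2a <- (ssa / (length(pops) - 1) - msw) / nc
  list(sigma_a = s2a, sigma_w = msw, phi = s2a / (s2a + msw))
}

# exhaustive minimal-removal unrelated set: smallest number of dropped
# individuals leaving no related pair; ties resolved toward dropping the
# most-missing individuals (mirrors the documented rule's objective)
oracle_min_removal <- function(adj, missingness) {
  ids <- rownames(adj)
  n <- length(ids)
  best <- NULL
  for (size in 0:n) {
    combos <- utils::combn(n, size, simplify = FALSE)
    ok <- Filter(function(drop) {
      keep <- setdiff(seq_len(n), drop)
      sum(adj[keep, keep]) == 0
    }, combos)
    if (length(ok)) {
      # among minimal removals prefer dropping high-missingness ids
      sc <- sapply(ok, function(drop) sum(missingness[ids[drop]]))
      best <- ids[setdiff(seq_len(n), ok[[which.max(sc)]])]
      break
    }
  }
  best
}

# build a small genotype matrix directly
toy_genotypes <- function(calls, loci = NULL, pops = NULL) {
  calls <- as.matrix(calls)
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(calls)))
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("i%02d", seq_len(nrow(calls)))
  }
  if (is.null(pops)) {
    pops <- setNames(rep("P1", nrow(calls)), rownames(calls))
  }
  genotype_matrix(calls, loci, pops)
}

fold_counts_test <- function(unfolded, sample_sizes) {
  tealdemog:::fold_counts(unfolded, sample_sizes)
}

# multinomial draw of an observed spectrum from an expected one
draw_sfs <- function(probs, n_snps) {
  obs <- probs
  cm <- as.matrix(probs$counts) * 0
  cm[!probs$mask] <- rmultinom(1, n_snps,
                               as.numeric(probs$counts)[!probs$mask])
  obs$counts <- if (probs$dims == 1L) as.numeric(cm) else cm
  obs$n_snps <- n_snps
  obs
}
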