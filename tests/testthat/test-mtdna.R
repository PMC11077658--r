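aln_from <- function(seqs, pops = NULL) {
  if (is.null(pops)) pops <- rep("P", length(seqs))
  sequence_alignment(seqs, sprintf("s%02d", seq_along(seqs)), pops)
}

test_that("haplotype collapsing tallies counts, labels and privacy", {
  aln <- aln_from(rep("ACGT", 4))
  h <- collapse_haplotypes(aln)
  expect_length(h$labels, 1L)
  expect_identical(h$labels, "I")

  aln2 <- aln_from(c("ACGT", "ACGT", "ACGA", "TCGT", "ACGA", "ACGT"),
                   pops = c("X", "X", "X", "Y", "Y", "Y"))
  h2 <- collapse_haplotypes(aln2)
  expect_identical(h2$labels, c("I", "II", "III"))
  expect_equal(unname(h2$counts["I", ]), c(2, 1))     # ACGT shared
  expect_equal(unname(h2$counts["II", ]), c(1, 1))    # ACGA shared
  expect_equal(unname(h2$counts["III", ]), c(0, 1))   # TCGT private
  expect_identical(unname(h2$private), c(FALSE, FALSE, TRUE))

  # length mismatch is an error at construction
  expect_error(aln_from(c("ACGT", "ACG")), "equal length")

  # N wildcard merging is optional
  alnN <- aln_from(c("ACGT", "ACGN"))
  expect_length(collapse_haplotypes(alnN)$labels, 2L)
  expect_length(collapse_haplotypes(alnN, n_wildcard = TRUE)$labels, 1L)
})

test_that("haplotype diversity reproduces published worked values", {
  expect_equal(hap_diversity(c(9, 1))$Hd, 0.2, tolerance = 1e-12)
  expect_equal(round(hap_diversity(c(10, 10))$Hd, 3), 0.526)
  expect_equal(hap_diversity(c(7))$Hd, 0)
  expect_error(hap_diversity(c(1)), "n >= 2")
  expect_gt(hap_diversity(c(9, 1))$variance, 0)
  # pooled statistics ignore ordering
  expect_equal(hap_diversity(c(1, 9))$Hd, hap_diversity(c(9, 1))$Hd)
})

test_that("nucleotide diversity equals the brute-force pairwise average", {
  two <- aln_from(c(paste(rep("A", 169), collapse = ""),
                    paste(c("C", rep("A", 168)), collapse = "")))
  expect_equal(nuc_diversity(two), 1 / 169)
  expect_equal(nuc_diversity(aln_from(rep("ACGTAC", 3))), 0)

  seqs <- c("AACCGG", "AACCGT", "TACCGT", "AANCGG")
  aln <- aln_from(seqs)
  # independent enumeration
  M <- do.call(rbind, strsplit(seqs, ""))
  tot <- 0; np <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- M[i, ] != "N" & M[j, ] != "N"
    tot <- tot + sum(M[i, ok] != M[j, ok]) / sum(ok)
    np <- np + 1
  }
  expect_equal(nuc_diversity(aln), tot / np)
})

test_that("Tajima's D matches an independently coded oracle and errors
           without segregating sites", {
  expect_error(tajimas_d(aln_from(rep("ACGT", 5))), "no segregating")
  seqs <- c("AAAA", "AAAT", "CAAT", "CAAA", "AAAA")
  aln <- aln_from(seqs)
  expect_equal(tajimas_d(aln), oracle_tajima(seqs), tolerance = 1e-12)

  seqs2 <- c("ACGTACGTAA", "ACGTACGTAT", "ACGAACGTAT", "TCGAACGGAT",
             "ACGTACGGAA", "ACGTACGTAT")
  expect_equal(tajimas_d(aln_from(seqs2)), oracle_tajima(seqs2),
               tolerance = 1e-12)
})

test_that("Tajima's D is near zero under the neutral constant-size null", {
  m <- demographic_model(c(P = 1), anc_sizes = 1)
  ds <- vapply(1:500, function(s) {
    set.seed(s)
    tr <- simulate_genealogies(demographic_model(c(P = 2500),
                                                 anc_sizes = 2500),
                               12, n_loci = 1)
    H <- drop_mutations(tr, 1e-6, 1000)[[1]]  # theta = 5
    if (ncol(H) == 0) return(NA_real_)
    tajimas_d(haplotypes_to_alignment(H, rep("P", 12)))
  }, 0)
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.15)
})

test_that("Phi_ST separates fixed populations and matches the enumeration
           oracle on a toy alignment", {
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c(rep("C", 10), rep("A", 10)), collapse = "")
  aln <- aln_from(c(rep(a, 5), rep(b, 5)),
                  pops = rep(c("X", "Y"), each = 5))
  res <- phi_st(aln, c("X", "Y"), n_permutations = 199, seed = 1)
  expect_equal(res$phi_st, 1)
  # only the 2 label-swap permutations of the 252 possible splits can
  # reach the observed statistic
  expect_lte(res$p_value, 0.05)

  expect_error(phi_st(aln_from(rep(a, 6),
                               pops = rep(c("X", "Y"), each = 3)),
                      c("X", "Y")), "identical")

  seqs <- c("AAAAA", "AAAAT", "AATAT", "CAAAA",
            "CCAAA", "CCAAT", "CCTTT", "CCTTA")
  pops <- rep(c("X", "Y"), each = 4)
  aln2 <- aln_from(seqs, pops)
  res2 <- phi_st(aln2, c("X", "Y"), n_permutations = 0)
  D2 <- matrix(0, 8, 8)
  M <- do.call(rbind, strsplit(seqs, ""))
  for (i in 1:7) for (j in (i + 1):8) {
    D2[i, j] <- D2[j, i] <- sum(M[i, ] != M[j, ])
  }
  expect_equal(res2$phi_st, oracle_two_level_amova(D2, pops)$phi,
               tolerance = 1e-12)
})

test_that("AMOVA handles the degenerate designs exactly", {
  a <- "AAAA"; b <- "AATT"; c2 <- "CCTT"
  # every population its own group: middle component exactly zero
  aln <- aln_from(c(a, a, b, b, c2, c2),
                  pops = rep(c("p1", "p2", "p3"), each = 2))
  res <- amova(aln, groups = c(p1 = "g1", p2 = "g2", p3 = "g3"),
               n_permutations = 0)
  expect_equal(res$SS[2], 0, tolerance = 1e-12)
  expect_equal(res$sigma2[2], 0)
  expect_equal(sum(res$percent), 100, tolerance = 1e-9)

  # all sequences identical: all components zero
  aln0 <- aln_from(rep(a, 8), pops = rep(c("p1", "p2", "p3", "p4"), 2))
  res0 <- amova(aln0, groups = c(p1 = "g1", p2 = "g1", p3 = "g2",
                                 p4 = "g2"), n_permutations = 0)
  expect_true(all(res0$sigma2 == 0))
})

test_that("AMOVA components match a brute-force decomposition on a
           three-group design", {
  set.seed(8)
  base <- c("A", "C", "G", "T")
  mk <- function(anchor, n, noise) {
    vapply(seq_len(n), function(i) {
      s <- anchor
      flips <- sample(length(s), noise)
      s[flips] <- sample(base, noise, replace = TRUE)
      paste(s, collapse = "")
    }, "")
  }
  a1 <- rep("A", 30); a2 <- a1; a2[1:8] <- "C"; a3 <- a1; a3[9:16] <- "G"
  seqs <- c(mk(a1, 4, 2), mk(a1, 3, 2), mk(a2, 4, 2), mk(a3, 5, 2))
  pops <- rep(c("p1", "p2", "p3", "p4"), c(4, 3, 4, 5))
  groups <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g3")
  aln <- aln_from(seqs, pops)
  res <- amova(aln, groups, n_permutations = 199, seed = 2)
  expect_equal(sum(res$percent), 100, tolerance = 1e-9)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # brute-force SS identities from the distance matrix
  M <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  D2 <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D2[i, j] <- D2[j, i] <- sum(M[i, ] != M[j, ])
  }
  ssd <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) s <- s + D2[i, j]
    s / (2 * length(idx))
  }
  ss_wp <- sum(sapply(unique(pops), function(p) ssd(which(pops == p))))
  grp <- unname(groups[pops])
  ss_g <- sum(sapply(unique(grp), function(g) ssd(which(grp == g))))
  ss_t <- ssd(1:n)
  expect_equal(res$SS, c(ss_t - ss_g, ss_g - ss_wp, ss_wp),
               tolerance = 1e-9)
  # two-level check: within-pop variance equals the oracle's MSW
  expect_equal(res$sigma2[3], ss_wp / (n - 4), tolerance = 1e-9)
})

test_that("TCS-style networks use shortest connections first and keep
           alternative equal-length cycles", {
  # two haplotypes one step apart
  h2 <- collapse_haplotypes(aln_from(c("AAAA", "AAAT", "AAAT")))
  net2 <- tcs_network(h2)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$steps, 1L)
  expect_equal(sum(igraph::V(net2$graph)$inferred), 0)

  # line A-1-B-1-C: no direct A-C edge at distance 2
  hl <- collapse_haplotypes(aln_from(c("AAAA", "AAAT", "AATT")))
  netl <- tcs_network(hl)
  expect_equal(nrow(netl$edges), 2L)
  expect_true(all(netl$edges$steps == 1L))

  # star: four haplotypes one step from a central one
  hub <- "AAAAA"
  spokes <- c("TAAAA", "ACAAA", "AAGAA", "AAATA")
  hs <- collapse_haplotypes(aln_from(c(hub, spokes)))
  nets <- tcs_network(hs)
  expect_equal(nrow(nets$edges), 4L)
  expect_true(all(nets$edges$from == "I" | nets$edges$to == "I"))

  # square with two equal alternative connections keeps the cycle
  sq <- c("AAAA", "TAAA", "TCAA", "ACAA")
  nq <- tcs_network(collapse_haplotypes(aln_from(sq)))
  expect_equal(nrow(nq$edges), 4L)

  # a fixed limit disconnects distant haplotypes
  far <- c("AAAAAAAA", "TTTTTAAA")
  nf <- tcs_network(collapse_haplotypes(aln_from(far)),
                    connection_limit = 3)
  expect_equal(nrow(nf$edges), 0L)
  expect_equal(length(unique(nf$components)), 2L)

  # edges never exceed the limit; every haplotype is in one component
  set.seed(12)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C"), 30, replace = TRUE), collapse = ""), "")
  h8 <- collapse_haplotypes(aln_from(seqs))
  n8 <- tcs_network(h8, connection_limit = 10)
  expect_true(all(n8$edges$steps <= 10))
  expect_length(n8$components, length(h8$labels))

  path <- tempfile(fileext = ".graphml")
  write_graphml(nets, path)
  expect_true(file.exists(path))
})
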