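#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences are merged into haplotypes, labelled with Roman
#' numerals in order of discovery, and tabulated per population.  By
#' default `N` (and `-`) mismatch any other state, the conservative choice
#' for museum-grade sequences; with `n_wildcard = TRUE` an `N` matches any
#' base (greedy merge into the first compatible haplotype).
#'
#' @param aln a [sequence_alignment()].
#' @param n_wildcard treat N as a wildcard when comparing sequences.
#' @return a `haplotype_table`: distinct sequences, per-population count
#'   matrix, and a private/shared classification.
#' @export
collapse_haplotypes <- function(aln, n_wildcard = FALSE) {
  stopifnot(inherits(aln, "sequence_alignment"))
  seqs <- aln$sequences
  if (!n_wildcard) {
    key <- match(seqs, unique(seqs))
    hap_seq <- unique(seqs)
  } else {
    hap_seq <- character(0)
    key <- integer(length(seqs))
    compat <- function(a, b) {
      ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
      all(ca == cb | ca == "N" | cb == "N")
    }
    for (i in seq_along(seqs)) {
      hit <- which(vapply(hap_seq, compat, TRUE, b = seqs[i]))
      if (length(hit)) {
        key[i] <- hit[1]
      } else {
        hap_seq <- c(hap_seq, seqs[i])
        key[i] <- length(hap_seq)
      }
    }
  }
  H <- length(hap_seq)
  labels <- as.character(utils::as.roman(seq_len(H)))
  pops <- sort(unique(aln$pops))
  counts <- matrix(0L, H, length(pops),
                   dimnames = list(labels, pops))
  for (i in seq_along(seqs)) {
    counts[key[i], aln$pops[i]] <- counts[key[i], aln$pops[i]] + 1L
  }
  structure(list(sequences = hap_seq, labels = labels, counts = counts,
                 private = rowSums(counts > 0) == 1L,
                 assignment = setNames(labels[key], aln$ids),
                 length = aln$length),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$labels), "haplotypes over",
      sum(x$counts), "sequences;", sum(x$private), "private\n")
  print(x$counts)
  invisible(x)
}

#' Haplotype diversity with sampling variance
#'
#' The unbiased estimator `Hd = n (1 - sum p_i^2) / (n - 1)` and its
#' standard sampling variance
#' `V(Hd) = 2/(n(n-1)) * (2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 -
#' (sum p^2)^2)`, enabling Welch-style comparisons downstream.
#'
#' @param counts per-haplotype counts (a numeric vector, or a
#'   `haplotype_table` column).
#' @return list with `Hd`, `variance`, `n`.
#' @export
hap_diversity <- function(counts) {
  counts <- as.numeric(counts[counts > 0])
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2 sequences")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, variance = v, n = n)
}

# pairwise differences / comparable sites between two character matrices
# of split sequences; sites with N or - in either member are skipped
pair_diff <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(diff = sum(a[ok] != b[ok]), comp = sum(ok))
}

seq_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequences, ""))
}

#' Nucleotide diversity of an alignment
#'
#' Mean proportion of differing sites over all sequence pairs, skipping
#' sites with N or `-` pairwise (not column-wise).
#'
#' @param aln a [sequence_alignment()].
#' @export
nuc_diversity <- function(aln) {
  stopifnot(inherits(aln, "sequence_alignment"))
  n <- length(aln$sequences)
  if (n < 2) stop("nucleotide diversity needs >= 2 sequences")
  M <- seq_char_matrix(aln)
  tot <- 0; npair <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- pair_diff(M[i, ], M[j, ])
      if (d["comp"] == 0) stop("zero comparable sites between sequences ",
                               aln$ids[i], " and ", aln$ids[j])
      tot <- tot + d["diff"] / d["comp"]
      npair <- npair + 1
    }
  }
  unname(tot / npair)
}

#' Tajima's D
#'
#' Standardized difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta:
#' `D = (k_hat - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' coefficients.  Sites containing N or `-` are excluded entirely
#' (complete deletion) before counting S and pairwise differences.
#' Negative D suggests expansion after a bottleneck, positive D sudden
#' contraction/structure.
#'
#' @param aln a [sequence_alignment()].
#' @export
tajimas_d <- function(aln) {
  stopifnot(inherits(aln, "sequence_alignment"))
  n <- length(aln$sequences)
  if (n < 4) stop("Tajima's D needs >= 4 sequences")
  M <- seq_char_matrix(aln)
  clean <- apply(M, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  M <- M[, clean, drop = FALSE]
  S <- sum(apply(M, 2, function(col) length(unique(col)) > 1))
  if (S == 0) stop("Tajima's D is undefined: no segregating sites")
  k <- 0
  np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + sum(M[i, ] != M[j, ])
      np <- np + 1
    }
  }
  k <- k / np
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# squared-distance sums of squares for a set of indices, treating the
# pairwise difference count as the squared distance (the molecular-variance
# convention)
ss_of <- function(D2, idx) {
  if (length(idx) < 2) return(0)
  sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
}

# pairwise difference-count matrix (pairwise deletion)
diff_matrix <- function(aln) {
  M <- seq_char_matrix(aln)
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- pair_diff(M[i, ], M[j, ])["diff"]
    }
  }
  D
}

#' Pairwise Phi_ST with a permutation test
#'
#' AMOVA-based differentiation between two populations, with pairwise
#' nucleotide-difference counts as (squared) distances and significance by
#' permuting sequence-to-population assignment (add-one convention).
#'
#' @param aln a [sequence_alignment()].
#' @param pops the two population labels to compare.
#' @param n_permutations assignment permutations.
#' @param seed integer seed.
#' @return list with `phi_st`, `p_value`, `n_permutations`.
#' @export
phi_st <- function(aln, pops, n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(aln, "sequence_alignment"), length(pops) == 2)
  sel <- aln$pops %in% pops
  sub <- sequence_alignment(aln$sequences[sel], aln$ids[sel],
                            aln$pops[sel])
  sizes <- table(sub$pops)[pops]
  if (any(is.na(sizes)) || any(sizes < 2)) {
    stop("each population needs >= 2 sequences")
  }
  D2 <- diff_matrix(sub)
  if (all(D2 == 0)) {
    stop("Phi_ST is undefined: all sequences are identical")
  }
  stat <- function(lab) {
    N <- length(lab)
    grp <- lapply(pops, function(p) which(lab == p))
    ssw <- sum(vapply(grp, ss_of, 0, D2 = D2))
    sst <- ss_of(D2, seq_len(N))
    ssa <- sst - ssw
    n_p <- lengths(grp)
    dfa <- length(grp) - 1
    dfw <- N - length(grp)
    msw <- ssw / dfw
    nc <- (N - sum(n_p^2) / N) / dfa
    s2a <- (ssa / dfa - msw) / nc
    s2a / (s2a + msw)
  }
  obs <- stat(sub$pops)
  p_value <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      exceed <- exceed + (stat(sample(sub$pops)) >= obs)
    }
    p_value <- (1 + exceed) / (1 + n_permutations)
  }
  list(phi_st = obs, p_value = p_value, n_permutations = n_permutations)
}

#' Three-level analysis of molecular variance (AMOVA)
#'
#' Hierarchical decomposition of molecular variance into among-groups,
#' among-populations-within-groups and within-populations components, on
#' pairwise nucleotide-difference counts taken as squared distances.
#' Percentages may be negative (variance-component estimators are not
#' constrained to be positive).  Significance per level comes from the
#' standard permutation schemes: whole populations across groups
#' (among-groups), individuals across populations within their group
#' (among-populations), and individuals across everything
#' (within-populations), each with the add-one convention.
#'
#' @param aln a [sequence_alignment()].
#' @param groups named character vector mapping population label to group.
#' @param n_permutations permutations per level.
#' @param seed integer seed.
#' @return an `amova_result` data.frame (level, df, SS, sigma2, percent,
#'   p_value) with Phi statistics in the `phi` attribute.
#' @export
amova <- function(aln, groups, n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(aln, "sequence_alignment"))
  pops <- aln$pops
  if (!all(pops %in% names(groups))) {
    stop("every population needs a group assignment; missing: ",
         paste(setdiff(unique(pops), names(groups)), collapse = ", "))
  }
  grp <- unname(groups[pops])
  if (length(unique(grp)) < 2) stop("AMOVA needs >= 2 groups")
  D2 <- diff_matrix(aln)

  decomp <- function(pop_lab, grp_lab) {
    N <- length(pop_lab)
    pop_ids <- unique(pop_lab)
    grp_ids <- unique(grp_lab)
    P <- length(pop_ids); Gn <- length(grp_ids)
    ss_pop <- sum(vapply(pop_ids, function(p)
      ss_of(D2, which(pop_lab == p)), 0))
    ss_grp <- sum(vapply(grp_ids, function(g)
      ss_of(D2, which(grp_lab == g)), 0))
    ss_tot <- ss_of(D2, seq_len(N))
    SS <- c(AG = ss_tot - ss_grp, AP = ss_grp - ss_pop, WP = ss_pop)
    df <- c(AG = Gn - 1, AP = P - Gn, WP = N - P)
    n_p <- vapply(pop_ids, function(p) sum(pop_lab == p), 0)
    grp_of_pop <- vapply(pop_ids, function(p)
      grp_lab[match(p, pop_lab)], "")
    N_g <- vapply(grp_ids, function(g) sum(grp_lab == g), 0)
    sum_np2_by_g <- vapply(grp_ids, function(g)
      sum(n_p[grp_of_pop == g]^2), 0)
    n1 <- (N - sum(sum_np2_by_g / N_g)) / max(df["AP"], 1)
    n2 <- (sum(sum_np2_by_g / N_g) - sum(n_p^2) / N) / df["AG"]
    n3 <- (N - sum(N_g^2) / N) / df["AG"]
    s2c <- SS["WP"] / df["WP"]
    s2b <- if (df["AP"] > 0) (SS["AP"] / df["AP"] - s2c) / n1 else 0
    s2a <- (SS["AG"] / df["AG"] - s2c - n2 * s2b) / n3
    sigma <- c(AG = unname(s2a), AP = unname(s2b), WP = unname(s2c))
    list(SS = SS, df = df, sigma = sigma)
  }

  obs <- decomp(pops, grp)
  tot <- sum(obs$sigma)
  phi <- c(phi_CT = obs$sigma[["AG"]] / tot,
           phi_SC = obs$sigma[["AP"]] /
             (obs$sigma[["AP"]] + obs$sigma[["WP"]]),
           phi_ST = (obs$sigma[["AG"]] + obs$sigma[["AP"]]) / tot)

  pvals <- c(AG = NA_real_, AP = NA_real_, WP = NA_real_)
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    ex <- c(AG = 0L, AP = 0L, WP = 0L)
    pop_ids <- unique(pops)
    pop_grp <- setNames(unname(groups[pop_ids]), pop_ids)
    for (i in seq_len(n_permutations)) {
      # among groups: permute whole populations across groups
      pg <- setNames(sample(pop_grp), names(pop_grp))
      d <- decomp(pops, unname(pg[pops]))
      ex["AG"] <- ex["AG"] + (d$sigma[["AG"]] >= obs$sigma[["AG"]])
      # among pops within groups: permute individuals within their group
      pp <- pops
      for (g in unique(grp)) {
        idx <- which(grp == g)
        pp[idx] <- pops[sample(idx)]
      }
      d <- decomp(pp, grp)
      ex["AP"] <- ex["AP"] + (d$sigma[["AP"]] >= obs$sigma[["AP"]])
      # within pops: permute individuals across everything
      ord <- sample(length(pops))
      d <- decomp(pops[ord], grp[ord])
      ex["WP"] <- ex["WP"] + (d$sigma[["WP"]] <= obs$sigma[["WP"]])
    }
    pvals <- (1 + ex) / (1 + n_permutations)
  }
  out <- data.frame(
    level = c("among_groups", "among_pops_within_groups", "within_pops"),
    df = unname(obs$df), SS = unname(obs$SS), sigma2 = unname(obs$sigma),
    percent = 100 * unname(obs$sigma) / tot, p_value = unname(pvals))
  if (obs$df[["AP"]] == 0) {
    out$sigma2[2] <- 0
    out$percent[2] <- 0
    out$p_value[2] <- NA_real_
  }
  structure(out, class = c("amova_result", "data.frame"), phi = phi)
}

# statistical-parsimony connection limit: the largest step count j for
# which the probability that no superimposed (hidden) change occurred is
# >= prob.  Hidden changes are approximated as Poisson with mean equal to
# the excess of the Jukes-Cantor-corrected substitution count over the
# observed differences.
parsimony_limit <- function(seq_length, prob = 0.95) {
  j <- 1
  repeat {
    p_obs <- (j + 1) / seq_length
    if (p_obs >= 0.75) break
    d <- -0.75 * log(1 - 4 * p_obs / 3)
    extra <- seq_length * d - (j + 1)
    if (exp(-extra) < prob) break
    j <- j + 1
    if (j >= seq_length) break
  }
  j
}

#' Statistical-parsimony (TCS-style) haplotype network
#'
#' Connects haplotypes in increasing order of pairwise mutational distance
#' (Hamming distance, sites with N/- excluded pairwise), never exceeding
#' the connection limit.  Within one distance tier, every pair that joined
#' two distinct components at the start of the tier is connected, so
#' alternative equal-length connections are retained as cycles; pairs
#' already connected through shorter paths are not linked again.
#' Multi-step edges contribute inferred intermediate nodes.  The automatic
#' connection limit is the largest step count whose parsimony probability
#' is at least 0.95 under a documented Poisson-homoplasy approximation.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()].
#' @param connection_limit `"auto"` or a fixed number of steps.
#' @return a `tcs_network`: haplotype-level edge list with step counts,
#'   the limit used, component membership, and an igraph graph including
#'   inferred intermediates.
#' @export
tcs_network <- function(haps, connection_limit = "auto") {
  stopifnot(inherits(haps, "haplotype_table"))
  H <- length(haps$labels)
  if (H < 2) stop("a network needs >= 2 haplotypes")
  aln <- sequence_alignment(haps$sequences, haps$labels,
                            rep("x", H))
  D <- diff_matrix(aln)
  limit <- if (identical(connection_limit, "auto")) {
    parsimony_limit(haps$length)
  } else {
    as.numeric(connection_limit)
  }
  comp <- seq_len(H)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0))
  for (d in sort(unique(D[upper.tri(D)]))) {
    if (d == 0 || d > limit) next
    comp_at_tier <- comp
    pairs <- which(D == d & upper.tri(D), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (comp_at_tier[i] == comp_at_tier[j]) next
      edges <- rbind(edges, data.frame(from = haps$labels[i],
                                       to = haps$labels[j],
                                       steps = d))
      comp[comp == comp[j]] <- comp[i]
    }
  }
  # expanded graph with inferred intermediates
  vattr <- data.frame(name = haps$labels,
                      freq = rowSums(haps$counts),
                      inferred = FALSE)
  elist <- list()
  n_int <- 0
  for (r in seq_len(nrow(edges))) {
    s <- edges$steps[r]
    if (s == 1) {
      elist[[length(elist) + 1]] <- c(edges$from[r], edges$to[r])
    } else {
      chain <- c(edges$from[r],
                 paste0("mv", n_int + seq_len(s - 1)),
                 edges$to[r])
      n_int <- n_int + s - 1
      for (q in seq_len(s)) {
        elist[[length(elist) + 1]] <- chain[q:(q + 1)]
      }
    }
  }
  if (n_int > 0) {
    vattr <- rbind(vattr, data.frame(name = paste0("mv", seq_len(n_int)),
                                     freq = 0, inferred = TRUE))
  }
  g <- igraph::graph_from_data_frame(
    if (length(elist)) do.call(rbind, elist) else
      matrix(character(0), 0, 2),
    directed = FALSE, vertices = vattr)
  structure(list(edges = edges, limit = limit,
                 components = setNames(match(comp, unique(comp)),
                                       haps$labels),
                 graph = g),
            class = "tcs_network")
}

#' @export
print.tcs_network <- function(x, ...) {
  cat("tcs_network:", length(x$components), "haplotypes,",
      nrow(x$edges), "edges, limit", x$limit, "steps,",
      length(unique(x$components)), "component(s)\n")
  invisible(x)
}

#' Write a haplotype network as GraphML
#'
#' @param net a `tcs_network`.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "tcs_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
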