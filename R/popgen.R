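#' Per-population diversity statistics
#'
#' Per site, among non-missing calls of a population's members: observed
#' heterozygosity `H_O` is the fraction of heterozygotes; expected
#' heterozygosity uses the unbiased estimator `H_E = 2 p q n/(n - 1)` with
#' `n` the number of sampled alleles; nucleotide diversity `pi` is the
#' average pairwise difference per site, which for a bi-allelic site equals
#' the same unbiased quantity (the two are computed through independent
#' routes and agree by construction).  Population values are
#' ratios-of-sums across sites.  `F_IS = 1 - mean(H_O)/mean(H_E)`
#' (ratio-of-averages, the convention of RAD pipelines; `NA` when the
#' denominator is 0).  In `mode = "all"` the per-site sums are divided by
#' `total_length` (the total number of sequenced positions, polymorphic
#' and non-polymorphic) instead of the SNP count.
#'
#' @param G a [genotype_matrix()].
#' @param pops populations to report (default: all with >= 2 individuals).
#' @param mode `"variant"` (SNP columns only) or `"all"` (requires
#'   `total_length`).
#' @param total_length total sequenced positions for `mode = "all"`.
#' @return data.frame with columns pop, n, H_O, H_E, pi, F_IS, mode.
#' @export
diversity <- function(G, pops = NULL, mode = c("variant", "all"),
                      total_length = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  mode <- match.arg(mode)
  if (mode == "all" && is.null(total_length)) {
    stop("mode = \"all\" requires total_length (sequenced positions)")
  }
  if (is.null(pops)) {
    tab <- table(G$pops)
    pops <- names(tab)[tab >= 2]
  }
  if (!all(pops %in% G$pops)) {
    stop("population(s) absent from the genotype matrix: ",
         paste(setdiff(pops, G$pops), collapse = ", "))
  }
  rows <- lapply(pops, function(p) {
    calls <- G$calls[G$pops == p, , drop = FALSE]
    if (nrow(calls) < 2) stop("population ", p, " has < 2 individuals")
    nonmiss <- colSums(!is.na(calls))
    use <- nonmiss > 0
    calls <- calls[, use, drop = FALSE]
    nonmiss <- nonmiss[use]
    n_alleles <- 2 * nonmiss
    x <- colSums(calls, na.rm = TRUE)          # alt allele counts
    p_hat <- x / n_alleles
    ho <- colSums(calls == 1L, na.rm = TRUE) / nonmiss
    he <- 2 * p_hat * (1 - p_hat) * n_alleles / (n_alleles - 1)
    # pairwise route for pi: x (n - x) / choose(n, 2) per site
    pi_site <- x * (n_alleles - x) / (n_alleles * (n_alleles - 1) / 2)
    denom <- if (mode == "variant") length(ho) else total_length
    HO <- sum(ho) / denom
    HE <- sum(he) / denom
    PI <- sum(pi_site) / denom
    FIS <- if (sum(he) > 0) 1 - sum(ho) / sum(he) else NA_real_
    data.frame(pop = p, n = nrow(calls), H_O = HO, H_E = HE, pi = PI,
               F_IS = FIS, mode = mode)
  })
  do.call(rbind, rows)
}

#' Per-individual heterozygosity
#'
#' Proportion of heterozygous calls among an individual's non-missing SNP
#' calls.  Individuals with no non-missing calls are returned as `NA` with
#' a warning.
#'
#' @param G a [genotype_matrix()].
#' @return named numeric vector.
#' @export
individual_heterozygosity <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  nonmiss <- rowSums(!is.na(G$calls))
  het <- rowSums(G$calls == 1L, na.rm = TRUE)
  out <- het / nonmiss
  if (any(nonmiss == 0)) {
    warning(sum(nonmiss == 0), " individual(s) with all calls missing ",
            "reported as NA")
    out[nonmiss == 0] <- NA_real_
  }
  out
}

#' KING-robust pairwise kinship
#'
#' The within-pair robust estimator
#' `phi_ij = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`, computed over the
#' SNPs where both individuals have calls: `N_AaAa` both-heterozygous
#' sites, `N_AAaa` opposite-homozygote sites, `N_Aa(.)` the heterozygous
#' site counts of each member over the shared sites.  Values are ~0.5 for
#' self, ~0.25 for parent-offspring or full sibs, ~0 (possibly negative)
#' for unrelated pairs.  Pairs with fewer overlapping calls than
#' `min_overlap` are flagged unreliable (see the `reliable` attribute).
#'
#' @param G a [genotype_matrix()].
#' @param min_overlap minimum overlapping non-missing SNPs per pair.
#' @return symmetric matrix of kinship estimates with attributes `overlap`
#'   (pairwise call counts) and `reliable` (logical matrix).
#' @export
kinship_king <- function(G, min_overlap = 100) {
  stopifnot(inherits(G, "genotype_matrix"))
  calls <- G$calls
  M <- !is.na(calls)
  H <- (calls == 1L); H[is.na(H)] <- FALSE
  AA <- (calls == 0L); AA[is.na(AA)] <- FALSE
  aa <- (calls == 2L); aa[is.na(aa)] <- FALSE
  storage.mode(M) <- storage.mode(H) <- storage.mode(AA) <-
    storage.mode(aa) <- "double"
  overlap <- M %*% t(M)
  hethet <- H %*% t(H)
  opp <- AA %*% t(aa) + aa %*% t(AA)
  het_i <- H %*% t(M)          # i's het sites that j also called
  denom <- het_i + t(het_i)
  phi <- (hethet - 2 * opp) / denom
  phi[denom == 0] <- NA_real_
  dimnames(phi) <- list(rownames(calls), rownames(calls))
  attr(phi, "overlap") <- overlap
  attr(phi, "reliable") <- overlap >= min_overlap
  class(phi) <- c("kinship_matrix", class(phi))
  phi
}

#' Select an unrelated individual set
#'
#' Resolves the graph of pairs with kinship above `threshold` by
#' repeatedly dropping, within each connected component, the individual
#' with the highest missingness (ties broken by dropping the
#' lexicographically later id) until no edge remains -- the "keep the
#' individual with less missing data" rule.  Pairs flagged unreliable in
#' the kinship matrix contribute no edges.
#'
#' @param kin a matrix from [kinship_king()].
#' @param missingness named per-individual missing-data proportions.
#' @param threshold kinship above which a pair counts as related
#'   (default 0: any positive kinship).
#' @return character vector of retained ids.
#' @export
select_unrelated <- function(kin, missingness, threshold = 0) {
  ids <- rownames(kin)
  stopifnot(!is.null(ids), all(ids %in% names(missingness)))
  rel <- attr(kin, "reliable")
  adj <- !is.na(kin) & kin > threshold
  if (!is.null(rel)) adj <- adj & rel
  diag(adj) <- FALSE
  alive <- setNames(rep(TRUE, length(ids)), ids)
  repeat {
    sub <- adj[alive, alive, drop = FALSE]
    deg <- rowSums(sub)
    if (all(deg == 0)) break
    # connected components among currently-edged nodes
    comp <- graph_components(sub)
    drop <- character(0)
    for (cc in unique(comp)) {
      members <- names(comp)[comp == cc]
      if (sum(sub[members, members]) == 0) next
      miss <- missingness[members]
      cand <- members[miss == max(miss)]  # tie -> drop the later id
      drop <- c(drop, sort(cand, decreasing = TRUE)[1])
    }
    alive[drop] <- FALSE
  }
  names(alive)[alive]
}

# label connected components of a logical adjacency matrix
graph_components <- function(adj) {
  ids <- rownames(adj)
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (v in ids) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cur
      queue <- c(queue, ids[adj[u, ] & is.na(comp)])
    }
  }
  comp
}

# Weir-Cockerham variance components for one permutation-block of
# population label assignments; vectorised over loci.
wc_components <- function(calls, pop_ind) {
  # pop_ind: list of logical index vectors, one per population
  r <- length(pop_ind)
  L <- ncol(calls)
  n_i <- p_i <- h_i <- vector("list", r)
  for (k in seq_len(r)) {
    sub <- calls[pop_ind[[k]], , drop = FALSE]
    n_i[[k]] <- colSums(!is.na(sub))
    p_i[[k]] <- colSums(sub, na.rm = TRUE) / (2 * n_i[[k]])
    h_i[[k]] <- colSums(sub == 1L, na.rm = TRUE) / n_i[[k]]
  }
  n_mat <- do.call(rbind, n_i)
  p_mat <- do.call(rbind, p_i)
  h_mat <- do.call(rbind, h_i)
  ok <- colSums(n_mat >= 1) == r
  n_mat <- n_mat[, ok, drop = FALSE]
  p_mat <- p_mat[, ok, drop = FALSE]
  h_mat <- h_mat[, ok, drop = FALSE]
  nbar <- colMeans(n_mat)
  ntot <- colSums(n_mat)
  nc <- (ntot - colSums(n_mat^2) / ntot) / (r - 1)
  pbar <- colSums(n_mat * p_mat) / ntot
  s2 <- colSums(n_mat * (p_mat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_mat * h_mat) / ntot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) *
       hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST with a permutation test
#'
#' The variance-components estimator summed over loci
#' (`theta = sum(a) / sum(a + b + c)`), with significance from permuting
#' individual population labels; `p = (1 + #[F_perm >= F_obs]) /
#' (1 + n_permutations)` (add-one convention, so p is never exactly 0).
#'
#' @param G a [genotype_matrix()].
#' @param pops the two (or more) population labels to compare.
#' @param n_permutations label permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return list with elements `fst`, `p_value`, `n_permutations`.
#' @export
fst_wc <- function(G, pops, n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), length(pops) >= 2)
  sel <- G$pops %in% pops
  calls <- G$calls[sel, , drop = FALSE]
  labels <- G$pops[sel]
  sizes <- table(labels)[pops]
  if (any(sizes < 2)) stop("each population needs >= 2 individuals")
  poly <- vapply(seq_len(ncol(calls)), function(s) {
    v <- calls[, s]; v <- v[!is.na(v)]
    x <- sum(v); x > 0 && x < 2 * length(v)
  }, TRUE)
  if (!any(poly)) {
    stop("F_ST is undefined: no polymorphic SNPs among the selected ",
         "individuals")
  }
  calls <- calls[, poly, drop = FALSE]
  theta_of <- function(lab) {
    idx <- lapply(pops, function(p) lab == p)
    w <- wc_components(calls, idx)
    sum(w$a) / sum(w$a + w$b + w$c)
  }
  fst <- theta_of(labels)
  p_value <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      exceed <- exceed + (theta_of(sample(labels)) >= fst)
    }
    p_value <- (1 + exceed) / (1 + n_permutations)
  }
  list(fst = fst, p_value = p_value, n_permutations = n_permutations)
}
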