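#' SNP filtering configuration
#'
#' @param presence_threshold minimum fraction of individuals with a
#'   non-missing call (the `R = 0.75` rule of RAD pipelines; computed over
#'   all individuals in the matrix, not per population).
#' @param maf_min minimum minor allele frequency, computed over non-missing
#'   calls only; the boundary is inclusive; 0 disables the filter.
#' @param one_snp_per_locus keep one uniformly-random SNP per RAD locus.
#' @param seed seed for the random SNP choice.
#' @export
filter_config <- function(presence_threshold = 0.75, maf_min = 0.01,
                          one_snp_per_locus = TRUE, seed = NULL) {
  stopifnot(presence_threshold > 0, presence_threshold <= 1,
            maf_min >= 0, maf_min < 0.5)
  structure(list(presence_threshold = presence_threshold,
                 maf_min = maf_min,
                 one_snp_per_locus = isTRUE(one_snp_per_locus),
                 seed = seed), class = "filter_config")
}

#' Filter SNP columns by presence, MAF and one-SNP-per-locus
#'
#' @param G a [genotype_matrix()].
#' @param f a [filter_config()].
#' @return the filtered [genotype_matrix()] with a `filter` attribute
#'   recording the configuration and per-step retention counts.
#' @export
filter_loci <- function(G, f = filter_config()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(f, "filter_config"))
  calls <- G$calls
  n_ind <- nrow(calls)
  nonmiss <- colSums(!is.na(calls))
  keep_presence <- nonmiss / n_ind >= f$presence_threshold
  alt <- colSums(calls, na.rm = TRUE)
  freq <- alt / (2 * nonmiss)
  maf <- pmin(freq, 1 - freq)
  keep_maf <- if (f$maf_min > 0) maf >= f$maf_min else rep(TRUE, ncol(calls))
  keep <- keep_presence & keep_maf
  counts <- c(input = ncol(calls), after_presence = sum(keep_presence),
              after_maf = sum(keep))
  idx <- which(keep)
  if (f$one_snp_per_locus && length(idx)) {
    if (!is.null(f$seed)) set.seed(f$seed)
    grp <- split(idx, G$locus_ids[idx])
    idx <- sort(vapply(grp, function(g)
      if (length(g) == 1L) g else g[sample.int(length(g), 1)], 0L))
  }
  counts <- c(counts, after_one_snp = length(idx))
  if (length(idx) == 0L) {
    stop("all SNP columns were removed by the filters (R = ",
         f$presence_threshold, ", MAF >= ", f$maf_min, ")")
  }
  out <- genotype_matrix(G$calls[, idx, drop = FALSE], G$locus_ids[idx],
                         G$pops)
  attr(out, "filter") <- list(config = f, retained = counts)
  out
}

#' Downsample individuals per population and drop missing data
#'
#' Keeps, per population, the target number of individuals and then drops
#' every SNP column with any remaining missing call, so the resulting
#' matrix is complete and suitable for joint-SFS tallying.  The default
#' deterministic strategy keeps the individuals with the least missing data
#' (ties broken by id order); `"random"` draws a seeded random subset.
#'
#' @param G a [genotype_matrix()].
#' @param targets named per-population counts, or a single fraction in
#'   (0, 1) applied to every population (floored).
#' @param strategy `"least_missing"` (default) or `"random"`.
#' @param seed seed for the random strategy.
#' @return a complete-data [genotype_matrix()].
#' @export
downsample_individuals <- function(G, targets,
                                   strategy = c("least_missing", "random"),
                                   seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  strategy <- match.arg(strategy)
  tab <- table(G$pops)
  if (length(targets) == 1L && is.null(names(targets)) && targets > 0 &&
      targets < 1) {
    targets <- setNames(as.integer(floor(as.numeric(tab) * targets)),
                        names(tab))
  }
  if (is.null(names(targets)) || !all(names(targets) %in% names(tab))) {
    stop("targets must be named by population")
  }
  if (any(targets > tab[names(targets)])) {
    stop("downsampling target exceeds available individuals in: ",
         paste(names(targets)[targets > tab[names(targets)]],
               collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- unlist(lapply(names(targets), function(p) {
    ids <- rownames(G$calls)[G$pops == p]
    if (strategy == "least_missing") {
      miss <- rowSums(is.na(G$calls[ids, , drop = FALSE]))
      ids <- ids[order(miss, ids)]
      ids[seq_len(targets[[p]])]
    } else {
      sample(ids, targets[[p]])
    }
  }))
  calls <- G$calls[keep, , drop = FALSE]
  complete <- colSums(is.na(calls)) == 0
  genotype_matrix(calls[, complete, drop = FALSE], G$locus_ids[complete],
                  G$pops[keep])
}

# ---- folded SFS container -------------------------------------------------

new_folded_sfs <- function(counts, sample_sizes, mask) {
  n_snps <- sum(counts[!mask])
  structure(list(dims = length(sample_sizes), counts = counts,
                 sample_sizes = sample_sizes, mask = mask,
                 n_snps = n_snps), class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("folded", if (x$dims == 2) "joint", "SFS;",
      "haploid sample sizes:", paste(x$sample_sizes, collapse = " + "),
      "\n  polymorphic mass:", format(x$n_snps), "over",
      sum(!x$mask), "unmasked cells\n")
  invisible(x)
}

# structural mask for a folded spectrum: monomorphic corners plus the
# folded-away half (total minor count beyond n/2)
folded_mask <- function(sample_sizes) {
  if (length(sample_sizes) == 1L) {
    n <- sample_sizes
    d <- 0:n
    mask <- d == 0 | d == n | d > n / 2
  } else {
    n1 <- sample_sizes[1]; n2 <- sample_sizes[2]
    d <- outer(0:n1, 0:n2, "+")
    mask <- d > (n1 + n2) / 2
    mask[1, 1] <- TRUE
    mask[n1 + 1, n2 + 1] <- TRUE
  }
  mask
}

# fold an unfolded count array (indices = derived counts) with half-weight
# merging of self-complementary configurations
fold_counts <- function(unfolded, sample_sizes) {
  if (length(sample_sizes) == 1L) {
    n <- sample_sizes
    out <- numeric(n + 1)
    for (i in 0:n) {
      w <- unfolded[i + 1]
      if (w == 0) next
      ic <- n - i
      if (i < ic) out[i + 1] <- out[i + 1] + w
      else if (i > ic) out[ic + 1] <- out[ic + 1] + w
      else out[i + 1] <- out[i + 1] + w  # self-complementary: stays put
    }
    out
  } else {
    n1 <- sample_sizes[1]; n2 <- sample_sizes[2]
    out <- matrix(0, n1 + 1, n2 + 1)
    for (i in 0:n1) {
      for (j in 0:n2) {
        w <- unfolded[i + 1, j + 1]
        if (w == 0) next
        d <- i + j; dc <- (n1 - i) + (n2 - j)
        if (d < dc) {
          out[i + 1, j + 1] <- out[i + 1, j + 1] + w
        } else if (d > dc) {
          out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + w
        } else {
          # half-weight merge of the self-complementary pair
          out[i + 1, j + 1] <- out[i + 1, j + 1] + w / 2
          out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + w / 2
        }
      }
    }
    out
  }
}

#' Folded (joint) site-frequency spectrum from genotypes
#'
#' Tallies per-SNP minor-allele counts for one population (1-D folded SFS)
#' or two populations (2-D folded joint SFS).  The genotype matrix must be
#' complete for the referenced individuals (use
#' [downsample_individuals()] first).  A configuration and its allele-swap
#' complement are merged once, with the half-weight convention at
#' self-complementary cells; the monomorphic corners are masked, so the sum
#' of unmasked cells equals the number of polymorphic SNPs.
#'
#' @param G a [genotype_matrix()].
#' @param pops one or two population labels.
#' @return a `folded_sfs` object.
#' @export
folded_joint_sfs <- function(G, pops) {
  stopifnot(inherits(G, "genotype_matrix"), length(pops) %in% c(1L, 2L))
  if (!all(pops %in% G$pops)) {
    stop("population(s) absent from the genotype matrix: ",
         paste(setdiff(pops, G$pops), collapse = ", "))
  }
  sub <- lapply(pops, function(p) G$calls[G$pops == p, , drop = FALSE])
  if (any(vapply(sub, function(m) anyNA(m), TRUE))) {
    stop("missing calls present in the referenced individuals; run ",
         "downsample_individuals() first to obtain a complete matrix")
  }
  ns <- vapply(sub, function(m) 2L * nrow(m), 0L)
  cnt <- lapply(sub, colSums)
  if (length(pops) == 1L) {
    unf <- tabulate(cnt[[1]] + 1L, nbins = ns[1] + 1L)
  } else {
    unf <- matrix(0, ns[1] + 1, ns[2] + 1)
    for (s in seq_along(cnt[[1]])) {
      unf[cnt[[1]][s] + 1, cnt[[2]][s] + 1] <-
        unf[cnt[[1]][s] + 1, cnt[[2]][s] + 1] + 1
    }
  }
  folded <- fold_counts(unf, ns)
  new_folded_sfs(folded, ns, folded_mask(ns))
}

#' Hypergeometric projection of a folded SFS to smaller sample sizes
#'
#' Computes the expected spectrum under random subsampling of alleles
#' without replacement.  Mass that projects into the monomorphic corners is
#' removed from the spectrum and reported in the `monomorphic_mass`
#' attribute.  Projection commutes with folding.
#'
#' @param s a `folded_sfs`.
#' @param m target haploid sample sizes (`2 <= m <= sample_sizes`).
#' @return a `folded_sfs` at sizes `m`.
#' @export
project_sfs <- function(s, m) {
  stopifnot(inherits(s, "folded_sfs"), length(m) == s$dims)
  if (any(m < 2)) stop("projection targets must be >= 2 haploids")
  if (any(m > s$sample_sizes)) stop("cannot project upwards")
  n <- s$sample_sizes
  proj1 <- function(n_from, n_to) {
    # P[i' | i]: rows = source count 0..n_from, cols = target count 0..n_to
    outer(0:n_from, 0:n_to, function(i, ip)
      dhyper(ip, i, n_from - i, n_to))
  }
  if (s$dims == 1L) {
    P <- proj1(n, m)
    unf <- as.numeric(s$counts %*% P)
    dim(unf) <- NULL
  } else {
    P1 <- proj1(n[1], m[1]); P2 <- proj1(n[2], m[2])
    unf <- t(P1) %*% s$counts %*% P2
  }
  folded <- fold_counts(if (s$dims == 1L) unf else unf, m)
  mask <- folded_mask(m)
  mono <- if (s$dims == 1L) folded[1] + folded[m + 1] else
    folded[1, 1] + folded[m[1] + 1, m[2] + 1]
  out <- new_folded_sfs(folded, m, mask)
  attr(out, "monomorphic_mass") <- mono
  out
}

#' Read and write folded spectra as flat text
#'
#' A dadi/fastsimcoal-style layout: a header with the dimensionality and
#' haploid sample sizes, the counts in row-major order, and a 0/1 mask
#' line.  `read_sfs(write_sfs(x))` round-trips bit-exactly.
#'
#' @param s a `folded_sfs`.
#' @param path file path.
#' @export
write_sfs <- function(s, path) {
  stopifnot(inherits(s, "folded_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# tealdemog folded SFS",
               paste("dims", s$dims),
               paste("sample_sizes", paste(s$sample_sizes, collapse = " ")),
               paste(sprintf("%.17g", as.numeric(s$counts)),
                     collapse = " "),
               paste(as.integer(s$mask), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  dims <- as.integer(strsplit(ln[1], " ")[[1]][2])
  ns <- as.integer(strsplit(ln[2], " ")[[1]][-1])
  counts <- as.numeric(strsplit(trimws(ln[3]), " +")[[1]])
  mask <- as.logical(as.integer(strsplit(trimws(ln[4]), " +")[[1]]))
  if (dims == 2L) {
    counts <- matrix(counts, ns[1] + 1, ns[2] + 1)
    mask <- matrix(mask, ns[1] + 1, ns[2] + 1)
  }
  new_folded_sfs(counts, ns, mask)
}
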