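#' Genotype matrix container
#'
#' Individuals x SNP genotype calls coded 0/1/2 (count of the alternate
#' allele) with `NA` for missing, a RAD-locus identifier per SNP column and
#' a population label per individual.
#'
#' @param calls integer matrix, individuals in rows (rownames = ids).
#' @param locus_ids character/integer vector, one per column.
#' @param pops named character vector of population labels (names = ids).
#' @export
genotype_matrix <- function(calls, locus_ids, pops) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ind%03d", seq_len(nrow(calls)))
  }
  if (length(locus_ids) != ncol(calls)) {
    stop("locus_ids length must equal the number of SNP columns")
  }
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (ncol(calls) > 0 && any(colSums(!is.na(calls)) == 0)) {
    stop("every SNP column needs at least one non-missing call")
  }
  pops <- pops[rownames(calls)]
  if (any(is.na(pops))) stop("every individual needs a population label")
  structure(list(calls = calls, locus_ids = as.character(locus_ids),
                 pops = pops), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "SNPs (", length(unique(x$locus_ids)), "loci )\n")
  cat("  populations:", paste(sprintf("%s=%d", names(table(x$pops)),
                                      table(x$pops)), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Aligned sequence container
#'
#' Equal-length nucleotide sequences (upper-case strings over A/C/G/T/N/-)
#' with sample ids and population labels, e.g. an mtDNA control-region
#' alignment.
#'
#' @param sequences character vector of equal-length sequences.
#' @param ids sample identifiers (defaults to names of `sequences`).
#' @param pops population label per sequence.
#' @export
sequence_alignment <- function(sequences, ids = names(sequences), pops) {
  sequences <- toupper(sequences)
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(sequences))
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("sequences must be aligned to equal length (offending: ",
         ids[which(nchar(sequences) != len[1])[1]], ")")
  }
  if (len == 0) stop("alignment length must be > 0")
  if (any(grepl("[^ACGTN-]", sequences))) {
    stop("sequences may only contain A, C, G, T, N or -")
  }
  if (length(pops) != length(sequences)) {
    stop("one population label per sequence is required")
  }
  structure(list(sequences = unname(sequences), ids = ids,
                 pops = unname(pops), length = len),
            class = "sequence_alignment")
}

#' @export
print.sequence_alignment <- function(x, ...) {
  cat("sequence_alignment:", length(x$sequences), "sequences of",
      x$length, "bp;", length(unique(x$pops)), "populations\n")
  invisible(x)
}

#' Pedigree specification for relatedness simulation
#'
#' Declares individuals to append to a simulated unrelated panel as
#' Mendelian offspring of named parents.  Declaring two children with the
#' same parent pair yields full sibs; a child of a child is allowed as long
#' as parents precede children in the list.
#'
#' @param children data.frame with columns `id`, `parent1`, `parent2` and
#'   optionally `pop` (defaults to parent1's population).
#' @export
pedigree_spec <- function(children) {
  stopifnot(is.data.frame(children),
            all(c("id", "parent1", "parent2") %in% names(children)))
  if (anyDuplicated(children$id)) stop("pedigree ids must be unique")
  structure(list(children = children), class = "pedigree_spec")
}

#' Simulate genealogies under a demographic model
#'
#' Runs the continuous-time structured coalescent: lineages within a deme of
#' haploid size N coalesce pairwise at rate 1/N per generation, migrate
#' backwards in time at the model's rates, merge into the ancestral deme at
#' the split time, and follow piecewise-constant ancestral sizes.
#'
#' @param model a [demographic_model()].
#' @param samples_per_deme haploid sample sizes, one per deme.
#' @param n_loci number of independent genealogies.
#' @param seed optional integer seed.
#' @return list of genealogies; each has 1-based `parent` pointers over the
#'   `2n - 1` nodes (leaves first, root last, `NA` parent for the root),
#'   `node_time` in generations, `leaf_deme`, `total_length` and `height`.
#' @export
simulate_genealogies <- function(model, samples_per_deme, n_loci = 1,
                                 seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  nd <- length(model$demes)
  if (length(samples_per_deme) != nd || any(samples_per_deme < 1)) {
    stop("samples_per_deme needs >= 1 haploid sample for each of the ",
         nd, " deme(s)")
  }
  if (!is.null(seed)) set.seed(seed)
  a <- model_cpp_args(model)
  n1 <- as.integer(samples_per_deme[1])
  n2 <- if (nd == 2L) as.integer(samples_per_deme[2]) else 0L
  trees <- cpp_sim_trees(n1, n2, a$N1, a$N2, a$m12, a$m21, a$Tdiv, a$ancN,
                         a$ancT, as.integer(n_loci))
  lapply(trees, structure, class = "genealogy")
}

#' Overlay infinite-sites mutations on genealogies
#'
#' Mutation counts per genealogy are Poisson with mean `mu * locus_length *
#' total branch length`; each mutation creates one bi-allelic column whose
#' derived-allele carriers are exactly the leaves below the mutated branch.
#'
#' @param genealogies output of [simulate_genealogies()].
#' @param mu mutation rate per site per generation (`>= 0`).
#' @param locus_length locus length in bp.
#' @return list of 0/1 matrices (leaves x segregating sites).
#' @export
drop_mutations <- function(genealogies, mu, locus_length) {
  stopifnot(mu >= 0, locus_length >= 1)
  lapply(genealogies, function(tr) {
    n <- tr$n_leaves
    m <- length(tr$parent)
    blen <- ifelse(is.na(tr$parent), 0, tr$node_time[tr$parent] -
                     tr$node_time)
    S <- rpois(1, mu * locus_length * sum(blen))
    out <- matrix(0L, n, S)
    if (S > 0) {
      branches <- sample.int(m, S, replace = TRUE, prob = blen)
      desc <- descendant_leaves(tr)
      for (s in seq_len(S)) out[desc[[branches[s]]], s] <- 1L
    }
    out
  })
}

# leaves below each node (list over nodes)
descendant_leaves <- function(tr) {
  n <- tr$n_leaves
  m <- length(tr$parent)
  desc <- vector("list", m)
  for (i in seq_len(n)) desc[[i]] <- i
  # internal nodes are created in increasing time order, so children have
  # smaller indices than parents and one forward pass suffices
  kids <- split(seq_len(m)[!is.na(tr$parent)],
                tr$parent[!is.na(tr$parent)])
  for (v in (n + 1):m) {
    desc[[v]] <- unlist(desc[kids[[as.character(v)]]], use.names = FALSE)
  }
  desc
}

#' Simulate a diploid SNP dataset
#'
#' Simulates `cfg$n_loci` unlinked loci under the model, forms diploid
#' individuals by pairing consecutive haplotypes within each deme, inserts
#' i.i.d. missing calls, and optionally appends Mendelian offspring
#' declared in a [pedigree_spec()].  SNP columns that end up entirely
#' missing are dropped (with a message) so the matrix invariant holds.
#'
#' @param model a [demographic_model()].
#' @param cfg a [sim_config()]; `cfg$samples` are diploid individuals per
#'   deme.
#' @param pedigree optional [pedigree_spec()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return a [genotype_matrix()].
#' @export
simulate_dataset <- function(model, cfg = sim_config(), pedigree = NULL,
                             seed = cfg$seed) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(cfg, "sim_config"))
  nd <- length(model$demes)
  samples <- cfg$samples
  if (length(samples) != nd) {
    samples <- samples[seq_len(nd)]
  }
  if (!is.null(seed)) set.seed(seed)
  a <- model_cpp_args(model)
  h1 <- 2L * as.integer(samples[1])
  h2 <- if (nd == 2L) 2L * as.integer(samples[2]) else 0L
  loci <- cpp_sim_snp_loci(h1, h2, a$N1, a$N2, a$m12, a$m21, a$Tdiv,
                           a$ancN, a$ancT, cfg$n_loci,
                           cfg$mu * cfg$locus_length)
  nsnp <- vapply(loci, ncol, 0L)
  keep <- nsnp > 0L
  haplo <- do.call(cbind, c(loci[keep], list(matrix(0L, h1 + h2, 0))))
  locus_ids <- rep(sprintf("locus%05d", which(keep)), nsnp[keep])
  # diploids: haplotypes 2i-1, 2i
  n_ind <- (h1 + h2) / 2L
  calls <- haplo[seq(1, h1 + h2, 2), , drop = FALSE] +
    haplo[seq(2, h1 + h2, 2), , drop = FALSE]
  pops <- rep(model$demes, samples)
  ids <- unlist(lapply(seq_len(nd), function(d)
    sprintf("%s_%02d", model$demes[d], seq_len(samples[d]))))
  rownames(calls) <- ids
  names(pops) <- ids
  if (!is.null(pedigree)) {
    stopifnot(inherits(pedigree, "pedigree_spec"))
    for (r in seq_len(nrow(pedigree$children))) {
      ch <- pedigree$children[r, ]
      if (!all(c(ch$parent1, ch$parent2) %in% rownames(calls))) {
        stop("pedigree references unknown parent id(s) for child ", ch$id)
      }
      g <- mendelian_child(calls[ch$parent1, ], calls[ch$parent2, ])
      calls <- rbind(calls, g)
      rownames(calls)[nrow(calls)] <- ch$id
      pops[ch$id] <- if (!is.null(ch$pop) && !is.na(ch$pop)) ch$pop else
        pops[[ch$parent1]]
    }
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < cfg$missing_rate, nrow(calls))
    calls[mask] <- NA_integer_
    dead <- colSums(!is.na(calls)) == 0
    if (any(dead)) {
      message("dropping ", sum(dead), " SNP column(s) left fully missing")
      calls <- calls[, !dead, drop = FALSE]
      locus_ids <- locus_ids[!dead]
    }
  }
  genotype_matrix(calls, locus_ids, pops)
}

# one Mendelian draw per locus from two parental genotype vectors
mendelian_child <- function(g1, g2) {
  gam <- function(g) {
    out <- integer(length(g))
    het <- !is.na(g) & g == 1L
    out[het] <- rbinom(sum(het), 1, 0.5)
    out[!is.na(g) & g == 2L] <- 1L
    out[is.na(g)] <- NA_integer_
    out
  }
  gam(g1) + gam(g2)
}

#' Simulate an mtDNA alignment
#'
#' A single non-recombining haploid genealogy is simulated for the whole
#' sample (one sequence per individual) with all model sizes rescaled by
#' `mt_ne_factor` (default one half of the haploid nuclear size, reflecting
#' maternal haploid inheritance).  Sequences then evolve from a random root
#' under finite-sites Jukes-Cantor mutation, so reverse and parallel
#' substitutions (homoplasy) are possible, as in real control-region data.
#'
#' @param model a [demographic_model()].
#' @param cfg a [sim_config()] (supplies sample sizes and the seed default).
#' @param seq_length fragment length in bp (default 169, a short
#'   control-region fragment).
#' @param mu_mt mtDNA mutation rate per site per generation.  The default
#'   2e-6 -- a fast control-region rate -- was chosen once so that
#'   study-like divergence histories (recent split, small ancestral deme)
#'   yield the haplotype richness seen in real control-region samples
#'   (several to ~15 haplotypes in samples of tens of birds).
#' @param mt_ne_factor mtDNA effective-size scaling factor.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return a [sequence_alignment()].
#' @export
simulate_mtdna <- function(model, cfg = sim_config(), seq_length = 169,
                           mu_mt = 2e-6, mt_ne_factor = 0.5,
                           seed = cfg$seed) {
  stopifnot(seq_length > 0, mu_mt >= 0, mt_ne_factor > 0)
  mt_model <- model
  mt_model$theta_contemp <- model$theta_contemp * mt_ne_factor
  mt_model$anc_sizes <- model$anc_sizes * mt_ne_factor
  if (!is.null(seed)) set.seed(seed)
  nd <- length(model$demes)
  samples <- cfg$samples[seq_len(nd)]
  tr <- simulate_genealogies(mt_model, as.integer(samples), n_loci = 1)[[1]]
  m <- length(tr$parent)
  bases <- c("A", "C", "G", "T")
  seqs <- matrix("", m, seq_length)
  seqs[m, ] <- sample(bases, seq_length, replace = TRUE)
  # walk from the root down (children have smaller indices than parents)
  for (v in seq(m - 1, 1)) {
    s <- seqs[tr$parent[v], ]
    blen <- tr$node_time[tr$parent[v]] - tr$node_time[v]
    nmut <- rpois(1, mu_mt * seq_length * blen)
    if (nmut > 0) {
      for (k in seq_len(nmut)) {
        site <- sample.int(seq_length, 1)
        s[site] <- sample(setdiff(bases, s[site]), 1)
      }
    }
    seqs[v, ] <- s
  }
  n <- tr$n_leaves
  pops <- rep(model$demes, samples)
  ids <- unlist(lapply(seq_len(nd), function(d)
    sprintf("%s_mt%02d", model$demes[d], seq_len(samples[d]))))
  sequence_alignment(apply(seqs[seq_len(n), , drop = FALSE], 1, paste,
                           collapse = ""), ids = ids, pops = pops)
}
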