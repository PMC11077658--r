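#' Two-deme demographic model with epochs and migration
#'
#' Describes the divergence history of two contemporary demes (by default
#' "ES" and "IQ", the Spanish and Iraqi populations of a split pair) on a
#' generations-before-present time axis: constant contemporary haploid sizes
#' back to the split at `T_div`, then a single ancestral deme whose haploid
#' size is piecewise constant (one, two or three ancestral epochs).
#' Migration is defined backwards in time: a lineage in deme i jumps to deme
#' j at rate `migration[i, j]` per generation.
#'
#' All population sizes are HAPLOID lineage counts (the convention in which
#' a mutation-scaled size of, say, 16388 haploid individuals means a pair of
#' lineages coalesces at rate 1/16388 per generation).  Diploid individuals
#' are formed downstream by pairing two haplotypes; do not multiply by two
#' again.
#'
#' @param theta_contemp named numeric vector of contemporary haploid sizes,
#'   one per deme (names become the deme labels).  A single entry gives a
#'   one-deme model (then `T_div` and `migration` are ignored and the
#'   ancestral epochs describe the whole history from the present).
#' @param T_div split time in generations before present.
#' @param migration 2x2 backwards migration-rate matrix (per generation), a
#'   single number for symmetric migration, or `NULL`/0 for strict isolation.
#' @param anc_sizes haploid sizes of the ancestral epochs, most recent
#'   first; the first applies from `T_div` backwards.
#' @param anc_times times (generations before present) at which the
#'   ancestral size changes; increasing, all `> T_div`; one fewer than
#'   `anc_sizes`.
#' @return an object of class `demographic_model`.
#' @examples
#' # one-epoch isolation-with-migration model, symmetric gene flow
#' m <- demographic_model(c(ES = 16388, IQ = 48654), T_div = 407,
#'                        migration = 8.71e-7, anc_sizes = 3225)
#' @export
demographic_model <- function(theta_contemp, T_div = 0, migration = NULL,
                              anc_sizes, anc_times = numeric(0)) {
  stopifnot(is.numeric(theta_contemp), length(theta_contemp) %in% c(1L, 2L),
            all(theta_contemp > 0))
  if (is.null(names(theta_contemp))) {
    names(theta_contemp) <- c("ES", "IQ")[seq_along(theta_contemp)]
  }
  stopifnot(is.numeric(anc_sizes), length(anc_sizes) >= 1L,
            length(anc_sizes) <= 3L, all(anc_sizes > 0))
  if (length(anc_times) != length(anc_sizes) - 1L) {
    stop("`anc_times` must have one fewer entry than `anc_sizes`")
  }
  one_deme <- length(theta_contemp) == 1L
  if (one_deme) {
    T_div <- 0
    mig <- matrix(0, 2, 2)
  } else {
    stopifnot(T_div >= 0)
    if (is.null(migration)) migration <- 0
    if (length(migration) == 1L) {
      mig <- matrix(c(0, migration, migration, 0), 2, 2)
    } else {
      mig <- as.matrix(migration)
      stopifnot(identical(dim(mig), c(2L, 2L)))
    }
    if (any(mig < 0)) stop("migration rates must be >= 0")
    diag(mig) <- 0
  }
  if (length(anc_times)) {
    if (any(diff(c(T_div, anc_times)) <= 0)) {
      stop("ancestral epoch times must be increasing and exceed T_div")
    }
  }
  structure(list(demes = names(theta_contemp),
                 theta_contemp = theta_contemp,
                 T_div = T_div,
                 migration = mig,
                 anc_sizes = as.numeric(anc_sizes),
                 anc_times = as.numeric(anc_times)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  if (length(x$demes) == 1L) {
    cat("Single-deme demographic model (", x$demes, ")\n", sep = "")
    cat("  epoch sizes (haploid):", paste(signif(x$anc_sizes, 5),
                                          collapse = ", "), "\n")
    if (length(x$anc_times)) {
      cat("  size-change times (gen):", paste(x$anc_times, collapse = ", "),
          "\n")
    }
  } else {
    cat("Two-deme demographic model (", paste(x$demes, collapse = " / "),
        ")\n", sep = "")
    cat("  contemporary haploid sizes:",
        paste(sprintf("%s=%s", x$demes, signif(x$theta_contemp, 6)),
              collapse = ", "), "\n")
    cat("  T_div:", x$T_div, "generations\n")
    cat("  backwards migration rates:", x$migration[1, 2], "/",
        x$migration[2, 1], "per generation\n")
    cat("  ancestral sizes:", paste(signif(x$anc_sizes, 5), collapse = ", "),
        if (length(x$anc_times)) paste("changing at",
                                       paste(x$anc_times, collapse = ", ")),
        "\n")
  }
  invisible(x)
}

# internal: arguments for the C++ simulator
model_cpp_args <- function(model) {
  if (length(model$demes) == 1L) {
    list(N1 = model$anc_sizes[1], N2 = 1, m12 = 0, m21 = 0, Tdiv = 0,
         ancN = model$anc_sizes, ancT = model$anc_times)
  } else {
    list(N1 = unname(model$theta_contemp[1]),
         N2 = unname(model$theta_contemp[2]),
         m12 = model$migration[1, 2], m21 = model$migration[2, 1],
         Tdiv = model$T_div, ancN = model$anc_sizes, ancT = model$anc_times)
  }
}

#' The nine-model divergence family
#'
#' The model family crosses three ancestral-demography levels (A: constant
#' ancestral size; B: one ancestral size change; C: two changes) with three
#' gene-flow levels (1: strict isolation, SI; 2: symmetric
#' isolation-with-migration, IM; 3: asymmetric IM).  `model_family()` lists
#' the free parameters and parameter count of each model; `build_model()`
#' assembles a [demographic_model()] from a named parameter vector, with the
#' Iraqi contemporary size `theta_IQ` supplied as a fixed constant (it is
#' not estimable from a polymorphism-only SFS and is fixed from nucleotide
#' diversity, see [theta_from_pi()]).
#'
#' @param id model identifier, one of `"A1"` ... `"C3"`.
#' @return `model_family()`: a data.frame with one row per model (id, k and
#'   free-parameter names); `model_params()`: the free-parameter names of
#'   one model.
#' @export
model_family <- function() {
  ids <- c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3")
  data.frame(model = ids,
             demography = rep(c("one-epoch", "two-epoch", "three-epoch"),
                              each = 3),
             migration = rep(c("SI", "IM symmetric", "IM asymmetric"), 3),
             k = c(3L, 4L, 5L, 5L, 6L, 7L, 7L, 8L, 9L),
             params = I(lapply(ids, model_params)),
             stringsAsFactors = FALSE)
}

#' @rdname model_family
#' @export
model_params <- function(id) {
  id <- match.arg(id, c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2",
                        "C3"))
  base <- c("theta_ANC", "theta_ES", "T_DIV")
  mig <- switch(substr(id, 2, 2), "1" = character(0), "2" = "m_S",
                "3" = c("m_ES_IQ", "m_IQ_ES"))
  epochs <- switch(substr(id, 1, 1), A = character(0),
                   B = c("theta_BOT1", "T_BOT1"),
                   C = c("theta_BOT1", "T_BOT1", "theta_BOT2", "T_BOT2"))
  c(base, mig, epochs)
}

#' @rdname model_family
#' @param params named numeric vector holding the free parameters of the
#'   model (see `model_params(id)`).  Epoch-change times `T_BOT1`/`T_BOT2`
#'   are absolute generations before present and must satisfy
#'   `T_BOT2 > T_BOT1 > T_DIV`.
#' @param theta_IQ fixed contemporary haploid size of the second deme.
#' @export
build_model <- function(id, params, theta_IQ) {
  need <- model_params(id)
  if (!all(need %in% names(params))) {
    stop("model ", id, " needs parameters: ", paste(need, collapse = ", "))
  }
  p <- as.list(params[need])
  mig <- switch(substr(id, 2, 2),
                "1" = 0,
                "2" = p$m_S,
                "3" = matrix(c(0, p$m_ES_IQ, p$m_IQ_ES, 0), 2, 2,
                             byrow = TRUE))
  anc_sizes <- c(p$theta_ANC, p$theta_BOT1, p$theta_BOT2)
  anc_times <- c(p$T_BOT1, p$T_BOT2)
  demographic_model(c(ES = unname(p$theta_ES), IQ = unname(theta_IQ)),
                    T_div = unname(p$T_DIV), migration = mig,
                    anc_sizes = unlist(anc_sizes, use.names = FALSE),
                    anc_times = unlist(anc_times, use.names = FALSE))
}

#' Simulation configuration
#'
#' Defaults emulate the study system the package was built around: a
#' ddRAD-style panel of short nuclear loci genotyped in 24 individuals from
#' one deme and 12 from the other, with ~10% missing calls, an Anatidae
#' nuclear mutation rate of 4.83e-9 per site per generation and a 4-year
#' generation time.  At the study-like divergence history (recent split
#' from a small ancestral deme) the default 32,000 loci yield on the order
#' of 2,500 polymorphic SNPs, the scale of the filtered panel the study
#' analysed.
#'
#' @param mu nuclear mutation rate per site per generation.
#' @param generation_time generation time in years.
#' @param n_loci number of independent (unlinked) loci to simulate.
#' @param locus_length locus length in bp.
#' @param missing_rate i.i.d. probability that a genotype call is missing.
#' @param samples named integer vector: diploid individuals per deme.
#' @param seed optional integer seed applied by the simulation functions.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(mu = 4.83e-9, generation_time = 4, n_loci = 32000,
                       locus_length = 300, missing_rate = 0.1,
                       samples = c(ES = 24, IQ = 12), seed = NULL) {
  stopifnot(mu > 0, generation_time > 0, missing_rate >= 0,
            missing_rate < 1, n_loci >= 1, locus_length >= 1,
            all(samples >= 1))
  structure(list(mu = mu, generation_time = generation_time,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 missing_rate = missing_rate, samples = samples,
                 seed = seed), class = "sim_config")
}
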