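#' Monte-Carlo expected folded joint SFS under a model
#'
#' Estimates SNP cell probabilities, conditioned on polymorphism, from the
#' expected branch lengths of simulated genealogies: under infinite sites,
#' the probability that a polymorphic SNP falls in configuration (i, j) is
#' proportional to the expected genealogy length subtending i + j leaves in
#' that configuration.  Cell estimates are folded with the same convention
#' as [folded_joint_sfs()]; empty unmasked cells are floored at a small
#' pseudo-probability before use in log-likelihoods, then renormalized.
#'
#' @param model a [demographic_model()].
#' @param sample_sizes haploid sample sizes per deme.
#' @param n_trees number of simulated genealogies.
#' @param floor_prob pseudo-probability for empty cells; default
#'   `1 / (10 * n_trees)`.
#' @param seed optional integer seed.
#' @return a `folded_sfs`-shaped object whose unmasked cells are
#'   probabilities summing to 1.
#' @export
expected_sfs_mc <- function(model, sample_sizes, n_trees = 5000,
                            floor_prob = NULL, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"), n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- model_cpp_args(model)
  nd <- length(model$demes)
  n1 <- as.integer(sample_sizes[1])
  n2 <- if (nd == 2L) as.integer(sample_sizes[2]) else 0L
  tal <- cpp_sfs_branch_tally(n1, n2, a$N1, a$N2, a$m12, a$m21, a$Tdiv,
                              a$ancN, a$ancT, as.integer(n_trees))
  ns <- if (nd == 2L) c(n1, n2) else n1
  if (nd == 1L) tal <- rowSums(tal)
  folded <- fold_counts(tal, ns)
  mask <- folded_mask(ns)
  p <- folded
  p[mask] <- 0
  tot <- sum(p)
  if (tot <= 0) stop("model produced no polymorphic branch length")
  p <- p / tot
  fl <- floor_prob %||% (1 / (10 * n_trees))
  p[!mask & p < fl] <- fl
  p[!mask] <- p[!mask] / sum(p[!mask])
  new_folded_sfs(p, ns, mask)
}

#' Composite log-likelihood of an observed folded SFS
#'
#' `lnL = sum over unmasked cells of m_cell * ln(p_cell)` in natural log,
#' with the multinomial constant omitted (it cancels in AIC differences).
#'
#' @param obs observed `folded_sfs` (counts).
#' @param probs expected `folded_sfs` (cell probabilities), same shape and
#'   mask.
#' @export
composite_loglik <- function(obs, probs) {
  stopifnot(inherits(obs, "folded_sfs"), inherits(probs, "folded_sfs"))
  if (!identical(obs$sample_sizes, probs$sample_sizes) ||
      !identical(dim(as.matrix(obs$counts)), dim(as.matrix(probs$counts)))) {
    stop("observed and expected spectra have different shapes")
  }
  m <- as.numeric(obs$counts)[!obs$mask]
  p <- as.numeric(probs$counts)[!probs$mask]
  use <- m > 0
  sum(m[use] * log(p[use]))
}

# default search bounds (natural scale); log-uniform starts are drawn
# within these and optimisation runs on the log scale
default_bounds <- function() {
  list(theta = c(1e2, 1e6), time = c(1, 1e5), mig = c(1e-9, 1e-2))
}

param_bounds <- function(pnames, bounds = default_bounds()) {
  lo <- hi <- setNames(numeric(length(pnames)), pnames)
  for (p in pnames) {
    b <- if (startsWith(p, "theta")) bounds$theta
    else if (startsWith(p, "m")) bounds$mig
    else bounds$time
    lo[p] <- b[1]; hi[p] <- b[2]
  }
  list(lo = lo, hi = hi)
}

# absolute epoch times -> increment parameterisation and back, so that the
# ordering T_BOT2 > T_BOT1 > T_DIV holds by construction during search
to_increments <- function(par) {
  if ("T_BOT1" %in% names(par)) {
    par["T_BOT1"] <- par["T_BOT1"] - par["T_DIV"]
    if ("T_BOT2" %in% names(par)) {
      par["T_BOT2"] <- par["T_BOT2"] - (par["T_BOT1"] + par["T_DIV"])
    }
  }
  par
}

from_increments <- function(par) {
  if ("T_BOT1" %in% names(par)) {
    par["T_BOT1"] <- par["T_DIV"] + par["T_BOT1"]
    if ("T_BOT2" %in% names(par)) {
      par["T_BOT2"] <- par["T_BOT1"] + par["T_BOT2"]
    }
  }
  par
}

#' Fit one divergence model to an observed folded joint SFS
#'
#' Maximizes the composite likelihood by multi-start derivative-free
#' search (Nelder-Mead on log-parameters).  Replicate 1 starts from a
#' moment-informed point anchored on the fixed `theta_IQ`; further
#' replicates draw log-uniform starts within the bounds.  Within a
#' replicate the Monte-Carlo expected SFS is computed under common random
#' numbers (a fixed per-replicate seed), which makes the objective
#' deterministic and smooth enough for direct search.  All replicate
#' optima are then re-evaluated at `n_trees_final` genealogies under one
#' data-derived seed so that competing models are compared on the same
#' footing.
#'
#' Because the polymorphism-conditioned folded joint SFS is nearly
#' invariant to a joint rescaling of all sizes and times (with migration
#' scaled inversely) when only one deme size is anchored, the likelihood
#' surface has a long, shallow ridge along that scale direction.  After
#' the replicate search, `fit_model()` therefore profiles the global scale
#' of the best replicate on a one-dimensional grid evaluated at
#' `n_trees_profile` genealogies (with a quadratic refinement and a short
#' high-precision polish).  Set `profile_scale = FALSE` to skip this.
#'
#' @param obs observed `folded_sfs` (2-D).
#' @param model_id one of `"A1"` ... `"C3"`.
#' @param theta_IQ fixed contemporary haploid size of the second deme.
#' @param n_replicates independent optimisation replicates (the full
#'   protocol uses 100; small studies can reduce this).
#' @param n_trees genealogies per objective evaluation during search.
#' @param n_trees_final genealogies for the shared final evaluation and
#'   the polish stage.
#' @param n_trees_profile genealogies per scale-profile point.
#' @param maxit Nelder-Mead iteration budget per replicate.
#' @param polish_maxit iteration budget of the post-profile polish.
#' @param profile_scale profile the global scale after the search.
#' @param bounds list with elements `theta`, `time`, `mig` (length-2
#'   ranges).
#' @param seed integer seed governing starts and replicate seeds.
#' @param eval_seed seed of the shared final evaluation; defaults to a
#'   value derived from the observed counts, so fits of different models
#'   to the same data are comparable.
#' @param extra_starts optional list of named parameter vectors used as
#'   additional search replicates -- e.g. the optimum of a nested model
#'   (with the extra parameters set near their boundary) when fitting a
#'   richer one, the usual sequential protocol for nested families.
#'   Missing parameters are filled from the informed start.
#' @return a `fit_result` list: `model`, `mle` (natural scale), `lnL`,
#'   `k`, `n_replicates`, `replicate_lnL`, `converged`, `seed`.
#' @export
fit_model <- function(obs, model_id, theta_IQ, n_replicates = 3,
                      n_trees = 5000, n_trees_final = 20000,
                      n_trees_profile = 80000, maxit = 120,
                      polish_maxit = 40,
                      profile_scale = TRUE, bounds = default_bounds(),
                      seed = NULL, eval_seed = NULL,
                      extra_starts = NULL) {
  stopifnot(inherits(obs, "folded_sfs"), obs$dims == 2L, theta_IQ > 0)
  pnames <- model_params(model_id)
  b <- param_bounds(pnames, bounds)
  if (!is.null(seed)) set.seed(seed)
  n_extra <- length(extra_starts)
  n_total <- n_replicates + n_extra
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_total + 2)
  if (is.null(eval_seed)) {
    eval_seed <- (floor(sum(obs$counts) * 7) %% 1000003) + 13
  }
  ns <- obs$sample_sizes

  loglik_at <- function(par, nt, sd) {
    mod <- build_model(model_id, par, theta_IQ)
    composite_loglik(obs, expected_sfs_mc(mod, ns, n_trees = nt,
                                          seed = sd))
  }
  objective <- function(logpar, rep_seed) {
    par <- from_increments(setNames(exp(logpar), pnames))
    if (any(par < b$lo * 0.99) || any(par > b$hi * 1.01)) return(1e12)
    -loglik_at(par, n_trees, rep_seed)
  }
  informed_start <- function() {
    st <- c(theta_ANC = theta_IQ / 10, theta_ES = theta_IQ / 3,
            T_DIV = theta_IQ / 100, m_S = 1e-6, m_ES_IQ = 1e-6,
            m_IQ_ES = 1e-6, theta_BOT1 = theta_IQ / 20,
            T_BOT1 = theta_IQ / 20, theta_BOT2 = theta_IQ / 40,
            T_BOT2 = theta_IQ / 10)
    pmin(pmax(st[pnames], b$lo), b$hi)
  }

  best <- vector("list", n_total)
  rep_lnl <- numeric(n_total)
  improved <- logical(n_total)
  for (r in seq_len(n_total)) {
    start <- if (r <= n_replicates) {
      if (r == 1L) informed_start() else
        setNames(exp(runif(length(pnames), log(b$lo), log(b$hi))), pnames)
    } else {
      st <- informed_start()
      ex <- extra_starts[[r - n_replicates]]
      st[intersect(names(ex), pnames)] <- ex[intersect(names(ex), pnames)]
      pmin(pmax(st, b$lo), b$hi)
    }
    lstart <- log(to_increments(start))
    f0 <- objective(lstart, rep_seeds[r])
    opt <- optim(lstart, objective, rep_seed = rep_seeds[r],
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    improved[r] <- opt$value < f0 - 1e-9
    par <- from_increments(setNames(exp(opt$par), pnames))
    # the search runs on a low-precision surface; keep whichever of the
    # start and the optimum scores better at the shared evaluation, so a
    # good supplied start can never be lost to search noise
    ll_opt <- loglik_at(par, n_trees_final, eval_seed)
    ll_start <- loglik_at(start, n_trees_final, eval_seed)
    if (ll_start > ll_opt) {
      rep_lnl[r] <- ll_start
      best[[r]] <- start
    } else {
      rep_lnl[r] <- ll_opt
      best[[r]] <- par
    }
  }
  w <- which.max(rep_lnl)
  mle <- best[[w]]
  lnl <- rep_lnl[w]

  if (profile_scale) {
    is_mig <- startsWith(pnames, "m")
    rescale <- function(par, s) {
      out <- par
      out[!is_mig] <- par[!is_mig] * s
      out[is_mig] <- par[is_mig] / s
      pmin(pmax(out, b$lo), b$hi)
    }
    prof_seed <- rep_seeds[n_total + 1]
    svals <- exp(seq(log(0.35), log(3), length.out = 6))
    lls <- vapply(svals, function(s)
      loglik_at(rescale(mle, s), n_trees_profile, prof_seed), 0)
    sb <- svals[which.max(lls)]
    ls3 <- log(sb) + c(-0.3, 0, 0.3)
    ll3 <- vapply(exp(ls3), function(s)
      loglik_at(rescale(mle, s), n_trees_profile, prof_seed), 0)
    # quadratic refinement on the log-scale axis
    A <- cbind(1, ls3, ls3^2)
    co <- solve(A, ll3)
    sopt <- if (co[3] < 0) exp(-co[2] / (2 * co[3])) else sb
    sopt <- min(max(sopt, 0.3), 3.5)
    cand <- rescale(mle, sopt)
    # short high-precision polish from the profiled point
    polish_obj <- function(logpar) {
      par <- from_increments(setNames(exp(logpar), pnames))
      if (any(par < b$lo * 0.99) || any(par > b$hi * 1.01)) return(1e12)
      -loglik_at(par, n_trees_final, rep_seeds[n_total + 2])
    }
    pol <- optim(log(to_increments(cand)), polish_obj,
                 method = "Nelder-Mead",
                 control = list(maxit = polish_maxit, reltol = 1e-9))
    cand2 <- from_increments(setNames(exp(pol$par), pnames))
    # compare incumbent and candidates at matched precision
    lnl <- loglik_at(mle, n_trees_profile, eval_seed)
    for (cc in list(cand, cand2)) {
      ll <- loglik_at(cc, n_trees_profile, eval_seed)
      if (ll > lnl) {
        mle <- cc
        lnl <- ll
      }
    }
  }

  structure(list(model = model_id, mle = mle, lnL = lnl,
                 k = length(pnames), n_replicates = n_replicates,
                 replicate_lnL = rep_lnl, converged = any(improved),
                 theta_IQ = theta_IQ, sample_sizes = ns, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("model", x$model, " lnL =", format(x$lnL), " k =", x$k,
      if (!x$converged) " [non-convergent]", "\n")
  print(signif(x$mle, 4))
  invisible(x)
}

#' Akaike information criterion
#'
#' @param lnL maximum log-likelihood (natural log).
#' @param k number of free parameters.
#' @return `2 * k - 2 * lnL`.
#' @export
aic <- function(lnL, k) {
  stopifnot(k >= 0)
  2 * k - 2 * lnL
}

#' AIC model-selection table
#'
#' Rescales AIC to the best model (`dAIC`) and computes Akaike weights
#' `w_i = exp(-dAIC_i / 2) / sum_j exp(-dAIC_j / 2)`.
#'
#' @param fits list of `fit_result` objects, or a data.frame with columns
#'   `model`, `lnL`, `k`.
#' @return data.frame with columns model, lnL, k, AIC, dAIC, weight,
#'   ordered by dAIC.
#' @export
model_selection <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits[, c("model", "lnL", "k")]
  } else {
    tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$model, lnL = f$lnL, k = f$k)))
  }
  if (nrow(tab) < 1) stop("at least one fit is required")
  if (anyDuplicated(tab$model)) stop("duplicate model ids")
  tab$AIC <- aic(tab$lnL, tab$k)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  rel <- exp(-tab$dAIC / 2)
  tab$weight <- rel / sum(rel)
  tab[order(tab$dAIC), ]
}

#' Parametric-bootstrap percentile confidence intervals
#'
#' Simulates `B` spectra of the observed polymorphic-SNP count from the
#' fitted model's expected SFS, refits each (with a reduced replicate
#' count), and reports per-parameter 2.5/97.5 percentiles.  Because this is
#' the percentile method, the interval need not contain the point
#' estimate.  Non-convergent bootstrap refits are excluded and counted.
#'
#' @param fit a `fit_result` from [fit_model()].
#' @param n_snps number of polymorphic SNPs per simulated spectrum
#'   (defaults to the count used for a typical RAD panel; pass the observed
#'   `obs$n_snps`).
#' @param B bootstrap replicates.
#' @param n_replicates optimisation replicates per refit.
#' @param ... further arguments to [fit_model()].
#' @param seed integer seed.
#' @return data.frame (param, point, lower, upper) with attributes `B` and
#'   `n_failed`.
#' @export
parametric_bootstrap <- function(fit, n_snps, B = 100, n_replicates = 3,
                                 ..., seed = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("refusing to bootstrap a non-convergent fit")
  if (!is.null(seed)) set.seed(seed)
  mod <- build_model(fit$model, fit$mle, fit$theta_IQ)
  probs <- expected_sfs_mc(mod, fit$sample_sizes, n_trees = 20000,
                           seed = sample.int(1e8, 1))
  boot_seeds <- sample.int(.Machine$integer.max - 1, B)
  est <- matrix(NA_real_, B, length(fit$mle),
                dimnames = list(NULL, names(fit$mle)))
  failed <- 0L
  for (bb in seq_len(B)) {
    counts <- probs
    draw <- rmultinom(1, n_snps, as.numeric(probs$counts)[!probs$mask])
    cm <- as.matrix(probs$counts) * 0
    cm[!probs$mask] <- draw
    counts$counts <- if (probs$dims == 1L) as.numeric(cm) else cm
    counts$n_snps <- n_snps
    rf <- fit_model(counts, fit$model, fit$theta_IQ,
                    n_replicates = n_replicates, seed = boot_seeds[bb],
                    ...)
    if (rf$converged) est[bb, ] <- rf$mle else failed <- failed + 1L
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  ci <- t(apply(est, 2, quantile, c(0.025, 0.975), names = FALSE))
  out <- data.frame(param = names(fit$mle), point = unname(fit$mle),
                    lower = ci[, 1], upper = ci[, 2], row.names = NULL)
  attr(out, "B") <- B
  attr(out, "n_failed") <- failed
  out
}

#' Fixed population size from nucleotide diversity
#'
#' Converts all-sites nucleotide diversity to a haploid effective size via
#' `N_hap = pi / (2 * mu)` (under the haploid-size convention in which a
#' lineage pair coalesces at rate 1/N, expected pairwise diversity is
#' `2 N mu`).
#'
#' @param pi nucleotide diversity per site over all (polymorphic and
#'   non-polymorphic) positions.
#' @param mu mutation rate per site per generation.
#' @export
theta_from_pi <- function(pi, mu) {
  stopifnot(pi >= 0, mu > 0)
  pi / (2 * mu)
}

#' Convert generations to years
#'
#' @param T_generations time in generations.
#' @param generation_time generation time in years (default 4, a typical
#'   duck value).
#' @export
generations_to_years <- function(T_generations, generation_time = 4) {
  stopifnot(all(T_generations >= 0), generation_time >= 0)
  T_generations * generation_time
}
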