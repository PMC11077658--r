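# Analytic folded SFS for a single population with piecewise-constant
# haploid size, via the classical distribution of the number of ancestral
# lineages through time: in coalescent-rescaled time tau the lineage-count
# process is a pure death chain, and
#   P(A_n(tau) = k) = sum_{j=k}^{n} exp(-j(j-1) tau / 2) c_{nkj}
# with alternating-sign coefficients computed in log space.  Expected times
# while k lineages survive then follow by integrating this probability over
# real time, epoch by epoch.

# coefficient c_{nkj} of exp(-j(j-1) tau / 2) in P(A_n(tau) = k)
tavare_coefs <- function(n, k) {
  j <- k:n
  # (2j-1) (-1)^(j-k) k_(j-1) n_[j] / (k! (j-k)! n_(j))
  lg <- log(2 * j - 1) +
    (lgamma(k + j - 1) - lgamma(k)) +            # rising k_(j-1)
    (lgamma(n + 1) - lgamma(n - j + 1)) -        # falling n_[j]
    lgamma(k + 1) - lgamma(j - k + 1) -
    (lgamma(n + j) - lgamma(n))                  # rising n_(j)
  (-1)^(j - k) * exp(lg)
}

#' Expected time spent with k ancestral lineages
#'
#' For a sample of `n` haploid lineages in a single population whose
#' haploid size is `sizes[e]` between `times[e-1]` and `times[e]`
#' (generations before present; `times` are the size-change points, one
#' fewer than `sizes`, and the last epoch extends to infinity), returns
#' `E[T_k]` for `k = 2..n` in generations.
#'
#' @keywords internal
lineage_time_expectation <- function(n, sizes, times = numeric(0)) {
  stopifnot(n >= 2, all(sizes > 0),
            length(times) == length(sizes) - 1)
  if (length(times) && any(diff(c(0, times)) <= 0)) {
    stop("epoch change times must be positive and increasing")
  }
  bnd <- c(0, times, Inf)
  # cumulative rescaled time at epoch boundaries
  lam <- c(0, cumsum(diff(bnd[-length(bnd)]) / sizes[-length(sizes)]))
  ET <- numeric(n - 1)
  for (k in 2:n) {
    co <- tavare_coefs(n, k)
    j <- k:n
    rate <- j * (j - 1) / 2
    tot <- 0
    for (e in seq_along(sizes)) {
      a <- lam[e]
      b <- if (e < length(sizes)) lam[e + 1] else Inf
      eb <- if (is.finite(b)) exp(-rate * b) else 0
      tot <- tot + sizes[e] * sum(co / rate * (exp(-rate * a) - eb))
    }
    ET[k - 1] <- tot
  }
  names(ET) <- paste0("k", 2:n)
  ET
}

#' Analytic expected SFS for a piecewise-constant single population
#'
#' Expected branch length (or mutation rate times it) subtending each
#' allele-count class, from the linear combination of expected
#' level-occupation times: a branch present while k lineages survive
#' subtends i of n leaves with probability
#' `choose(n - i - 1, k - 2) / choose(n - 1, k - 1)`.  For constant size
#' the unfolded spectrum reduces to the neutral `theta / i` shape, and the
#' folded spectrum to `theta (1/i + 1/(n-i)) / (1 + [i == n - i])`.
#'
#' @param sizes haploid sizes per epoch, most recent first.
#' @param times size-change times (generations), one fewer than `sizes`.
#' @param n haploid sample size.
#' @param fold return the folded spectrum (default) or unfolded.
#' @return numeric vector of expected branch lengths per class: unfolded
#'   classes `1..n-1`, or folded classes `1..floor(n/2)`.
#' @export
expected_sfs_analytic_1pop <- function(sizes, times = numeric(0), n,
                                       fold = TRUE) {
  stopifnot(n >= 2)
  if (length(times)) {
    starts <- c(0, times)
    keep <- diff(c(starts, Inf)) > 0
    if (!all(keep)) {
      warning("collapsing zero-duration epoch(s)")
      sizes <- sizes[keep]
      times <- starts[keep][-1]
    }
  }
  ET <- lineage_time_expectation(n, sizes, times)
  xi <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    k <- 2:n
    p <- exp(lchoose(n - i - 1, k - 2) - lchoose(n - 1, k - 1))
    xi[i] <- sum(p * k * ET)
  }
  if (!fold) return(xi)
  nf <- floor(n / 2)
  eta <- numeric(nf)
  for (i in 1:nf) {
    eta[i] <- if (i == n - i) xi[i] else xi[i] + xi[n - i]
  }
  eta
}

#' Stairway-style piecewise-constant N_e reconstruction
#'
#' Fits per-epoch haploid sizes to an observed 1-D folded SFS by maximizing
#' the composite likelihood of the analytic expected spectrum
#' ([expected_sfs_analytic_1pop()]), with epoch boundaries supplied as a
#' schedule in generations.  Uncertainty bands come from a SNP-resampling
#' bootstrap (multinomial resampling of the observed spectrum), refitting
#' each replicate and taking 2.5/97.5 percentiles.
#'
#' @param obs observed 1-D `folded_sfs` (or a plain numeric vector of
#'   folded class counts `1..floor(n/2)` together with `n`).
#' @param epoch_times size-change times in generations (increasing);
#'   `length(epoch_times) + 1` epochs are fitted.
#' @param n haploid sample size (taken from `obs` when it is a
#'   `folded_sfs`).
#' @param B bootstrap replicates (0 = point trajectory only).
#' @param mu mutation rate per site per generation.
#' @param total_sites total number of sequenced positions (polymorphic and
#'   not) behind the SFS.  When supplied, the fit maximizes the absolute
#'   Poisson likelihood of the class counts with expectation
#'   `mu * total_sites * eta_i`, which anchors the overall population-size
#'   scale -- a constant-size history has an N-independent *shape*, so
#'   shape-only fits cannot identify absolute size.  When `NULL`, only the
#'   normalized shape is fitted and sizes are identified solely through
#'   the epoch schedule's absolute times (adequate for trajectory shapes,
#'   not for absolute levels).
#' @param generation_time years per generation for the time axis.
#' @param seed integer seed.
#' @return a `ne_trajectory`: data.frame with epoch start times
#'   (generations and years) and haploid N_e point estimates plus
#'   percentile bands when `B > 0`.
#' @export
fit_stairway <- function(obs, epoch_times, n = NULL, B = 0,
                         mu = 4.83e-9, total_sites = NULL,
                         generation_time = 4, seed = NULL) {
  if (inherits(obs, "folded_sfs")) {
    stopifnot(obs$dims == 1L)
    n <- obs$sample_sizes
    eta_obs <- obs$counts[!obs$mask]
  } else {
    stopifnot(!is.null(n))
    eta_obs <- as.numeric(obs)
  }
  stopifnot(n >= 4, length(eta_obs) == floor(n / 2))
  if (sum(eta_obs) < 50) {
    stop("need at least 50 polymorphic SNPs for a stairway-style fit")
  }
  n_epochs <- length(epoch_times) + 1L
  if (n_epochs > length(eta_obs)) {
    stop("more epochs (", n_epochs, ") than folded SFS classes (",
         length(eta_obs), "): the schedule is underdetermined")
  }
  if (!is.null(seed)) set.seed(seed)

  fit_once <- function(eta) {
    nll <- function(logN) {
      lam <- expected_sfs_analytic_1pop(exp(logN), epoch_times, n)
      if (is.null(total_sites)) {
        p <- lam / sum(lam)
        -sum(eta * log(p))
      } else {
        ex <- mu * total_sites * lam
        sum(ex) - sum(eta * log(ex))
      }
    }
    start <- if (is.null(total_sites)) {
      rep(log(1e4), n_epochs)
    } else {
      # Watterson anchor: S = mu * sites * 2N * a1
      N0 <- sum(eta) / (mu * total_sites * 2 * sum(1 / (1:(n - 1))))
      rep(log(max(N0, 100)), n_epochs)
    }
    opt <- optim(start, nll, method = "L-BFGS-B", lower = log(10),
                 upper = log(1e9), control = list(maxit = 500))
    exp(opt$par)
  }

  point <- fit_once(eta_obs)
  tab <- data.frame(epoch = seq_len(n_epochs),
                    t_start_gen = c(0, epoch_times),
                    t_start_years = generations_to_years(
                      c(0, epoch_times), generation_time),
                    Ne_hap = point)
  if (B > 0) {
    S <- round(sum(eta_obs))
    bs <- matrix(NA_real_, B, n_epochs)
    for (bb in seq_len(B)) {
      eta_b <- as.numeric(rmultinom(1, S, eta_obs / sum(eta_obs)))
      bs[bb, ] <- fit_once(eta_b)
    }
    tab$Ne_lower <- apply(bs, 2, quantile, 0.025)
    tab$Ne_median <- apply(bs, 2, quantile, 0.5)
    tab$Ne_upper <- apply(bs, 2, quantile, 0.975)
  }
  structure(tab, class = c("ne_trajectory", "data.frame"),
            n = n, B = B, mu = mu, generation_time = generation_time)
}
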