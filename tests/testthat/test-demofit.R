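make_sfs <- function(counts, n) {
  mask <- tealdemog:::folded_mask(n)
  cm <- if (length(n) == 2L) matrix(0, n[1] + 1, n[2] + 1) else
    numeric(n + 1)
  cm[!mask] <- counts
  tealdemog:::new_folded_sfs(cm, n, mask)
}

test_that("composite log-likelihood matches hand computations and is
           maximized at the empirical proportions", {
  obs <- make_sfs(c(5, 0, 0), 6L)   # all mass in the first folded class
  p1 <- make_sfs(c(1, 1e-12, 1e-12), 6L)
  expect_equal(composite_loglik(obs, p1), 5 * log(1), tolerance = 1e-9)

  obs2 <- make_sfs(c(3, 1, 0), 6L)
  p2 <- make_sfs(c(0.75, 0.25, 1e-12), 6L)
  expect_equal(composite_loglik(obs2, p2), 3 * log(0.75) + log(0.25))

  # perturbing probabilities away from obs/sum(obs) never helps
  base <- c(3, 1, 2) / 6
  ll0 <- composite_loglik(make_sfs(c(3, 1, 2), 6L), make_sfs(base, 6L))
  set.seed(1)
  for (i in 1:50) {
    e <- runif(3); e <- e / sum(e)
    q <- 0.8 * base + 0.2 * e
    expect_lte(composite_loglik(make_sfs(c(3, 1, 2), 6L),
                                make_sfs(q / sum(q), 6L)), ll0 + 1e-12)
  }

  expect_error(composite_loglik(obs, make_sfs(c(.5, .3, .2, 0), 8L)),
               "different shapes")
})

test_that("AIC arithmetic and the selection table behave", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-10, 2), 24)
  tab <- model_selection(data.frame(model = c("X", "Y"),
                                    lnL = c(-100, -100), k = c(2, 2)))
  expect_equal(tab$weight, c(0.5, 0.5))
  one <- model_selection(data.frame(model = "X", lnL = -5, k = 1))
  expect_equal(one$dAIC, 0)
  expect_equal(one$weight, 1)
  expect_error(model_selection(data.frame(model = c("X", "X"),
                                          lnL = c(-1, -2), k = c(1, 1))),
               "duplicate")
  # weight ordering is inverse to dAIC ordering and weights sum to one
  set.seed(3)
  tab2 <- model_selection(data.frame(model = letters[1:5],
                                     lnL = -runif(5, 50, 60),
                                     k = sample(2:6)))
  expect_equal(sum(tab2$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab2$dAIC) >= 0))
  expect_true(all(diff(tab2$weight) <= 1e-12))
})

test_that("unit conversions invert the published scalings", {
  expect_equal(theta_from_pi(4.70e-4, 4.83e-9), 48654, tolerance = 1e-4)
  expect_equal(theta_from_pi(0, 1e-8), 0)
  expect_equal(theta_from_pi(1e-3, 2e-8), theta_from_pi(1e-3, 1e-8) / 2)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(100, 5), 500)
})

test_that("the model family has the documented parameter counts", {
  fam <- model_family()
  expect_identical(fam$k,
                   vapply(fam$model, function(id)
                     length(model_params(id)), 0L),
                   ignore_attr = TRUE)
  expect_identical(unname(fam$k), c(3L, 4L, 5L, 5L, 6L, 7L, 7L, 8L, 9L))
  # ordering constraints are enforced
  expect_error(build_model("B1", c(theta_ANC = 100, theta_ES = 100,
                                   T_DIV = 50, theta_BOT1 = 10,
                                   T_BOT1 = 40), 100),
               "increasing")
})

test_that("analytic single-population SFS reduces to the neutral shape and
           reacts to expansions", {
  xi <- expected_sfs_analytic_1pop(1000, n = 4, fold = FALSE)
  expect_equal(xi / xi[1], c(1, 1 / 2, 1 / 3), tolerance = 1e-10)

  # folded constant-size shape: (1/i + 1/(n-i)) with half-weight center
  n <- 8
  eta <- expected_sfs_analytic_1pop(500, n = n)
  shape <- sapply(1:4, function(i)
    if (i == n - i) 1 / i else 1 / i + 1 / (n - i))
  expect_equal(eta / eta[1], shape / shape[1], tolerance = 1e-10)

  # recent 10x expansion inflates singletons relative to constant size
  ex <- expected_sfs_analytic_1pop(c(5000, 500), times = 200, n = 10)
  ct <- expected_sfs_analytic_1pop(500, n = 10)
  expect_gt((ex[1] / sum(ex)) / (ct[1] / sum(ct)), 1)
})

test_that("analytic and Monte-Carlo expected spectra agree for a
           three-epoch history", {
  sizes <- c(800, 3000, 400); times <- c(300, 1500)
  eta <- expected_sfs_analytic_1pop(sizes, times, n = 10)
  p_an <- eta / sum(eta)
  m <- demographic_model(c(P = 800), anc_sizes = sizes, anc_times = times)
  pm <- expected_sfs_mc(m, 10, n_trees = 60000, seed = 21)
  p_mc <- pm$counts[!pm$mask]
  # binomial-scale Monte-Carlo error bound per cell
  se <- sqrt(p_an * (1 - p_an) / 60000) * 3 + 0.004
  expect_true(all(abs(p_mc - p_an) < 3 * se))
})

test_that("the degenerate-epoch guard collapses zero-duration epochs", {
  expect_warning(out <- expected_sfs_analytic_1pop(c(500, 900), times = 0,
                                                   n = 6),
                 "zero-duration")
  expect_equal(out, expected_sfs_analytic_1pop(900, n = 6),
               tolerance = 1e-9)
})

test_that("SI spectra concentrate on private alleles at large divergence
           and symmetric models are deme-exchangeable", {
  deep <- demographic_model(c(A = 500, B = 500), T_div = 50000,
                            migration = 0, anc_sizes = 500)
  p <- expected_sfs_mc(deep, c(6, 6), n_trees = 20000, seed = 5)
  shared <- sum(p$counts[2:6, 2:6])  # both demes polymorphic
  expect_lt(shared / sum(p$counts[!p$mask]), 0.02)

  sym <- demographic_model(c(A = 1000, B = 1000), T_div = 1000,
                           migration = 1e-4, anc_sizes = 1000)
  ps <- expected_sfs_mc(sym, c(8, 8), n_trees = 40000, seed = 6)
  m1 <- ps$counts; m2 <- t(ps$counts)
  keep <- !ps$mask & !t(ps$mask)
  expect_lt(max(abs(m1[keep] - m2[keep])), 0.015)
})

test_that("nested models never lose likelihood at matched evaluation
           precision", {
  truth <- c(theta_ANC = 800, theta_ES = 2000, T_DIV = 300, m_S = 5e-5)
  mod <- build_model("A2", truth, theta_IQ = 4000)
  probs <- expected_sfs_mc(mod, c(8, 4), n_trees = 30000, seed = 31)
  set.seed(32)
  obs <- draw_sfs(probs, 4000)
  f1 <- fit_model(obs, "A1", theta_IQ = 4000, n_replicates = 2,
                  n_trees = 2500, n_trees_final = 8000,
                  n_trees_profile = 15000, maxit = 80, seed = 1)
  f2 <- fit_model(obs, "A2", theta_IQ = 4000, n_replicates = 2,
                  n_trees = 2500, n_trees_final = 8000,
                  n_trees_profile = 15000, maxit = 80, seed = 1)
  expect_s3_class(f1, "fit_result")
  # A1 is A2 with m = 0: its maximized lnL cannot exceed A2's by more
  # than optimizer/Monte-Carlo tolerance
  expect_lt(f1$lnL - f2$lnL, 15)
})

test_that("parametric bootstrap returns ordered percentile intervals", {
  truth <- c(theta_ANC = 800, theta_ES = 2000, T_DIV = 300, m_S = 5e-5)
  mod <- build_model("A2", truth, theta_IQ = 4000)
  probs <- expected_sfs_mc(mod, c(8, 4), n_trees = 20000, seed = 41)
  set.seed(42)
  obs <- draw_sfs(probs, 3000)
  fit <- fit_model(obs, "A2", theta_IQ = 4000, n_replicates = 2,
                   n_trees = 2500, n_trees_final = 6000,
                   n_trees_profile = 10000, maxit = 60, seed = 2)
  ci <- parametric_bootstrap(fit, n_snps = 3000, B = 2, n_replicates = 1,
                             n_trees = 2000, n_trees_final = 4000,
                             n_trees_profile = 6000, maxit = 40, seed = 3)
  expect_identical(ci$param, names(fit$mle))
  expect_true(all(ci$lower <= ci$upper + 1e-9))
  expect_identical(attr(ci, "B"), 2)
})

test_that("stairway fits run, reject underdetermined schedules, and
           recover a constant size from an absolutely anchored SFS", {
  n <- 16; mu <- 4.83e-9; sites <- 1.6e8  # ~1e5 SNPs at N = 20000
  eta <- expected_sfs_analytic_1pop(20000, n = n)
  lam <- mu * sites * eta
  set.seed(51)
  obs_counts <- rpois(length(lam), lam)
  expect_error(fit_stairway(obs_counts, epoch_times = 1:10, n = n),
               "underdetermined")
  # per-epoch medians over independent datasets stay within 50% of truth
  devs <- sapply(1:5, function(s) {
    set.seed(60 + s)
    oc <- rpois(length(lam), lam)
    tr <- fit_stairway(oc, epoch_times = c(2000, 15000), n = n, B = 0,
                       mu = mu, total_sites = sites)
    tr$Ne_hap
  })
  expect_true(all(abs(apply(devs, 1, median) - 20000) / 20000 < 0.5))

  tr <- fit_stairway(obs_counts, epoch_times = c(2000, 15000), n = n,
                     B = 0, mu = mu, total_sites = sites)
  expect_s3_class(tr, "ne_trajectory")
  expect_false("Ne_median" %in% names(tr))  # B = 0: no bands

  trb <- fit_stairway(obs_counts, epoch_times = c(2000, 15000), n = n,
                      B = 8, mu = mu, total_sites = sites, seed = 6)
  expect_true(all(trb$Ne_lower <= trb$Ne_median + 1e-9 &
                    trb$Ne_median <= trb$Ne_upper + 1e-9))
})
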