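test_that("total branch length and segregating sites match coalescent
           expectations for a constant-size deme", {
  N <- 1000; n <- 10; reps <- 2000
  m <- demographic_model(c(POP = N), anc_sizes = N)
  trees <- simulate_genealogies(m, n, n_loci = reps, seed = 42)
  tl <- vapply(trees, `[[`, 0, "total_length")
  expect_true(all(vapply(trees, function(t) sum(is.na(t$parent)), 0L) == 1))
  exp_len <- 2 * N * sum(1 / (1:(n - 1)))
  se <- sd(tl) / sqrt(reps)
  expect_lt(abs(mean(tl) - exp_len), 3 * se)

  # Watterson's E[S] on the same genealogies
  mu <- 1e-6; len <- 100
  S <- vapply(drop_mutations(trees, mu, len), ncol, 0L)
  theta_w <- 2 * N * mu * len
  exp_S <- theta_w * sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(S) - exp_S), 3 * sd(S) / sqrt(reps))
})

test_that("a zero-divergence split with no migration reduces to a single
           pooled deme", {
  N <- 800; reps <- 1200
  split0 <- demographic_model(c(A = 10, B = 10), T_div = 0, migration = 0,
                              anc_sizes = N)
  single <- demographic_model(c(P = N), anc_sizes = N)
  h1 <- vapply(simulate_genealogies(split0, c(4, 4), reps, seed = 1),
               `[[`, 0, "height")
  h2 <- vapply(simulate_genealogies(single, 8, reps, seed = 2),
               `[[`, 0, "height")
  expect_gt(suppressWarnings(stats::ks.test(h1, h2))$p.value, 0.01)
})

test_that("without migration, lineages from the two demes only coalesce
           behind the split", {
  m <- demographic_model(c(ES = 16388, IQ = 48654), T_div = 407,
                         migration = 0, anc_sizes = 3225)
  trees <- simulate_genealogies(m, c(12, 6), n_loci = 200, seed = 7)
  expect_true(all(vapply(trees, `[[`, 0, "height") > 407))
})

test_that("mutation overlay respects the infinite-sites contract", {
  m <- demographic_model(c(P = 500), anc_sizes = 500)
  trees <- simulate_genealogies(m, 6, n_loci = 50, seed = 3)
  expect_true(all(vapply(drop_mutations(trees, 0, 100), ncol, 0L) == 0))
  mats <- drop_mutations(trees, 1e-4, 100)
  counts <- unlist(lapply(mats, colSums))
  expect_true(all(counts >= 1 & counts <= 5))  # never 0 or n carriers

  # a hand-built two-leaf genealogy: every mutation is a singleton
  toy <- structure(list(parent = c(3L, 3L, NA), node_time = c(0, 0, 50),
                        leaf_deme = c(1L, 1L), n_leaves = 2L,
                        total_length = 100, height = 50),
                   class = "genealogy")
  set.seed(9)
  cols <- drop_mutations(list(toy), 1e-2, 100)[[1]]
  expect_gt(ncol(cols), 0)
  expect_true(all(colSums(cols) == 1))
})

test_that("tree heights agree with an independent coalescent simulator", {
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  py <- '
import msprime, sys
mode = sys.argv[1]
out = []
if mode == "const":
    for s in range(400):
        ts = msprime.sim_ancestry(samples=8, ploidy=1,
                                  population_size=1000, random_seed=s + 1)
        out.append(ts.max_root_time)
elif mode == "im":
    dem = msprime.Demography()
    dem.add_population(name="A", initial_size=16388)
    dem.add_population(name="B", initial_size=48654)
    dem.add_population(name="C", initial_size=3225)
    dem.set_migration_rate("A", "B", 1e-4)
    dem.set_migration_rate("B", "A", 1e-4)
    dem.add_population_split(time=407, derived=["A", "B"], ancestral="C")
    for s in range(400):
        ts = msprime.sim_ancestry(samples={"A": 6, "B": 3}, ploidy=1,
                                  demography=dem, random_seed=s + 1)
        out.append(ts.max_root_time)
else:
    dem = msprime.Demography()
    dem.add_population(name="A", initial_size=4000)
    dem.add_population_parameters_change(time=800, initial_size=500,
                                         population="A")
    for s in range(400):
        ts = msprime.sim_ancestry(samples=10, ploidy=1, demography=dem,
                                  random_seed=s + 1)
        out.append(ts.max_root_time)
print("\\n".join(str(x) for x in out))
'
  run_oracle <- function(mode) {
    as.numeric(system2("python", c("-c", shQuote(py), mode),
                       stdout = TRUE))
  }
  # with ploidy = 1 the oracle's population_size is a haploid size (pair
  # coalescence rate 1/N), the same convention as demographic_model()
  cases <- list(
    const = list(model = demographic_model(c(P = 1000), anc_sizes = 1000),
                 samples = 8),
    im = list(model = demographic_model(c(A = 16388, B = 48654),
                                        T_div = 407, migration = 1e-4,
                                        anc_sizes = 3225),
              samples = c(6, 3)),
    bott = list(model = demographic_model(c(P = 4000),
                                          anc_sizes = c(4000, 500),
                                          anc_times = 800),
                samples = 10))
  for (mode in names(cases)) {
    ora <- run_oracle(mode)
    skip_if(anyNA(ora) || length(ora) != 400, "oracle run failed")
    mine <- vapply(simulate_genealogies(cases[[mode]]$model,
                                        cases[[mode]]$samples,
                                        n_loci = 400, seed = 11),
                   `[[`, 0, "height")
    expect_gt(suppressWarnings(stats::ks.test(mine, ora))$p.value, 0.01,
              label = paste("KS p for", mode))
  }
})

test_that("simulate_dataset honours missingness, pairing, grouping and the
           fixed seed", {
  m <- demographic_model(c(ES = 2000, IQ = 1000), T_div = 500,
                         migration = 0, anc_sizes = 800)
  cfg <- sim_config(mu = 2e-7, n_loci = 300, locus_length = 200,
                    missing_rate = 0, samples = c(ES = 6, IQ = 4))
  G1 <- simulate_dataset(m, cfg, seed = 5)
  expect_false(anyNA(G1$calls))
  expect_identical(sort(unique(G1$pops)), c("ES", "IQ"))
  expect_length(G1$locus_ids, ncol(G1$calls))
  G2 <- simulate_dataset(m, cfg, seed = 5)
  expect_identical(G1$calls, G2$calls)  # bit-identical under a fixed seed

  cfg2 <- sim_config(mu = 2e-7, n_loci = 300, locus_length = 200,
                     missing_rate = 0.3, samples = c(ES = 6, IQ = 4))
  G3 <- simulate_dataset(m, cfg2, seed = 5)
  miss <- mean(is.na(G3$calls))
  expect_gt(miss, 0.2); expect_lt(miss, 0.4)
})

test_that("pedigree offspring are Mendelian-consistent with their parents", {
  m <- demographic_model(c(P = 3000), anc_sizes = 3000)
  cfg <- sim_config(mu = 2e-7, n_loci = 400, locus_length = 200,
                    missing_rate = 0, samples = c(P = 6))
  ped <- pedigree_spec(data.frame(id = "kid1", parent1 = "P_01",
                                  parent2 = "P_02"))
  G <- simulate_dataset(m, cfg, pedigree = ped, seed = 8)
  kid <- G$calls["kid1", ]
  for (par in c("P_01", "P_02")) {
    p <- G$calls[par, ]
    ok <- !is.na(kid) & !is.na(p)
    # sharing at least one allele excludes opposite homozygotes
    expect_true(all(!(kid[ok] == 0 & p[ok] == 2) &
                      !(kid[ok] == 2 & p[ok] == 0)))
  }
  bad <- pedigree_spec(data.frame(id = "x", parent1 = "nope",
                                  parent2 = "P_01"))
  expect_error(simulate_dataset(m, cfg, pedigree = bad, seed = 8),
               "unknown parent")
})

test_that("strong ancient divergence leaves a clear nuclear F_ST signal", {
  m <- demographic_model(c(A = 2000, B = 2000), T_div = 8000,
                         migration = 0, anc_sizes = 2000)
  cfg <- sim_config(mu = 2e-7, n_loci = 400, locus_length = 200,
                    missing_rate = 0, samples = c(A = 8, B = 8))
  fsts <- vapply(1:5, function(s) {
    G <- simulate_dataset(m, cfg, seed = s)
    fst_wc(G, c("A", "B"), n_permutations = 0)$fst
  }, 0)
  expect_gt(mean(fsts), 0.2)
})

test_that("mtDNA simulation produces one haplotype at mu = 0 and matches
           pairwise-diversity expectations at small theta", {
  m <- demographic_model(c(P = 2000), anc_sizes = 2000)
  cfg <- sim_config(samples = c(P = 8))
  aln0 <- simulate_mtdna(m, cfg, seq_length = 120, mu_mt = 0, seed = 2)
  expect_length(unique(aln0$sequences), 1L)

  # E[pairwise differences per site] ~ 2 N_mt mu for a sample of two
  cfg2 <- sim_config(samples = c(P = 2))
  pis <- vapply(1:400, function(s) {
    aln <- simulate_mtdna(m, cfg2, seq_length = 150, mu_mt = 2e-6,
                          mt_ne_factor = 0.5, seed = s)
    nuc_diversity(aln)
  }, 0)
  expected <- 2 * (2000 * 0.5) * 2e-6
  expect_lt(abs(mean(pis) - expected), 3 * sd(pis) / sqrt(length(pis)))
})

test_that("long isolation yields deme-private mtDNA haplotypes in most
           replicates", {
  m <- demographic_model(c(A = 1000, B = 1000), T_div = 60000,
                         migration = 0, anc_sizes = 1000)
  cfg <- sim_config(samples = c(A = 6, B = 6))
  shared <- vapply(1:20, function(s) {
    aln <- simulate_mtdna(m, cfg, seq_length = 300, mu_mt = 1e-6, seed = s)
    haps <- collapse_haplotypes(aln)
    sum(rowSums(haps$counts > 0) == 2)
  }, 0)
  expect_gte(mean(shared == 0), 0.9)
})
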