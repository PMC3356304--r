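test_that("null samples follow the per-nucleotide model: E[N] = sum(m_i)", {
  u <- split_universe(40, 10, short = 5000, mu = 5e-6)
  # redraws enforce N >= 1, so the target is E[N | N >= 1] = sum(m) / (1 - P0)
  p0 <- prod(1 - u$mutation_rates)
  expected_N <- sum(u$mutation_rates) / (1 - p0)
  set.seed(22)
  Ns <- replicate(4000, simulate_null_sample(u)$N)
  sd_N <- sqrt(sum(u$mutation_rates * (1 - u$mutation_rates)))
  expect_lt(abs(mean(Ns) - expected_N), 3 * sd_N / sqrt(4000))
})

test_that("a 10x longer gene mutates ~10x as often in the small-rate limit", {
  u <- split_universe(1, 1, short = 1000, mu = 1e-6)  # 1 kb vs 10 kb
  ratio <- u$mutation_rates[2] / u$mutation_rates[1]
  expect_equal(ratio, 10, tolerance = 0.01)  # mu*l << 1
  set.seed(9)
  hits <- matrix(runif(2 * 5e4) < rep(u$mutation_rates, 5e4), nrow = 2)
  emp_ratio <- sum(hits[2, ]) / sum(hits[1, ])
  expect_equal(emp_ratio, 10, tolerance = 0.35)
})

test_that("simulation requires a positive mutation rate", {
  u <- gene_universe(c("a", "b"), c(100, 200))  # no mu
  expect_error(simulate_null_sample(u), "no positive mutation rates")
  expect_error(set_mu(u, 0), "> 0")
})

test_that("per-nucleotide and per-gene simulation modes agree in distribution", {
  u <- split_universe(30, 10, short = 4000, mu = 1e-5)
  set.seed(31)
  N_gene <- replicate(1500, simulate_null_sample(u)$N)
  N_nt <- replicate(1500, simulate_null_sample(u, per_nucleotide = TRUE)$N)
  se <- sqrt(var(N_gene) / 1500 + var(N_nt) / 1500)
  expect_lt(abs(mean(N_gene) - mean(N_nt)), 4 * se)
})

test_that("a unit multiplier reduces to the null cohort", {
  u <- split_universe(20, 5)
  boost <- setNames(rep(1, 5), u$gene_ids[1:5])
  set.seed(12); a <- simulate_null_sample(u)
  set.seed(12); b <- simulate_null_sample(u, boost = boost)
  expect_identical(a$mut_genes, b$mut_genes)
})

test_that("an infeasible multiplier errors", {
  u <- split_universe(5, 5, short = 50000, mu = 5e-5)  # long genes m ~ 0.9
  boost <- setNames(rep(25, 2), u$gene_ids[9:10])
  expect_error(simulate_null_sample(u, boost = boost), ">= 1")
})

test_that("simulate_cohort is deterministic under seed and varies across seeds", {
  cfg <- simulation_config(n_genes = 120, n_samples = 4, seed = 5,
                           n_random_pathways = 3, random_pathway_size = 10,
                           mu = 2e-5)
  a <- suppressMessages(simulate_cohort(cfg))
  b <- suppressMessages(simulate_cohort(cfg))
  expect_identical(lapply(a$samples, `[[`, "mut_genes"),
                   lapply(b$samples, `[[`, "mut_genes"))
  cfg2 <- simulation_config(n_genes = 120, n_samples = 4, seed = 6,
                            n_random_pathways = 3, random_pathway_size = 10,
                            mu = 2e-5)
  c2 <- suppressMessages(simulate_cohort(cfg2))
  expect_false(identical(lapply(a$samples, `[[`, "mut_genes"),
                         lapply(c2$samples, `[[`, "mut_genes")))
})

test_that("written cohort files round-trip through the readers", {
  dir <- tempfile()
  cfg <- simulation_config(
    n_genes = 200, n_samples = 6, seed = 41, mu = 5e-6,
    drivers = list(list(id = "drvA", n_genes = 12, multiplier = 5)),
    decoy = list(id = "decoy", n_genes = 12),
    n_random_pathways = 4, random_pathway_size = 15
  )
  sim <- suppressMessages(simulate_cohort(cfg, out_dir = dir))
  expect_true(all(file.exists(unlist(sim$files))))

  u2 <- read_gene_lengths(sim$files$lengths)
  expect_equal(u2$gene_ids, sim$universe$gene_ids)
  expect_equal(u2$lengths, sim$universe$lengths)

  pc2 <- suppressMessages(read_gmt(sim$files$gmt, u2, min_size = 1,
                                   max_size = 500))
  expect_equal(pc2$sets[order(names(pc2$sets))],
               sim$pathways$sets[order(names(sim$pathways$sets))])

  sm2 <- suppressMessages(read_mutations(sim$files$mutations, u2,
                                         min_mut_genes = 1))
  got <- lapply(sm2, function(s) sort(s$mut_genes))
  want <- lapply(sim$samples, function(s) sort(s$mut_genes))
  expect_equal(got[order(names(got))], want[order(names(want))])

  prov <- yaml::read_yaml(sim$files$provenance)
  expect_equal(prov$seed, 41)
  expect_equal(prov$n_samples, 6)
})

test_that("driver boosts raise driver-gene mutation frequency; decoy stays at background", {
  cfg <- simulation_config(
    n_genes = 300, n_samples = 40, seed = 19, mu = 4e-6,
    drivers = list(list(id = "drv", n_genes = 15, multiplier = 10)),
    decoy = list(id = "decoy", n_genes = 15),
    n_random_pathways = 2, random_pathway_size = 10
  )
  sim <- suppressMessages(simulate_cohort(cfg))
  drv <- sim$truth$drivers$drv$members
  dec <- sim$truth$decoy$members
  m <- setNames(sim$universe$mutation_rates, sim$universe$gene_ids)
  hit_rate <- function(genes) {
    mean(vapply(sim$samples,
                function(s) mean(genes %in% s$mut_genes), 0))
  }
  # drivers mutate well above their baseline rates; decoy stays near its own
  expect_gt(hit_rate(drv), 5 * mean(m[drv]))
  expect_lt(abs(hit_rate(dec) - mean(m[dec])), 4 * sd(m[dec]) / sqrt(15) + 0.05)
})
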