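test_that("jaccard handles the canonical cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(j <- jaccard(character(0), character(0)), "empty")
  expect_equal(j, 0)
})

test_that("crosstalk requires at least two significant pathways", {
  u <- toy_universe(n = 10)
  pc <- pathway_collection(list(a = u$gene_ids[1:5]),
                           universe = u, min_size = 1, max_size = 500)
  sm <- sample_mutations("s", u$gene_ids[1:3], u)
  expect_message(
    res <- crosstalk_sample(sm, "a", u, pc, resample_plan(100, 1)),
    "fewer than 2"
  )
  expect_equal(nrow(res), 0L)
})

test_that("degenerate pairs give p_emp = 1", {
  u <- toy_universe(n = 10)
  sm <- sample_mutations("s", u$gene_ids[c(1, 6)], u)
  # disjoint mutated members: jc_obs = 0, every resample JC >= 0
  pc <- pathway_collection(list(a = u$gene_ids[1:5], b = u$gene_ids[6:10]),
                           universe = u, min_size = 1, max_size = 500)
  res <- crosstalk_sample(sm, c("a", "b"), u, pc, resample_plan(300, 2))
  expect_equal(res$jc, 0)
  expect_equal(res$p_emp, 1)
  expect_equal(res$n_shared_mut_genes, 0L)

  # identical pathways covering the universe: JC = 1 in every resample
  pc2 <- pathway_collection(list(x = u$gene_ids, y = u$gene_ids),
                            universe = u, min_size = 1, max_size = 500)
  res2 <- crosstalk_sample(sm, c("x", "y"), u, pc2, resample_plan(300, 2))
  expect_equal(res2$jc, 1)
  expect_equal(res2$p_emp, 1)
})

test_that("crosstalk is symmetric in the pathway pair", {
  u <- split_universe(10, 10)
  pc <- pathway_collection(list(a = u$gene_ids[1:8], b = u$gene_ids[5:14]),
                           universe = u, min_size = 1, max_size = 500)
  sm <- sample_mutations("s", u$gene_ids[c(1, 5, 6, 11)], u)
  r1 <- crosstalk_sample(sm, c("a", "b"), u, pc, resample_plan(500, 3))
  r2 <- crosstalk_sample(sm, c("b", "a"), u, pc, resample_plan(500, 3))
  expect_equal(r1$jc, r2$jc)
  expect_equal(r1$p_emp, r2$p_emp)
  expect_equal(r1$n_shared_mut_genes, r2$n_shared_mut_genes)
})

test_that("p_emp is monotone non-increasing in jc_observed for a fixed null", {
  # same pathway pair, same sample id and N (hence identical null draws);
  # only the observed MutGene sets differ
  u <- toy_universe(n = 12)
  pc <- pathway_collection(list(a = u$gene_ids[1:6], b = u$gene_ids[4:9]),
                           universe = u, min_size = 1, max_size = 500)
  plan <- resample_plan(400, 6)
  jc_of <- function(genes) {
    sm <- sample_mutations("s", genes, u)
    crosstalk_sample(sm, c("a", "b"), u, pc, plan)
  }
  r0 <- jc_of(u$gene_ids[c(1, 7, 10, 11)])   # jc = 0
  r1 <- jc_of(u$gene_ids[c(1, 4, 10, 11)])   # jc = 1/2
  r2 <- jc_of(u$gene_ids[c(4, 5, 10, 11)])   # jc = 1
  expect_equal(c(r0$jc, r1$jc, r2$jc), c(0, 0.5, 1))
  expect_equal(r0$p_emp, 1)
  expect_lte(r1$p_emp, r0$p_emp)
  expect_lte(r2$p_emp, r1$p_emp)
})

test_that("crosstalk p_emp matches exhaustive enumeration on a 6-gene universe", {
  m <- c(0.02, 0.04, 0.06, 0.1, 0.15, 0.3)
  u <- gene_universe(letters[1:6], rep(1, 6))
  u$mu <- 1; u$mutation_rates <- m
  A <- letters[1:4]; B <- letters[3:6]
  sm <- sample_mutations("s", c("a", "c", "d"), u)
  mutA <- intersect(sm$mut_genes, A); mutB <- intersect(sm$mut_genes, B)
  jc_obs <- jaccard(mutA, mutB)

  # oracle: exact probability that a weighted draw D of size N gives
  # JC(D∩A, D∩B) >= jc_obs, enumerating all subsets with their exact
  # selection probabilities
  probs <- ss_set_probs(m, sm$N)
  q <- 0
  for (key in names(probs)) {
    D <- letters[as.integer(strsplit(key, ",")[[1]])]
    nb <- length(intersect(D, intersect(A, B)))
    ne <- length(intersect(D, union(A, B)))
    jc <- if (ne == 0) 0 else nb / ne
    if (jc >= jc_obs) q <- q + probs[[key]]
  }

  pc <- pathway_collection(list(A = A, B = B), universe = u,
                           min_size = 1, max_size = 500)
  Bres <- 4e4
  res <- crosstalk_sample(sm, c("A", "B"), u, pc, resample_plan(Bres, 31))
  tol <- 3 * sqrt(q * (1 - q) / Bres) + 2 / Bres
  expect_lt(abs(res$p_emp - q), tol)
})

test_that("hot shared MutGenes make the significant edge set a clique", {
  # three pathways sharing one mutated hub gene; fillers disjoint
  u <- toy_universe(n = 60)
  hub <- "g01"
  pc <- pathway_collection(
    list(p1 = c(hub, u$gene_ids[10:17]),
         p2 = c(hub, u$gene_ids[20:27]),
         p3 = c(hub, u$gene_ids[30:37])),
    universe = u, min_size = 1, max_size = 500
  )
  sm <- sample_mutations("s", c(hub, u$gene_ids[40:42]), u)
  res <- crosstalk_sample(sm, c("p1", "p2", "p3"), u, pc,
                          resample_plan(2000, 12))
  expect_equal(nrow(res), 3L)
  expect_true(all(res$jc == 1))          # each pair shares exactly the hub
  expect_true(all(res$significant))     # clique among all three pathways
})

test_that("full-membership JC mode reports the static coefficient", {
  u <- toy_universe(n = 10)
  pc <- pathway_collection(list(a = u$gene_ids[1:6], b = u$gene_ids[4:9]),
                           universe = u, min_size = 1, max_size = 500)
  sm <- sample_mutations("s", u$gene_ids[1:2], u)
  res <- crosstalk_sample(sm, c("a", "b"), u, pc, resample_plan(10, 1),
                          jc_on = "full")
  expect_equal(res$jc, 3 / 9)
  expect_true(is.na(res$p_emp))
})
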