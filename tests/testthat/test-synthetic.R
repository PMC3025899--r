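test_that("the island-model generator is seed-reproducible", {
  p <- simParams(n_demes = 2, sample_sizes = 8, seed = 91)
  a <- simulateIslandCoalescent(p)
  b <- simulateIslandCoalescent(p)
  expect_identical(as.character(a$alignment@seqs),
                   as.character(b$alignment@seqs))
  expect_identical(a$map@sites, b$map@sites)
  c3 <- simulateIslandCoalescent(simParams(n_demes = 2, sample_sizes = 8,
                                           seed = 92))
  expect_false(identical(as.character(a$alignment@seqs),
                         as.character(c3$alignment@seqs)))
})

test_that("very high migration removes population structure", {
  f <- vapply(1:25, function(i) {
    s <- simulateIslandCoalescent(simParams(n_demes = 2, sample_sizes = 10,
                                            Nm = 200, seed = 1000 + i))
    out <- fstNmMatrices(s$alignment, s$map)$fst[1, 2]
    if (is.na(out)) 0 else out
  }, numeric(1))
  expect_lt(mean(f), 0.05)
})

test_that("simulated base composition converges to the configured frequencies", {
  p <- simParams(n_demes = 1, sample_sizes = 2, theta = 0.002, L = 20000,
                 seed = 93)
  s <- simulateIslandCoalescent(p)
  ch <- strsplit(as.character(s$alignment@seqs[[1]]), "")[[1]]
  freq <- table(factor(ch, levels = c("A", "C", "G", "T"))) / length(ch)
  gof <- stats::chisq.test(table(factor(ch, levels = c("A", "C", "G", "T"))),
                           p = p$base_composition)
  expect_gt(gof$p.value, 1e-4)
  expect_equal(as.numeric(freq), unname(p$base_composition), tolerance = 0.1)
})

test_that("constant-size coalescent trees have the right waiting times", {
  # two tips: a single Exp(1/N) interval with mean N
  dur <- vapply(1:1000, function(i) {
    tr <- simulateConstantCoalescentTree(2, 100, seed = 2000 + i)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expect_lt(abs(mean(dur) - 100) / 100, 0.1)

  # height grows stochastically with N
  h1 <- vapply(1:40, function(i)
    max(ape::node.depth.edgelength(
      simulateConstantCoalescentTree(10, 100, seed = 3000 + i))), numeric(1))
  h2 <- vapply(1:40, function(i)
    max(ape::node.depth.edgelength(
      simulateConstantCoalescentTree(10, 1000, seed = 4000 + i))), numeric(1))
  expect_lt(stats::wilcox.test(h1, h2, alternative = "less")$p.value, 0.01)

  expect_identical(ape::write.tree(simulateConstantCoalescentTree(6, 50, 7)),
                   ape::write.tree(simulateConstantCoalescentTree(6, 50, 7)))
})

test_that("scenarios produce their defining genetic signatures", {
  expect_error(makeScenario("no_such_thing", seed = 1), "available")

  # deep fragmentation: between-cluster FST exceeds within-cluster FST
  hits <- 0L; n_rep <- 40L
  for (i in seq_len(n_rep)) {
    s <- makeScenario("fragmentation", seed = 5000 + i, n_demes = 4,
                      n_per_deme = 6, t_split = 10)
    fm <- fstNmMatrices(s$alignment, s$map)
    within <- c(fm$fst["P1", "P2"], fm$fst["P3", "P4"])
    between <- c(fm$fst["P1", "P3"], fm$fst["P1", "P4"],
                 fm$fst["P2", "P3"], fm$fst["P2", "P4"])
    if (mean(between) > mean(within)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)

  # stepping stone: differentiation increases with deme distance
  hits <- 0L; n_rep <- 30L
  for (i in seq_len(n_rep)) {
    s <- makeScenario("ibd_stepping_stone", seed = 6000 + i, n_demes = 5,
                      n_per_deme = 6)
    fm <- fstNmMatrices(s$alignment, s$map)
    dm <- populationDistanceMatrix(s$map)[fm$populations, fm$populations]
    lower <- lower.tri(fm$fst)
    r <- suppressWarnings(stats::cor(fm$fst[lower], dm[lower]))
    if (!is.na(r) && r > 0) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)

  s1 <- makeScenario("range_expansion", seed = 77, n_demes = 3, n_per_deme = 5)
  s2 <- makeScenario("range_expansion", seed = 77, n_demes = 3, n_per_deme = 5)
  expect_identical(as.character(s1$alignment@seqs),
                   as.character(s2$alignment@seqs))
})

test_that("the packaged fixture validates its printed checksums", {
  fx <- makePaperFixture()
  expect_equal(nTotal(fx$table), 77)
  expect_equal(nrow(haploCounts(fx$table)), 38)
  cn <- fx$clade_nesting
  cm <- fx$clade_members
  h32 <- cm$haplotype[cm$clade %in%
                        cn$clade[cn$parent %in% cn$clade[cn$parent == "3-2"]]]
  expect_equal(sum(haploCounts(fx$table)[h32, ]), 51)
  # per-population totals match the printed sampling design
  expect_equal(unname(colSums(haploCounts(fx$table))),
               c(10, 10, 10, 10, 8, 10, 10, 9))
})
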