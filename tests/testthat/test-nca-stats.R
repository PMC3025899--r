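# a tiny two-clade design over four haplotypes on a path A-B-C-D
toyDesign <- function(countsA = c(1L, 1L), countsB = c(1L, 1L),
                      pops = c("P1", "P2"),
                      sites = data.frame(population = c("P1", "P2"),
                                         lat = c(40, 40),
                                         lon = c(106, 107.17))) {
  d <- pathDist(LETTERS[1:4])
  cnt <- matrix(0L, 4, length(pops), dimnames = list(LETTERS[1:4], pops))
  cnt["A", 1] <- countsA[1]; cnt["B", 1] <- countsA[2]
  cnt["C", 2] <- countsB[1]; cnt["D", 2] <- countsB[2]
  nw <- minimumSpanningNetwork(d, cnt)
  list(design = buildNesting(nw),
       tab = new("HaplotypeTable", counts = cnt, sequences = character(0)),
       map = newPopulationMap(
         data.frame(sample = paste0("s", seq_along(pops)), population = pops),
         sites))
}

test_that("clade distances follow their geometric definitions", {
  td <- toyDesign()
  cd <- cladeDistances(td$design, td$tab, td$map)
  # a clade whose individuals all sit in one population has Dc = 0
  lvl1 <- cd[grepl("^1-", cd$nesting_clade), ]
  expect_true(all(abs(lvl1$Dc) < 1e-9))

  # a clade split equally between two sites ~100 km apart spreads ~50 km
  sep <- greatCircleKm(40, 106, 40, 107.17)
  cnt <- matrix(c(1L, 1L), 2, 2, dimnames = list(c("A", "B"), c("P1", "P2")))
  cnt["A", ] <- c(1L, 1L); cnt["B", ] <- c(0L, 0L)
  cnt <- cnt[1, , drop = FALSE]
  d2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  cnt2 <- matrix(c(1L, 1L, 1L, 1L), 2, 2,
                 dimnames = list(c("A", "B"), c("P1", "P2")))
  tab2 <- new("HaplotypeTable", counts = cnt2, sequences = character(0))
  des2 <- buildNesting(minimumSpanningNetwork(d2, cnt2))
  map2 <- tdMap <- newPopulationMap(
    data.frame(sample = c("s1", "s2"), population = c("P1", "P2")),
    data.frame(population = c("P1", "P2"), lat = c(40, 40),
               lon = c(106, 107.17)))
  cd2 <- cladeDistances(des2, tab2, map2)
  expect_equal(cd2$Dc, rep(sep / 2, nrow(cd2)), tolerance = 0.2 / (sep / 2))
})

test_that("Dn equals Dc when the nesting clade is the clade itself", {
  # a design in which "total" has a single member clade holding everything
  cnt <- matrix(c(2L, 1L, 0L, 3L), 2, 2,
                dimnames = list(c("A", "B"), c("P1", "P2")))
  des <- new("NestingDesign",
             clades = data.frame(clade_id = c("A", "B", "1-1", "total"),
                                 level = c(0L, 0L, 1L, 2L),
                                 status = c("tip", "tip", "interior",
                                            "interior"),
                                 parent = c("1-1", "1-1", "total", NA),
                                 stringsAsFactors = FALSE),
             members = list(`1-1` = c("A", "B"), total = "1-1"),
             haplotypes = list(`1-1` = c("A", "B"), total = c("A", "B")),
             tree = data.frame(u = "A", v = "B", steps = 1L),
             network = data.frame(u = "A", v = "B", steps = 1L),
             broken = data.frame())
  tab <- new("HaplotypeTable", counts = cnt, sequences = character(0))
  map <- newPopulationMap(
    data.frame(sample = c("s1", "s2"), population = c("P1", "P2")),
    data.frame(population = c("P1", "P2"), lat = c(39, 41), lon = c(106, 108)))
  cd <- cladeDistances(des, tab, map)
  row <- cd[cd$nesting_clade == "total", ]
  expect_equal(row$Dn, row$Dc)
})

test_that("Dc and Dn are invariant to uniform longitude translation", {
  td <- toyDesign(countsA = c(3L, 2L), countsB = c(1L, 4L))
  cd1 <- cladeDistances(td$design, td$tab, td$map)
  shifted <- td$map@sites
  shifted$lon <- ((shifted$lon + 57 + 180) %% 360) - 180
  map2 <- newPopulationMap(td$map@samples, shifted)
  cd2 <- cladeDistances(td$design, td$tab, map2)
  expect_equal(cd1$Dc, cd2$Dc, tolerance = 1e-9)
  expect_equal(cd1$Dn, cd2$Dn, tolerance = 1e-9)
})

test_that("permutation p-values are 1 for location-invariant data", {
  td <- toyDesign(pops = c("P1", "P1"),
                  sites = data.frame(population = "P1", lat = 40, lon = 106))
  ps <- permutationSignificance(td$design, td$tab, td$map, n_perm = 50,
                                seed = 1)
  u <- ps$units[!is.na(ps$units$p_small_Dc), ]
  expect_true(all(u$p_small_Dc == 1))
  expect_true(all(u$p_large_Dn == 1))
})

test_that("exact permutation p-values match exhaustive enumeration", {
  skip_if_not_installed("geosphere")
  td <- toyDesign(countsA = c(2L, 1L), countsB = c(1L, 1L),
                  pops = c("P1", "P2"))
  ps <- permutationSignificance(td$design, td$tab, td$map, n_perm = 1,
                                seed = 1, exact = TRUE)
  tot <- ps$units[ps$units$nesting_clade == "total", ]
  mem <- td$design@members[["total"]]
  cnt <- haploCounts(td$tab)
  wl <- lapply(mem, cpPhylogeo:::.unitPopCounts, design = td$design,
               cnt = cnt)
  labels <- unlist(lapply(wl, function(w) rep(names(w), w)))
  sizes <- vapply(wl, sum, numeric(1))
  orc <- oracle_nca_exact(labels, sizes, td$map@sites)
  k <- length(mem)
  expect_equal(tot$Dc, unname(orc$obs[seq_len(k)]), tolerance = 1e-6)
  expect_equal(tot$Dn, unname(orc$obs[k + seq_len(k)]), tolerance = 1e-6)
  expect_equal(tot$p_small_Dc, unname(orc$p_small[seq_len(k)]))
  expect_equal(tot$p_large_Dc, unname(orc$p_large[seq_len(k)]))
  expect_equal(tot$p_small_Dn, unname(orc$p_small[k + seq_len(k)]))
  expect_equal(tot$p_large_Dn, unname(orc$p_large[k + seq_len(k)]))
})

test_that("permutation runs are reproducible under a fixed seed", {
  td <- toyDesign(countsA = c(3L, 2L), countsB = c(1L, 4L))
  a <- permutationSignificance(td$design, td$tab, td$map, n_perm = 300,
                               seed = 77)
  b <- permutationSignificance(td$design, td$tab, td$map, n_perm = 300,
                               seed = 77)
  expect_identical(a, b)
  expect_error(permutationSignificance(td$design, td$tab, td$map,
                                       n_perm = 10), "seed")
})

test_that("the nested contingency test matches exhaustive expectations", {
  # complete separation (3,0 / 0,3): exact p = 2 / C(6,3) = 0.1
  d <- pathDist(c("A", "B"))
  cnt <- matrix(c(3L, 0L, 0L, 3L), 2, 2,
                dimnames = list(c("A", "B"), c("P1", "P2")))
  des <- buildNesting(minimumSpanningNetwork(d, cnt))
  tab <- new("HaplotypeTable", counts = cnt, sequences = character(0))
  ct <- nestedContingencyTest(des, tab, n_perm = 20000, seed = 3)
  p <- ct$p_perm[ct$nesting_clade == "total"]
  expect_equal(p, 0.1, tolerance = 0.1)

  # complete separation at n = 10 + 10 is overwhelming
  cnt2 <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
                 dimnames = list(c("A", "B"), c("P1", "P2")))
  des2 <- buildNesting(minimumSpanningNetwork(d, cnt2))
  tab2 <- new("HaplotypeTable", counts = cnt2, sequences = character(0))
  ct2 <- nestedContingencyTest(des2, tab2, n_perm = 10000, seed = 3)
  expect_lte(ct2$p_perm[ct2$nesting_clade == "total"], 0.001)

  # a uniform table shows no association
  cnt3 <- matrix(5L, 2, 2, dimnames = list(c("A", "B"), c("P1", "P2")))
  des3 <- buildNesting(minimumSpanningNetwork(d, cnt3))
  tab3 <- new("HaplotypeTable", counts = cnt3, sequences = character(0))
  ct3 <- nestedContingencyTest(des3, tab3, n_perm = 2000, seed = 3)
  expect_gt(ct3$p_perm[ct3$nesting_clade == "total"], 0.5)

  # determinism
  ct3b <- nestedContingencyTest(des3, tab3, n_perm = 2000, seed = 3)
  expect_identical(ct3, ct3b)

  # single-column tables are flagged not-applicable
  cnt4 <- matrix(c(3L, 4L), 2, 1, dimnames = list(c("A", "B"), "P1"))
  des4 <- buildNesting(minimumSpanningNetwork(d, cnt4))
  tab4 <- new("HaplotypeTable", counts = cnt4, sequences = character(0))
  ct4 <- nestedContingencyTest(des4, tab4, n_perm = 100, seed = 1)
  expect_false(any(ct4$applicable))
})
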