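test_that("K2P distances follow the closed form and flag saturation", {
  expect_equal(k2pDistance("ACGTACGT", "ACGTACGT"), 0)

  # exactly 10 transitions and 5 transversions over 100 sites
  x <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  y <- x
  y[1:10] <- "G"                       # transitions (A->G)
  y[11:15] <- "C"                      # transversions (A->C)
  d <- k2pDistance(paste(x, collapse = ""), paste(y, collapse = ""))
  expect_equal(d, -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(d, 0.1702, tolerance = 1e-3)

  # P = 0.5, Q = 0 sits on the log-domain boundary
  z <- x; z[1:50] <- "G"
  sat <- k2pDistance(paste(x, collapse = ""), paste(z, collapse = ""))
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
})

test_that("the K2P matrix agrees with ape's distance implementation", {
  a <- relatedAlignment(6, 200, nmut = 12, seed = 61)
  d1 <- k2pMatrix(a)
  m <- alignmentMatrix(a)
  db <- ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "K80",
                      pairwise.deletion = TRUE, as.matrix = TRUE)
  expect_equal(d1, db[rownames(d1), colnames(d1)], tolerance = 1e-10)
})

test_that("neighbor joining recovers additive trees exactly", {
  # three taxa: closed-form star
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighborJoining(d3)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  expect_equal(unname(ape::cophenetic.phylo(t3)[c("a", "b", "c"),
                                                c("a", "b", "c")]),
               unname(d3), tolerance = 1e-10)

  # four taxa from a known tree: exact branch lengths and topology
  labs <- c("a", "b", "c", "d")
  d4 <- matrix(c(0, 5, 5, 7,
                 5, 0, 6, 8,
                 5, 6, 0, 6,
                 7, 8, 6, 0), 4, 4, dimnames = list(labs, labs))
  t4 <- neighborJoining(d4)
  expect_equal(ape::cophenetic.phylo(t4)[labs, labs], d4, tolerance = 1e-10)

  # larger random additive matrices round-trip through NJ
  skip_if_not_installed("phangorn")
  set.seed(62)
  for (n in c(6, 8)) {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
    tr <- ape::unroot(tr)
    dd <- ape::cophenetic.phylo(tr)
    rec <- neighborJoining(dd)
    expect_equal(phangorn::RF.dist(rec, tr), 0)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dd), colnames(dd)], dd,
                 tolerance = 1e-8)
    # label-order invariance
    ord <- sample(rownames(dd))
    rec2 <- neighborJoining(dd[ord, ord])
    expect_equal(phangorn::RF.dist(rec2, rec), 0)
  }

  dna <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighborJoining(dna), "a-b")
})

test_that("bootstrap gives full support to a clean bipartition", {
  base <- paste(rep("A", 60), collapse = "")
  flip <- function(s, idx, to) {
    v <- strsplit(s, "")[[1]]; v[idx] <- to; paste(v, collapse = "")
  }
  cl1 <- c(x1 = base, x2 = flip(base, 1, "C"), x3 = flip(base, 2, "C"))
  far <- flip(base, 21:32, "T")
  cl2 <- c(y1 = far, y2 = flip(far, 3, "G"), y3 = flip(far, 4, "G"))
  a <- newHaploAlignment(c(cl1, cl2))
  bs <- bootstrapSupport(a, n_reps = 80, seed = 5)
  expect_equal(bs$n_used, 80)
  expect_true(any(bs$tree$node.label == 100))
  bs2 <- bootstrapSupport(a, n_reps = 80, seed = 5)
  expect_identical(bs$tree$node.label, bs2$tree$node.label)
})

test_that("bootstrap supports are Monte-Carlo consistent across depths", {
  a <- relatedAlignment(6, 120, nmut = 10, seed = 63)
  b1 <- bootstrapSupport(a, n_reps = 100, seed = 7)
  b2 <- bootstrapSupport(a, n_reps = 400, seed = 8)
  expect_true(all(abs(b1$tree$node.label - b2$tree$node.label) <= 25))
})

test_that("newick output round-trips topology, lengths and supports", {
  t3 <- neighborJoining(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                               dimnames = list(letters[1:3], letters[1:3])))
  tf <- tempfile(fileext = ".nwk")
  writeNewick(t3, tf)
  back <- readNewick(tf)
  expect_equal(sort(back$tip.label), sort(t3$tip.label))
  expect_equal(sort(back$edge.length), sort(t3$edge.length),
               tolerance = 1e-9)

  set.seed(64)
  t20 <- ape::rtree(20)
  writeNewick(t20, tf)
  b20 <- readNewick(tf)
  expect_equal(ape::cophenetic.phylo(b20)[t20$tip.label, t20$tip.label],
               ape::cophenetic.phylo(t20), tolerance = 1e-9)

  sup <- t20; sup$node.label <- as.character(seq_len(sup$Nnode))
  writeNewick(sup, tf)
  expect_equal(readNewick(tf)$node.label, sup$node.label)

  writeLines("((a:1,b:2", tf)
  expect_error(readNewick(tf), "newick")
})
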