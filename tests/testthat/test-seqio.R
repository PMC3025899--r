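test_that("FASTA alignments are read in order, uppercased, with U mapped to T", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 first sample", "acguacguac", ">s2", "ACGTACGTAC"), tf)
  a <- readFastaAlignment(tf)
  expect_s4_class(a, "HaploAlignment")
  expect_equal(alnLength(a), 10L)
  expect_equal(sampleIDs(a), c("s1", "s2"))
  expect_equal(as.character(a@seqs[["s1"]]), "ACGTACGTAC")

  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTA"), tf)
  expect_error(readFastaAlignment(tf), "s2")
  writeLines(character(0), tf)
  expect_error(readFastaAlignment(tf))
})

test_that("indel columns are removed with 0-based kept indices", {
  a <- newHaploAlignment(c(x = "ACGT", y = "AC-T"))
  r <- dropIndelColumns(a)
  expect_equal(alnLength(r$alignment), 3L)
  expect_equal(r$kept_columns, c(0L, 1L, 3L))

  b <- randomAlignment(4, 12, seed = 1)
  r2 <- dropIndelColumns(b)
  expect_equal(alnLength(r2$alignment), 12L)
  expect_equal(r2$kept_columns, 0:11)

  # gaps at two distinct columns across 5 sequences shrink L by 2
  m <- alignmentMatrix(randomAlignment(5, 20, seed = 2))
  m[2, 5] <- "-"; m[4, 17] <- "-"
  c3 <- newHaploAlignment(apply(m, 1, paste, collapse = ""))
  expect_equal(alnLength(dropIndelColumns(c3)$alignment), 18L)

  allgap <- newHaploAlignment(c(x = "A-", y = "-A"))
  expect_error(dropIndelColumns(allgap), "degenerate")
})

test_that("haplotype collapsing matches string deduplication and keeps counts", {
  ids <- sprintf("s%d", 1:4)
  a <- newHaploAlignment(stats::setNames(c(rep("ACGT", 3), "ACGA"), ids))
  t1 <- collapseHaplotypes(a, toyMap(ids))
  expect_equal(rownames(haploCounts(t1)), c("H01", "H02"))
  expect_equal(unname(rowSums(haploCounts(t1))), c(3, 1))

  b <- randomAlignment(10, 30, seed = 3)   # essentially all distinct
  t2 <- collapseHaplotypes(b, toyMap(sampleIDs(b)))
  expect_equal(nrow(haploCounts(t2)), length(unique(as.character(b@seqs))))

  # 20 random sequences from a small haplotype pool: counts = distinct strings
  set.seed(4)
  pool <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE), collapse = ""),
    character(1))
  seqs <- sample(pool, 20, replace = TRUE)
  names(seqs) <- sprintf("s%02d", 1:20)
  t3 <- collapseHaplotypes(newHaploAlignment(seqs), toyMap(names(seqs)))
  expect_equal(nrow(haploCounts(t3)), length(unique(seqs)))
  expect_equal(sum(haploCounts(t3)), 20)   # total preserved

  expect_error(collapseHaplotypes(a, toyMap(c("s1", "s2", "s3"))), "missing")
})

test_that("N acts as a wildcard for haplotype identity", {
  ids <- c("a", "b", "c")
  a <- newHaploAlignment(stats::setNames(c("ACGT", "ACNT", "TCGT"), ids))
  t1 <- collapseHaplotypes(a, toyMap(ids))
  expect_equal(nrow(haploCounts(t1)), 2L)
  # the resolved sequence is kept as the representative
  expect_equal(unname(haploSequences(t1)[["H01"]]), "ACGT")
})

test_that("degree-minute coordinates parse to signed decimal degrees", {
  expect_equal(parseDmsCoordinate("106°49'E 39°25'N"),
               c(lat = 39 + 25 / 60, lon = 106 + 49 / 60), tolerance = 1e-9)
  expect_equal(parseDmsCoordinate("0°0'E 0°0'N"),
               c(lat = 0, lon = 0))
  expect_equal(parseDmsCoordinate("107°03'E 40°16'N"),
               c(lat = 40 + 16 / 60, lon = 107.05), tolerance = 1e-9)
  # hemisphere signs and token order
  expect_equal(parseDmsCoordinate("39°30'S 10°15'W"),
               c(lat = -39.5, lon = -10.25))
  expect_error(parseDmsCoordinate("106°75'E 39°25'N"), "minutes")
  expect_error(parseDmsCoordinate("garbage"), "malformed")
})

test_that("haversine distance matches an independent implementation", {
  expect_equal(greatCircleKm(10, 20, 10, 20), 0)
  expect_equal(greatCircleKm(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  skip_if_not_installed("geosphere")
  szs <- parseDmsCoordinate("106°49'E 39°25'N")
  blg <- parseDmsCoordinate("107°03'E 40°16'N")
  ref <- geosphere::distHaversine(c(szs[["lon"]], szs[["lat"]]),
                                  c(blg[["lon"]], blg[["lat"]]),
                                  r = 6371000) / 1000
  expect_equal(greatCircleKm(szs[["lat"]], szs[["lon"]],
                             blg[["lat"]], blg[["lon"]]),
               ref, tolerance = 0.1 / ref)
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  for (i in 1:25) {
    p <- cbind(lat = stats::runif(3, -90, 90), lon = stats::runif(3, -180, 180))
    dab <- greatCircleKm(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    dba <- greatCircleKm(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    dbc <- greatCircleKm(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    dac <- greatCircleKm(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc + 1e-6)
  }
})

test_that("haplotype count tables read with totals and error checks", {
  fx <- system.file("extdata", "haplotype_counts.tsv", package = "cpPhylogeo")
  tab <- readHaplotypeCounts(fx)
  expect_equal(nTotal(tab), 77)
  expect_equal(dim(haploCounts(tab)), c(38L, 8L))

  tf <- tempfile(fileext = ".tsv")
  writeLines(c("haplotype\tYK", "H30\t8"), tf)
  mono <- readHaplotypeCounts(tf)
  expect_equal(nTotal(mono), 8)
  expect_equal(nrow(haploCounts(mono)), 1L)

  writeLines("haplotype\tYK", tf)
  expect_error(readHaplotypeCounts(tf), "no rows")
  writeLines(c("haplotype\tYK", "H30\t-2"), tf)
  expect_error(readHaplotypeCounts(tf), "non-negative")
})
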