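# Independent oracles and small builders used across the test files.

# random gap-free alignment over ACGT
randomAlignment <- function(n, L, seed, with_n = FALSE) {
  set.seed(seed)
  alpha <- c("A", "C", "G", "T", if (with_n) "N")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alpha, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n))
  newHaploAlignment(seqs)
}

# one-population map covering the given sample ids
toyMap <- function(ids, pops = rep("pop1", length(ids)),
                   sites = NULL) {
  if (is.null(sites)) {
    up <- unique(pops)
    sites <- data.frame(population = up,
                        lat = seq(39, by = 0.5, length.out = length(up)),
                        lon = seq(106, by = 0.5, length.out = length(up)))
  }
  newPopulationMap(data.frame(sample = ids, population = pops), sites)
}

# brute-force nucleotide diversity: explicit double loop over pairs/sites
oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- m[i, ] != "N" & m[j, ] != "N"
    tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
    np <- np + 1
  }
  tot / np
}

# decode a Pruefer sequence into a tree edge list (labels 1..k)
pruferDecode <- function(pseq, k) {
  degree <- rep(1L, k)
  for (x in pseq) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, nrow = k - 1L, ncol = 2L)
  r <- 0L
  for (x in pseq) {
    leaf <- which(degree == 1L)[1L]
    r <- r + 1L
    edges[r, ] <- c(leaf, x)
    degree[leaf] <- degree[leaf] - 1L
    degree[x] <- degree[x] - 1L
  }
  last <- which(degree == 1L)
  edges[k - 1L, ] <- last
  edges
}

# minimum spanning-tree weight by exhaustive enumeration over all k^(k-2)
# labeled trees (Cayley/Pruefer)
oracle_mst_weight <- function(d) {
  k <- nrow(d)
  if (k == 1L) return(0)
  if (k == 2L) return(d[1L, 2L])
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2L)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    ed <- pruferDecode(grid[r, ], k)
    w <- sum(d[ed])
    if (w < best) best <- w
  }
  best
}

# exhaustive NCA permutation p-values for one nesting clade: independent
# spread implementation (geosphere haversine, own centroid)
oracle_nca_exact <- function(labels, sizes, sites) {
  stopifnot(requireNamespace("geosphere", quietly = TRUE))
  spread <- function(lab, centre_lab) {
    xy <- sites[match(lab, sites$population), c("lon", "lat")]
    cxy <- sites[match(centre_lab, sites$population), c("lon", "lat")]
    v <- colMeans(cbind(
      cos(cxy$lat * pi / 180) * cos(cxy$lon * pi / 180),
      cos(cxy$lat * pi / 180) * sin(cxy$lon * pi / 180),
      sin(cxy$lat * pi / 180)))
    v <- v / sqrt(sum(v^2))
    centre <- c(atan2(v[2], v[1]) * 180 / pi, asin(v[3]) * 180 / pi)
    mean(geosphere::distHaversine(as.matrix(xy), centre, r = 6371000) / 1000)
  }
  k <- length(sizes)
  statFor <- function(ord) {
    lab <- labels[ord]
    off <- 0
    Dc <- Dn <- numeric(k)
    for (i in seq_len(k)) {
      li <- lab[seq(off + 1, off + sizes[i])]
      off <- off + sizes[i]
      Dc[i] <- spread(li, li)
      Dn[i] <- spread(li, lab)
    }
    c(Dc, Dn)
  }
  perms <- allOrders(length(labels))
  stats <- t(apply(perms, 1, statFor))
  obs <- statFor(seq_along(labels))
  eps <- 1e-9
  list(
    p_small = colMeans(sweep(stats, 2, obs + eps, `<=`)),
    p_large = colMeans(sweep(stats, 2, obs - eps, `>=`)),
    obs = obs)
}

# all orderings of 1..n (recursive, independent of the package internals)
allOrders <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allOrders(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

# coalescent tree under exponential growth (backward N(t) = N0 exp(-r t)),
# for the skyline direction check
growthTree <- function(n, N0, r, seed) {
  set.seed(seed)
  labels <- sprintf("t%d", seq_len(n))
  heights <- stats::setNames(rep(0, n), labels)
  t <- 0
  while (length(labels) > 1L) {
    i <- length(labels)
    E <- stats::rexp(1L)
    t <- (1 / r) * log(exp(r * t) + r * E * N0 / choose(i, 2))
    pair <- sample.int(i, 2L)
    a <- labels[pair[1L]]; b <- labels[pair[2L]]
    nwk <- sprintf("(%s:%.10g,%s:%.10g)", a, t - heights[[a]],
                   b, t - heights[[b]])
    labels <- c(labels[-pair], nwk)
    heights <- c(heights[-pair], stats::setNames(t, nwk))
  }
  ape::read.tree(text = paste0(labels, ";"))
}

# run the full NCA chain on a simulated scenario and return the set of
# conclusions reached across all nesting clades
scenarioConclusions <- function(name, seed, n_perm = 200) {
  sim <- makeScenario(name, seed = seed)
  tab <- collapseHaplotypes(sim$alignment, sim$map)
  nw <- minimumSpanningNetwork(stepMatrix(tab), haploCounts(tab))
  des <- buildNesting(nw)
  nca <- permutationSignificance(des, tab, sim$map, n_perm = n_perm,
                                 seed = seed + 1)
  ct <- nestedContingencyTest(des, tab, n_perm = n_perm, seed = seed + 2)
  nests <- cladeTable(des)$clade_id[cladeTable(des)$level >= 1]
  vapply(nests, function(nc)
    applyInferenceKey(nca, ct, des, tab, nesting_clade = nc)$conclusion,
    character(1))
}

# integer path distance matrix over the given labels
pathDist <- function(labels) {
  k <- length(labels)
  d <- outer(seq_len(k), seq_len(k), function(i, j) abs(i - j))
  dimnames(d) <- list(labels, labels)
  d
}

# low-divergence alignment: a random base sequence with a few substitutions
# per record (keeps K2P well inside its log domain)
relatedAlignment <- function(n, L, nmut, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- root
    idx <- sample.int(L, nmut)
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n))
  newHaploAlignment(seqs)
}
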