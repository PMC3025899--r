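#' Simulation parameters for the island-model generator
#'
#' Defaults emulate the sampling design and sequence properties of a small
#' range-wide chloroplast-spacer survey: eight demes with samples of 8-10,
#' one non-recombining maternally inherited locus of 881 sites, an A/T-rich
#' base composition (A+T = 73.6%), and gene flow low enough to produce high
#' between-population differentiation and many private haplotypes.
#'
#' @param n_demes number of demes.
#' @param sample_sizes per-deme sample sizes (recycled if length 1).
#' @param Nm migrants per generation (haploid maternal number); the
#'   per-lineage migration rate is internally scaled by (d-1)/d so that the
#'   island-model expectation FST = 1/(1 + 2Nm) holds for any deme number.
#' @param theta per-site scaled mutation rate (2 N mu per site).
#' @param L number of sites.
#' @param base_composition frequencies of A, C, G, T (sum to 1).
#' @param seed RNG seed.
#' @return list of class \code{SimParams}.
#' @export
simParams <- function(n_demes = 8L,
                      sample_sizes = c(10L, 10L, 10L, 10L, 8L, 10L, 10L, 9L),
                      Nm = 0.3, theta = 0.005, L = 881L,
                      base_composition = c(A = 0.368, C = 0.132,
                                           G = 0.132, T = 0.368),
                      seed = 1L) {
  if (length(sample_sizes) == 1L) sample_sizes <- rep(sample_sizes, n_demes)
  stopifnot(n_demes >= 1, length(sample_sizes) == n_demes,
            all(sample_sizes >= 1), Nm >= 0, theta > 0, L >= 1,
            length(base_composition) == 4,
            abs(sum(base_composition) - 1) < 1e-8)
  structure(list(n_demes = as.integer(n_demes),
                 sample_sizes = as.integer(sample_sizes), Nm = Nm,
                 theta = theta, L = as.integer(L),
                 base_composition = base_composition, seed = as.integer(seed)),
            class = "SimParams")
}

# structured coalescent under an arbitrary per-lineage migration rate
# matrix (scaled time, units of N generations; within-deme coalescence at
# rate C(k,2) per deme). merge_time: optional time at which all lineages
# collapse into deme 1 (panmixia onward). Returns parent/branch arrays.
.structuredCoalescent <- function(deme_of, mig, merge_time = Inf) {
  n <- length(deme_of)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); blen <- numeric(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  deme <- deme_of
  t <- 0; nxt <- n
  merged <- FALSE
  while (length(active) > 1L) {
    if (!merged && t >= merge_time) { deme[active] <- 1L; merged <- TRUE }
    k_by <- table(factor(deme[active], levels = seq_len(nrow(mig))))
    coal_rates <- choose(as.numeric(k_by), 2)
    mig_rates <- as.numeric(k_by) * rowSums(mig)
    tot <- sum(coal_rates) + sum(mig_rates)
    if (tot <= 0) {
      if (!merged && is.finite(merge_time)) { t <- merge_time; next }
      stop("degenerate configuration: no events possible ",
           "(isolated lineages with no migration)")
    }
    dt <- stats::rexp(1L, tot)
    if (!merged && t + dt > merge_time) { # event lands past the merge
      t <- merge_time
      next
    }
    t <- t + dt
    if (stats::runif(1L) < sum(coal_rates) / tot) {
      dd <- sample.int(length(coal_rates), 1L, prob = coal_rates)
      pair <- sample(active[deme[active] == dd], 2L)
      nxt <- nxt + 1L
      node_time[nxt] <- t
      for (ch in pair) {
        parent[ch] <- nxt
        blen[ch] <- t - node_time[ch]
      }
      deme[nxt] <- dd
      active <- c(setdiff(active, pair), nxt)
    } else {
      src <- sample.int(nrow(mig), 1L, prob = as.numeric(k_by) * rowSums(mig))
      ln <- active[deme[active] == src]
      ln <- if (length(ln) == 1L) ln else sample(ln, 1L)
      dst <- sample.int(ncol(mig), 1L, prob = mig[src, ])
      deme[ln] <- dst
    }
  }
  root <- active
  list(parent = parent, blen = blen, node_time = node_time, root = root,
       n_tips = n)
}

# drop finite-sites mutations down the genealogy
.simSequences <- function(g, theta_site, L, base_comp) {
  bases <- c("A", "C", "G", "T")
  rate <- theta_site * L / 2   # per lineage per coalescent time unit
  children <- split(seq_along(g$parent)[g$parent > 0L],
                    g$parent[g$parent > 0L])
  seqs <- vector("list", 2L * g$n_tips - 1L)
  seqs[[g$root]] <- sample(bases, L, replace = TRUE, prob = base_comp)
  stack <- g$root
  while (length(stack)) {
    node <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (ch in children[[as.character(node)]]) {
      s <- seqs[[node]]
      nmut <- stats::rpois(1L, rate * g$blen[ch])
      if (nmut > 0) for (i in seq_len(nmut)) {
        site <- sample.int(L, 1L)
        cur <- s[site]
        pr <- base_comp[bases != cur]
        s[site] <- sample(bases[bases != cur], 1L, prob = pr / sum(pr))
      }
      seqs[[ch]] <- s
      if (!is.null(children[[as.character(ch)]])) stack <- c(stack, ch)
    }
  }
  vapply(seq_len(g$n_tips), function(i) paste(seqs[[i]], collapse = ""),
         character(1))
}

# deme coordinates on a grid, roughly 50 km spacing
.gridCoordinates <- function(d, spacing_km = 50) {
  ncol <- ceiling(sqrt(d))
  row <- (seq_len(d) - 1L) %/% ncol
  col <- (seq_len(d) - 1L) %% ncol
  lat0 <- 39.5; lon0 <- 106.5
  dlat <- spacing_km / 111.2
  dlon <- spacing_km / (111.2 * cos(lat0 * pi / 180))
  data.frame(population = sprintf("P%d", seq_len(d)),
             lat = lat0 + row * dlat, lon = lon0 + col * dlon,
             elevation = NA_real_, stringsAsFactors = FALSE)
}

.assembleSimOutput <- function(g, p, sites) {
  seqs <- .simSequences(g, p$theta, p$L, p$base_composition)
  deme_of <- rep(seq_len(p$n_demes), p$sample_sizes)
  ids <- sprintf("P%d_%02d", deme_of,
                 unlist(lapply(p$sample_sizes, seq_len)))
  names(seqs) <- ids
  aln <- newHaploAlignment(seqs)
  map <- newPopulationMap(
    data.frame(sample = ids, population = sprintf("P%d", deme_of)),
    sites)
  list(alignment = aln, map = map)
}

#' Simulate an island-model sample at a cpDNA-like locus
#'
#' Draws a genealogy from the structured coalescent with symmetric
#' migration at the rate implied by \code{Nm} (scaled so that the
#' island-model expectation FST = 1/(1 + 2Nm) holds), then drops
#' finite-sites mutations on the branches at rate theta L / 2 per lineage
#' per coalescent time unit with the configured base composition. Deme
#' coordinates are assigned on a grid. Fully reproducible from the seed.
#'
#' @param p a [simParams()] object.
#' @return list with \code{alignment} ([HaploAlignment-class]) and
#'   \code{map} ([PopulationMap-class]).
#' @export
simulateIslandCoalescent <- function(p) {
  stopifnot(inherits(p, "SimParams"))
  set.seed(p$seed)
  d <- p$n_demes
  mig <- matrix(0, d, d)
  if (d > 1L && p$Nm > 0) {
    per_lineage <- p$Nm * (d - 1) / d      # finite-island correction
    mig[] <- per_lineage / (d - 1)
    diag(mig) <- 0
  }
  deme_of <- rep(seq_len(d), p$sample_sizes)
  g <- .structuredCoalescent(deme_of, mig)
  .assembleSimOutput(g, p, .gridCoordinates(d))
}

#' Simulate a constant-size Kingman coalescent tree
#'
#' Waiting times while i lineages remain are Exp(C(i,2)/N); the tree is
#' ultrametric by construction with branch lengths in generations.
#'
#' @param n number of tips (>= 2).
#' @param N effective population size (gene copies).
#' @param seed RNG seed.
#' @return an \code{ape::phylo} ultrametric tree.
#' @export
simulateConstantCoalescentTree <- function(n, N, seed) {
  stopifnot(n >= 2, N > 0)
  set.seed(seed)
  heights <- stats::setNames(rep(0, n), sprintf("t%d", seq_len(n)))
  labels <- sprintf("t%d", seq_len(n))
  t <- 0
  while (length(labels) > 1L) {
    i <- length(labels)
    t <- t + stats::rexp(1L, choose(i, 2) / N)
    pair <- sample.int(i, 2L)
    a <- labels[pair[1L]]; b <- labels[pair[2L]]
    nwk <- sprintf("(%s:%.10g,%s:%.10g)", a, t - heights[[a]],
                   b, t - heights[[b]])
    labels <- c(labels[-pair], nwk)
    heights <- c(heights[-pair], stats::setNames(t, nwk))
  }
  ape::read.tree(text = paste0(labels, ";"))
}

#' Generate a named demographic scenario
#'
#' \describe{
#'   \item{ibd_stepping_stone}{linear demes with nearest-neighbour
#'     migration; produces isolation by distance.}
#'   \item{fragmentation}{two deme clusters with no migration between them,
#'     split \code{t_split} coalescent time units ago; produces deeply
#'     divergent allopatric clades.}
#'   \item{range_expansion}{all demes founded very recently from deme 1;
#'     produces shallow star-like genealogies shared across demes.}
#' }
#'
#' @param name scenario name.
#' @param seed RNG seed.
#' @param n_demes number of demes (default 8).
#' @param n_per_deme samples per deme (default 10).
#' @param Nm migration intensity used where the scenario migrates
#'   (default 1).
#' @param t_split cluster split time for the fragmentation scenario, in
#'   coalescent time units (default 8).
#' @param theta,L mutation parameters as in [simParams()].
#' @return list with \code{alignment}, \code{map} and \code{scenario}
#'   metadata.
#' @export
makeScenario <- function(name = c("ibd_stepping_stone", "fragmentation",
                                  "range_expansion"),
                         seed, n_demes = 8L, n_per_deme = 10L, Nm = 1,
                         t_split = 8, theta = 0.005, L = 881L) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown scenario '", name[1L], "'; available: ibd_stepping_stone, ",
         "fragmentation, range_expansion", call. = FALSE))
  if (missing(seed)) stop("a seed is required")
  p <- simParams(n_demes = n_demes, sample_sizes = n_per_deme, Nm = Nm,
                 theta = theta, L = L, seed = seed)
  set.seed(seed)
  d <- n_demes
  deme_of <- rep(seq_len(d), p$sample_sizes)
  if (name == "ibd_stepping_stone") {
    mig <- matrix(0, d, d)
    for (i in seq_len(d - 1L)) {
      mig[i, i + 1L] <- mig[i + 1L, i] <- Nm
    }
    sites <- .gridCoordinates(d)
    sites$lat <- 39.5                                   # linear array
    sites$lon <- 106.5 + (seq_len(d) - 1L) * 50 / (111.2 * cos(39.5 * pi / 180))
    g <- .structuredCoalescent(deme_of, mig)
  } else if (name == "fragmentation") {
    half <- ceiling(d / 2)
    cl <- ifelse(seq_len(d) <= half, 1L, 2L)
    mig <- matrix(0, d, d)
    for (i in seq_len(d)) for (j in seq_len(d))
      if (i != j && cl[i] == cl[j]) mig[i, j] <- Nm / max(1, sum(cl == cl[i]) - 1)
    sites <- .gridCoordinates(d, spacing_km = 30)
    sites$lon <- sites$lon + ifelse(cl == 2L, 250 / (111.2 * cos(39.5 * pi / 180)), 0)
    g <- .structuredCoalescent(deme_of, mig, merge_time = t_split)
  } else {
    mig <- matrix(0, d, d)
    sites <- .gridCoordinates(d)
    g <- .structuredCoalescent(deme_of, mig, merge_time = 0.05)
  }
  out <- .assembleSimOutput(g, p, sites)
  out$scenario <- list(name = name, seed = seed, n_demes = d,
                       n_per_deme = n_per_deme, Nm = Nm,
                       t_split = if (name == "fragmentation") t_split else NA)
  out
}

#' Packaged study fixture (printed tables)
#'
#' Returns the published haplotype-by-population count table, the site
#' coordinates, and a clade-membership map consistent with every printed
#' clade-by-population count, with internal checksums validated (77
#' individuals, 38 haplotypes, clade totals).
#'
#' @return list of class \code{PaperFixture}: \code{table} (a
#'   [HaplotypeTable-class]), \code{map} (a [PopulationMap-class] with one
#'   pseudo-sample per individual), \code{clade_members} (haplotype ->
#'   1-step clade), \code{clade_nesting} (clade -> parent).
#' @export
makePaperFixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "cpPhylogeo")
  tab <- readHaplotypeCounts(ext("haplotype_counts.tsv"))
  sites_raw <- utils::read.table(ext("study_sites.tsv"), header = TRUE,
                                 sep = "\t", quote = "", stringsAsFactors = FALSE)
  cc <- t(vapply(sites_raw$coordinate, parseDmsCoordinate, numeric(2)))
  sites <- data.frame(population = sites_raw$population,
                      lat = cc[, "lat"], lon = cc[, "lon"],
                      elevation = sites_raw$elevation,
                      stringsAsFactors = FALSE)
  cm <- utils::read.table(ext("clade_members.tsv"), header = TRUE,
                          sep = "\t", quote = "", stringsAsFactors = FALSE)
  cn <- utils::read.table(ext("clade_nesting.tsv"), header = TRUE,
                          sep = "\t", quote = "", stringsAsFactors = FALSE)
  cnt <- haploCounts(tab)
  if (sum(cnt) != 77L || nrow(cnt) != 38L || ncol(cnt) != 8L)
    stop("fixture checksum failure: count table totals do not match")
  clade32 <- cn$clade[cn$parent == "3-2"]
  h32 <- cm$haplotype[cm$clade %in% cn$clade[cn$parent %in% clade32]]
  if (sum(cnt[h32, ]) != 51L)
    stop("fixture checksum failure: clade 3-2 must hold 51 individuals")
  # one pseudo-sample per individual so the table also works with sample-level
  # interfaces
  pops <- colnames(cnt)
  idx <- which(cnt > 0, arr.ind = TRUE)
  samples <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r) {
    k <- cnt[idx[r, 1L], idx[r, 2L]]
    data.frame(sample = sprintf("%s_%s_%d", rownames(cnt)[idx[r, 1L]],
                                pops[idx[r, 2L]], seq_len(k)),
               population = pops[idx[r, 2L]], stringsAsFactors = FALSE)
  }))
  structure(list(table = tab,
                 map = newPopulationMap(samples, sites),
                 clade_members = cm, clade_nesting = cn),
            class = "PaperFixture")
}

#' Nesting design from fixture clade memberships
#'
#' Builds a [NestingDesign-class] from an explicit haplotype-to-clade map
#' and clade-nesting table (as packaged by [makePaperFixture()]), for use
#' when the nesting is known rather than derived from a network. The
#' haplotype-level tree is left empty, so connection-based tip/interior
#' classification is unavailable; statuses are set NA.
#'
#' @param clade_members data.frame haplotype, clade.
#' @param clade_nesting data.frame clade, parent, level.
#' @return a [NestingDesign-class].
#' @export
nestingFromFixture <- function(clade_members, clade_nesting) {
  members <- split(clade_members$haplotype, clade_members$clade)
  haplos <- members
  lv1 <- sort(unique(clade_members$clade))
  for (lv in sort(unique(clade_nesting$level))) {
    rows <- clade_nesting[clade_nesting$level == lv, , drop = FALSE]
    for (par in unique(rows$parent)) {
      kids <- rows$clade[rows$parent == par]
      members[[par]] <- kids
      haplos[[par]] <- unlist(haplos[kids], use.names = FALSE)
    }
  }
  clades <- rbind(
    data.frame(clade_id = lv1, level = 1L,
               status = NA_character_,
               parent = clade_nesting$parent[match(lv1, clade_nesting$clade)],
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(sort(unique(clade_nesting$level)), function(lv) {
      kids <- unique(clade_nesting$parent[clade_nesting$level == lv])
      data.frame(clade_id = kids, level = lv + 1L, status = NA_character_,
                 parent = clade_nesting$parent[
                   match(kids, clade_nesting$clade)],
                 stringsAsFactors = FALSE)
    })))
  clades <- clades[!duplicated(clades$clade_id), , drop = FALSE]
  new("NestingDesign", clades = clades, members = members,
      haplotypes = haplos,
      tree = data.frame(u = character(0), v = character(0),
                        steps = integer(0), stringsAsFactors = FALSE),
      broken = data.frame())
}
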