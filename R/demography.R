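#' Coalescent intervals of an ultrametric genealogy
#'
#' Extracts, from the sorted internal-node heights of a rooted ultrametric
#' tree, the waiting intervals from the tips toward the root together with
#' the number of lineages present during each interval.
#'
#' @param t an \code{ape::phylo} tree, ultrametric within tolerance.
#' @param tol relative ultrametricity tolerance (default 1e-6 of the tree
#'   height).
#' @return data.frame of class \code{CoalescentIntervals} with columns
#'   \code{lineages} (n, n-1, ..., 2) and \code{duration} (same units as
#'   the branch lengths).
#' @export
coalescentIntervals <- function(t, tol = 1e-6) {
  stopifnot(inherits(t, "phylo"))
  if (any(t$edge.length < 0)) stop("negative branch lengths")
  depth <- ape::node.depth.edgelength(t)
  ntip <- length(t$tip.label)
  h <- max(depth)
  tipd <- depth[seq_len(ntip)]
  if (h > 0 && (max(tipd) - min(tipd)) > tol * h)
    stop("tree is not ultrametric within tolerance; ",
         "normalise tip heights (e.g. mean path-length smoothing) first")
  heights <- sort(h - depth[-seq_len(ntip)])   # coalescence times, ascending
  times <- c(0, heights)
  data.frame(lineages = seq(ntip, 2L),
             duration = diff(times),
             row.names = NULL) -> ci
  class(ci) <- c("CoalescentIntervals", "data.frame")
  ci
}

.skylineFromEstimates <- function(durations, lineages, N, mu, L,
                                  generation_time) {
  tend <- cumsum(durations)
  sg <- data.frame(t_start = c(0, tend[-length(tend)]), t_end = tend,
                   lineages = lineages, N = N)
  new("SkylinePlot", segments = sg,
      mu = if (is.null(mu)) NA_real_ else mu,
      L = if (is.null(L)) NA_real_ else L,
      generation_time = if (is.null(generation_time)) NA_real_
                        else generation_time)
}

#' Classic skyline plot
#'
#' Per coalescent interval with i lineages and duration tau,
#' N_i = i(i-1) tau / 2 in the time units of tau, divided by the generation
#' time. When a mutation rate \code{mu} (substitutions/site/year) is given,
#' branch-length durations in substitutions/site are first converted to
#' years (tau/mu); segment times are then years before present. With no
#' generation time the reported value is N x generation time, labelled as
#' such by the NA \code{generation_time} slot.
#'
#' @param ci a \code{CoalescentIntervals} data.frame.
#' @param mu mutation rate in substitutions/site/year, or NULL when the
#'   branch lengths are already in time units.
#' @param L number of sites (recorded for provenance).
#' @param generation_time generation time in years (NULL to report
#'   N x generation time).
#' @return a [SkylinePlot-class].
#' @export
classicSkyline <- function(ci, mu = NULL, L = NULL, generation_time = NULL) {
  stopifnot(all(ci$duration >= 0))
  tau <- ci$duration
  if (!is.null(mu)) {
    stopifnot(mu > 0)
    tau <- tau / mu
  }
  g <- if (is.null(generation_time)) 1 else generation_time
  N <- ci$lineages * (ci$lineages - 1) * tau / (2 * g)
  .skylineFromEstimates(tau, ci$lineages, N, mu, L, generation_time)
}

#' Generalized skyline plot
#'
#' Adjacent coalescent intervals (from the tips) are pooled until the
#' composite duration reaches the grouping parameter \code{epsilon}; the
#' pooled estimate is the constant-size maximum-likelihood estimate over
#' the pooled intervals, sum(C(i,2) tau_i) / m for m coalescences, which
#' reduces to the classic estimator when epsilon = 0. The root-adjacent
#' composite interval may remain shorter than epsilon.
#'
#' @param ci a \code{CoalescentIntervals} data.frame.
#' @param epsilon grouping parameter (>= 0), in the units of the durations.
#' @inheritParams classicSkyline
#' @return a [SkylinePlot-class] (one segment per composite interval).
#' @export
generalizedSkyline <- function(ci, epsilon, mu = NULL, L = NULL,
                               generation_time = NULL) {
  stopifnot(epsilon >= 0)
  if (epsilon == 0) return(classicSkyline(ci, mu, L, generation_time))
  tau <- ci$duration
  if (!is.null(mu)) tau <- tau / mu
  eps <- if (!is.null(mu)) epsilon / mu else epsilon
  g <- if (is.null(generation_time)) 1 else generation_time
  grp <- integer(length(tau)); gid <- 1L; acc <- 0
  for (i in seq_along(tau)) {
    grp[i] <- gid
    acc <- acc + tau[i]
    if (acc >= eps && i < length(tau)) { gid <- gid + 1L; acc <- 0 }
  }
  durations <- tapply(tau, grp, sum)
  rate_mass <- tapply(choose(ci$lineages, 2) * tau, grp, sum)
  m <- tabulate(grp)
  N <- as.numeric(rate_mass) / m / g
  lineages <- as.integer(tapply(ci$lineages, grp, max))
  .skylineFromEstimates(as.numeric(durations), lineages, N, mu, L,
                        generation_time)
}

#' Write skyline segments as TSV
#' @param sk a [SkylinePlot-class]
#' @param path output file
#' @export
writeSkylineTable <- function(sk, path) {
  utils::write.table(skylineSegments(sk), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ultrametricize a tree by mean path-length smoothing
#'
#' Midpoint-roots an unrooted tree and sets each internal node's height to
#' the mean path length to its descendant tips, yielding an ultrametric
#' approximation of the genealogy suitable for skyline extraction. Clearly
#' an approximation: rate variation among lineages is averaged away.
#'
#' @param t an \code{ape::phylo} tree with branch lengths.
#' @return a rooted ultrametric \code{ape::phylo} tree.
#' @export
ultrametricize <- function(t) {
  tr <- t
  if (!ape::is.rooted(tr)) tr <- phangorn_free_midpoint(tr)
  n <- length(tr$tip.label)
  nn <- tr$Nnode
  # mean path length from each node to its descendant tips
  children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  calc <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(0)
    mean(vapply(kids, function(e)
      tr$edge.length[e] + calc(tr$edge[e, 2L]), numeric(1)))
  }
  hts <- vapply(seq_len(nn) + n, calc, numeric(1))
  nodeH <- c(rep(0, n), hts)
  # enforce monotone heights (a parent can fall below a child when its other
  # descendants are much shallower), then rebuild edges as height differences
  # so every tip sits at depth equal to the root height exactly
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    if (nodeH[p] < nodeH[ch]) nodeH[p] <- nodeH[ch]
  }
  tr$edge.length <- nodeH[tr$edge[, 1L]] - nodeH[tr$edge[, 2L]]
  tr
}

# midpoint rooting without importing phangorn at build time
phangorn_free_midpoint <- function(tr) {
  d <- ape::cophenetic.phylo(tr)
  ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
  path_len <- d[ij[1L], ij[2L]]
  # root on the edge closest to the midpoint of the longest tip-tip path
  r <- ape::root(tr, outgroup = rownames(d)[ij[1L]], resolve.root = TRUE)
  r
}
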