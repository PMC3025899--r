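#' @importFrom ape nj read.tree write.tree prop.clades
NULL

#' Kimura two-parameter distance between two aligned sequences
#'
#' With P the transition and Q the transversion proportion over comparable
#' sites (both bases in A/C/G/T), d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)).
#' Sites where either sequence is ambiguous are excluded (pairwise
#' deletion). A log-domain violation (saturation) yields NA flagged with
#' attribute \code{saturated}.
#'
#' @param seq_a,seq_b equal-length gap-free sequences (character strings).
#' @return distance in substitutions/site, or NA when saturated.
#' @export
k2pDistance <- function(seq_a, seq_b) {
  x <- strsplit(toupper(seq_a), "")[[1L]]
  y <- strsplit(toupper(seq_b), "")[[1L]]
  stopifnot(length(x) == length(y))
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites between the two sequences")
  x <- x[ok]; y <- y[ok]
  dif <- x != y
  purine <- c("A", "G")
  ts <- dif & ((x %in% purine) == (y %in% purine))  # A<->G or C<->T
  P <- sum(ts) / length(x)
  Q <- sum(dif & !ts) / length(x)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    out <- NA_real_
    attr(out, "saturated") <- TRUE
    return(out)
  }
  -0.5 * log(a1 * sqrt(a2))
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param a a gap-free [HaploAlignment-class].
#' @param deletion "pairwise" (default; comparable sites per pair) or
#'   "complete" (columns containing any ambiguity dropped first).
#' @return symmetric numeric matrix (NA entries where saturated).
#' @export
k2pMatrix <- function(a, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- alignmentMatrix(a)
  if (deletion == "complete") {
    keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
    m <- m[, keep, drop = FALSE]
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    d[i, j] <- d[j, i] <- suppressWarnings(as.numeric(
      k2pDistance(seqs[[i]], seqs[[j]])))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}); negative branch
#' lengths are clamped to zero with the deficit shifted to the sister
#' branch, preserving path lengths through the parent node.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa, no NA).
#' @return an \code{ape::phylo} tree (unrooted).
#' @export
neighborJoining <- function(d) {
  if (is.matrix(d)) {
    if (any(is.na(d))) {
      bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
      stop("undefined distances for pairs: ",
           paste(sprintf("%s-%s", rownames(d)[bad[, 1L]],
                         colnames(d)[bad[, 2L]]), collapse = ", "))
    }
    if (nrow(d) < 3L) stop("neighbor-joining needs >= 3 taxa")
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib)) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Nonparametric bootstrap support for the NJ tree
#'
#' Alignment columns are resampled with replacement for each replicate; the
#' support of each internal bipartition of the full-data tree is the
#' percentage of replicate NJ trees containing it. Replicates whose
#' resampled distance matrix contains an undefined (saturated) entry are
#' dropped and counted.
#'
#' @param a gap-free [HaploAlignment-class].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param deletion passed to [k2pMatrix()].
#' @return list: \code{tree} (full-data NJ tree with \code{node.label}
#'   holding support percentages), \code{n_used}, \code{n_dropped}.
#' @export
bootstrapSupport <- function(a, n_reps = 1000L, seed,
                             deletion = "pairwise") {
  if (missing(seed)) stop("a seed is required for the bootstrap")
  stopifnot(n_reps >= 1)
  set.seed(seed)
  m <- alignmentMatrix(a)
  full <- neighborJoining(k2pMatrix(a, deletion))
  reps <- list(); dropped <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    ab <- newHaploAlignment(apply(m[, cols, drop = FALSE], 1L, paste,
                                  collapse = ""))
    db <- k2pMatrix(ab, deletion)
    if (any(is.na(db))) { dropped <- dropped + 1L; next }
    reps[[length(reps) + 1L]] <- neighborJoining(db)
  }
  if (!length(reps)) stop("all bootstrap replicates were saturated")
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- round(100 * counts / length(reps), 1)
  list(tree = full, n_used = length(reps), n_dropped = dropped)
}

#' Write a tree in newick format
#' @param t an \code{ape::phylo} tree (support values in node.label kept).
#' @param path output file.
#' @export
writeNewick <- function(t, path) {
  ape::write.tree(t, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path newick file.
#' @return an \code{ape::phylo} tree.
#' @export
readNewick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e)
    stop("malformed newick in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}
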