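#' Pairwise mutational-step matrix between haplotypes
#'
#' Entry (i, j) counts the sites at which haplotypes i and j carry
#' differing, unambiguous bases (N-bearing site pairs excluded).
#'
#' @param t a [HaplotypeTable-class] with sequences.
#' @return symmetric integer matrix with haplotype dimnames.
#' @export
stepMatrix <- function(t) {
  stopifnot(is(t, "HaplotypeTable"))
  sq <- haploSequences(t)
  if (!length(sq))
    stop("this haplotype table carries no sequences; rebuild it with ",
         "collapseHaplotypes() on the alignment to compute mutational steps")
  m <- do.call(rbind, strsplit(sq, ""))
  rownames(m) <- names(sq)
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    ok <- m[i, ] != "N" & m[j, ] != "N"
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  d
}

# deterministic edge ordering: (weight, lexicographic endpoint pair)
.sortedEdgeList <- function(d) {
  ids <- rownames(d)
  k <- length(ids)
  eu <- character(0); ev <- character(0); ew <- integer(0)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- ids[i]; b <- ids[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    eu <- c(eu, a); ev <- c(ev, b); ew <- c(ew, d[i, j])
  }
  e <- data.frame(u = eu, v = ev, steps = ew, stringsAsFactors = FALSE)
  e[order(e$steps, e$u, e$v), , drop = FALSE]
}

#' Minimum spanning network over haplotypes
#'
#' Builds a minimum spanning tree by Kruskal's algorithm with deterministic
#' tie-breaking (weight, then lexicographic endpoint pair), then adds every
#' non-tree pair whose direct distance equals the minimax path weight
#' between its endpoints as an "alternative" co-minimal connection. This is
#' the MINSPNET behaviour: ties yield loops, and the emitted network is
#' independent of input order.
#'
#' @param d symmetric step matrix (from [stepMatrix()]).
#' @param counts optional haplotype x population count matrix to attach.
#' @return a [HaplotypeNetwork-class].
#' @export
minimumSpanningNetwork <- function(d, counts = NULL) {
  ids <- rownames(d)
  stopifnot(!is.null(ids), identical(ids, colnames(d)))
  if (is.null(counts))
    counts <- matrix(1L, nrow = length(ids), ncol = 1L,
                     dimnames = list(ids, "pop1"))
  counts <- counts[ids, , drop = FALSE]
  if (length(ids) == 1L) {
    return(new("HaplotypeNetwork", nodes = ids, counts = counts,
               edges = data.frame(u = character(0), v = character(0),
                                  steps = integer(0), edge_class = character(0),
                                  stringsAsFactors = FALSE)))
  }
  el <- .sortedEdgeList(d)
  comp <- stats::setNames(ids, ids)              # union-find, parent pointers
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  mst <- logical(nrow(el))
  for (r in seq_len(nrow(el))) {
    ru <- find(el$u[r]); rv <- find(el$v[r])
    if (ru != rv) {
      comp[[ru]] <- rv
      mst[r] <- TRUE
    }
  }
  tree <- el[mst, , drop = FALSE]
  mm <- .minimaxMatrix(ids, tree)
  alt <- el[!mst & el$steps == mm[cbind(el$u, el$v)], , drop = FALSE]
  edges <- rbind(cbind(tree, edge_class = "mst"),
                 if (nrow(alt)) cbind(alt, edge_class = "alternative"))
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  new("HaplotypeNetwork", nodes = ids, counts = counts, edges = edges)
}

# minimax (bottleneck) path weights over a spanning tree
.minimaxMatrix <- function(ids, tree) {
  k <- length(ids)
  mm <- matrix(Inf, k, k, dimnames = list(ids, ids))
  diag(mm) <- 0
  adj <- stats::setNames(vector("list", k), ids)
  for (r in seq_len(nrow(tree))) {
    adj[[tree$u[r]]] <- rbind(adj[[tree$u[r]]],
                              data.frame(to = tree$v[r], w = tree$steps[r]))
    adj[[tree$v[r]]] <- rbind(adj[[tree$v[r]]],
                              data.frame(to = tree$u[r], w = tree$steps[r]))
  }
  for (src in ids) {   # DFS from each source over the unique tree paths
    stack <- list(list(node = src, from = "", mx = 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      mm[src, top$node] <- top$mx
      nb <- adj[[top$node]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        if (nb$to[r] != top$from)
          stack[[length(stack) + 1L]] <-
            list(node = nb$to[r], from = top$node, mx = max(top$mx, nb$w[r]))
      }
    }
  }
  mm
}

#' Export a haplotype network as an edge-list TSV
#'
#' Columns u, v, steps, edge_class; rows in lexicographic (u, v) order so the
#' file is deterministic.
#'
#' @param nw a [HaplotypeNetwork-class].
#' @param path output file.
#' @export
exportNetwork <- function(nw, path) {
  stopifnot(is(nw, "HaplotypeNetwork"))
  e <- networkEdges(nw)
  e <- e[order(e$u, e$v), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [exportNetwork()]
#'
#' @param path edge-list TSV.
#' @param counts optional haplotype x population counts to attach.
#' @return a [HaplotypeNetwork-class].
#' @export
readNetwork <- function(path, counts = NULL) {
  e <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE)
  nodes <- sort(unique(c(e$u, e$v)))
  if (is.null(counts))
    counts <- matrix(1L, nrow = length(nodes), ncol = 1L,
                     dimnames = list(nodes, "pop1"))
  new("HaplotypeNetwork", nodes = nodes, counts = counts, edges = e)
}
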