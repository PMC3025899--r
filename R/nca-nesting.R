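#' Build the hierarchical nesting design of a haplotype network
#'
#' Implements the classic nesting rules: starting at the tips of the
#' cladogram, each tip unit is united with the interior unit one mutational
#' connection away into a 1-step clade; the formed clades are pruned and the
#' procedure repeats on the interior residue until all units are placed.
#' The same rules are then applied to the 1-step clades to form 2-step
#' clades, and so on, stopping when a level consists of a single clade (the
#' total cladogram).
#'
#' Reticulation loops are broken before nesting at the edge joining the two
#' lowest-frequency haplotypes (frequency criterion); removed edges are
#' recorded. A unit stranded alone after a pruning pass is attached to the
#' adjacent nested category of smallest size, ties broken toward the clade
#' whose connecting unit was an interior (anchor) unit, then by clade id.
#'
#' @param nw a [HaplotypeNetwork-class].
#' @return a [NestingDesign-class].
#' @export
buildNesting <- function(nw) {
  stopifnot(is(nw, "HaplotypeNetwork"))
  ids <- nw@nodes
  freq <- rowSums(nw@counts)[ids]
  tree <- .breakLoops(networkEdges(nw), ids, freq)
  broken <- tree$broken; tree <- tree$tree

  clades <- data.frame(clade_id = character(0), level = integer(0),
                       status = character(0), parent = character(0),
                       stringsAsFactors = FALSE)
  members <- list(); haplos <- list()
  units <- ids
  unitHap <- stats::setNames(as.list(ids), ids)  # unit -> haplotype ids
  uedges <- tree[, c("u", "v")]
  level <- 0L
  repeat {
    level <- level + 1L
    nest <- .nestOneLevel(units, uedges)
    new_ids <- if (length(nest$clades) == 1L) "total" else
      sprintf("%d-%d", level, seq_along(nest$clades))
    for (k in seq_along(nest$clades)) {
      cid <- new_ids[k]
      members[[cid]] <- nest$clades[[k]]
      haplos[[cid]] <- unlist(unitHap[nest$clades[[k]]], use.names = FALSE)
    }
    # record parents of the units just nested
    parent_of <- stats::setNames(rep(new_ids, lengths(nest$clades)),
                                 unlist(nest$clades))
    if (level == 1L) {
      clades <- rbind(clades, data.frame(
        clade_id = ids, level = 0L, status = NA_character_,
        parent = parent_of[ids], stringsAsFactors = FALSE))
    } else {
      clades$parent[match(units, clades$clade_id)] <- parent_of[units]
    }
    clades <- rbind(clades, data.frame(
      clade_id = new_ids, level = level, status = NA_character_,
      parent = NA_character_, stringsAsFactors = FALSE))
    if (length(nest$clades) == 1L) break
    # lift the tree to the new units
    unitHap <- stats::setNames(lapply(new_ids, function(cid) haplos[[cid]]),
                               new_ids)
    units <- new_ids
    uedges <- .liftEdges(tree, unitHap)
    if (length(units) == 1L) { # safety; cannot normally trigger
      members[["total"]] <- units; haplos[["total"]] <- unitHap[[1L]]
      break
    }
  }
  des <- new("NestingDesign", clades = clades, members = members,
             haplotypes = haplos, tree = tree,
             network = networkEdges(nw)[, c("u", "v", "steps")],
             broken = broken)
  # tip/interior status for every clade with a parent, per connection count
  des@clades$status <- vapply(seq_len(nrow(clades)), function(i) {
    if (is.na(clades$parent[i])) "interior"
    else classifyInteriorTip(des, clades$clade_id[i])
  }, character(1))
  des
}

# remove cycle edges at the lowest-frequency haplotype pairs until a tree
.breakLoops <- function(edges, ids, freq) {
  e <- edges[, c("u", "v", "steps")]
  broken <- e[0, ]
  while (nrow(e) > length(ids) - 1L) {
    on_cycle <- vapply(seq_len(nrow(e)), function(r)
      .isConnected(ids, e[-r, , drop = FALSE]), logical(1))
    cand <- which(on_cycle)
    sc_lo <- pmin(freq[e$u[cand]], freq[e$v[cand]])
    sc_sum <- freq[e$u[cand]] + freq[e$v[cand]]
    ord <- order(sc_sum, sc_lo, e$u[cand], e$v[cand])
    drop <- cand[ord[1L]]
    broken <- rbind(broken, e[drop, ])
    e <- e[-drop, , drop = FALSE]
  }
  rownames(e) <- NULL; rownames(broken) <- NULL
  list(tree = e, broken = broken)
}

.isConnected <- function(ids, edges) {
  if (length(ids) <= 1L) return(TRUE)
  comp <- stats::setNames(ids, ids)
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  for (r in seq_len(nrow(edges))) {
    ru <- find(edges$u[r]); rv <- find(edges$v[r])
    if (ru != rv) comp[[ru]] <- rv
  }
  length(unique(vapply(ids, find, character(1)))) == 1L
}

# one nesting pass: unite tips with their interior neighbours, prune, and
# repeat on the residue; each connected component of the residue is treated
# separately (pruning can disconnect it), and stranded singletons attach to
# the smallest adjacent clade
.nestOneLevel <- function(units, uedges) {
  remaining <- units
  clades <- list(); role <- character(0)  # unit -> "interior"/"tip"
  cladeOf <- integer(0)
  induced <- function(set) {
    keep <- uedges$u %in% set & uedges$v %in% set
    uedges[keep, , drop = FALSE]
  }
  components <- function(set, ed) {
    comp <- stats::setNames(set, set)
    find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
    for (r in seq_len(nrow(ed))) {
      ru <- find(ed$u[r]); rv <- find(ed$v[r])
      if (ru != rv) comp[[ru]] <- rv
    }
    split(set, vapply(set, find, character(1)))
  }
  attachStranded <- function(un) {
    nb <- unique(c(uedges$v[uedges$u == un], uedges$u[uedges$v == un]))
    nb <- nb[nb %in% names(cladeOf)]
    if (!length(nb)) {                  # single-unit network
      clades[[length(clades) + 1L]] <<- un
      role[un] <<- "interior"; cladeOf[un] <<- length(clades)
      return(invisible())
    }
    ci <- cladeOf[nb]
    sz <- lengths(clades)[ci]
    pref <- ifelse(role[nb] == "interior", 0L, 1L)
    tgt <- ci[order(sz, pref, ci)[1L]]
    clades[[tgt]] <<- c(clades[[tgt]], un)
    role[un] <<- "tip"; cladeOf[un] <<- tgt
  }
  while (length(remaining)) {
    ed <- induced(remaining)
    comps <- components(remaining, ed)
    assigned <- character(0)
    for (comp in comps) {
      if (length(comp) == 1L) {
        attachStranded(comp)
        assigned <- c(assigned, comp)
        next
      }
      ced <- induced(comp)
      if (length(comp) == 2L) {
        clades[[length(clades) + 1L]] <- comp
        role[comp] <- "interior"; cladeOf[comp] <- length(clades)
        assigned <- c(assigned, comp)
        next
      }
      deg <- stats::setNames(integer(length(comp)), comp)
      for (r in seq_len(nrow(ced))) {
        deg[ced$u[r]] <- deg[ced$u[r]] + 1L
        deg[ced$v[r]] <- deg[ced$v[r]] + 1L
      }
      tips <- names(deg)[deg == 1L]
      if (!length(tips)) {              # cycle residue: one clade
        clades[[length(clades) + 1L]] <- comp
        role[comp] <- "interior"; cladeOf[comp] <- length(clades)
        assigned <- c(assigned, comp)
        next
      }
      anchors <- vapply(tips, function(tp) {
        nb <- c(ced$v[ced$u == tp], ced$u[ced$v == tp])
        nb[1L]
      }, character(1))
      for (an in unique(anchors)) {
        grp <- c(an, tips[anchors == an])
        clades[[length(clades) + 1L]] <- grp
        role[an] <- "interior"; role[tips[anchors == an]] <- "tip"
        cladeOf[grp] <- length(clades)
      }
      assigned <- c(assigned, unlist(clades[unique(cladeOf[tips])]))
    }
    remaining <- setdiff(remaining, c(assigned, unlist(clades)))
  }
  list(clades = clades, role = role)
}

# edges between new units, induced by the haplotype-level tree
.liftEdges <- function(tree, unitHap) {
  un <- names(unitHap)
  of <- stats::setNames(rep(un, lengths(unitHap)), unlist(unitHap))
  uu <- of[tree$u]; vv <- of[tree$v]
  keep <- uu != vv
  unique(data.frame(u = pmin(uu[keep], vv[keep]),
                    v = pmax(uu[keep], vv[keep]),
                    stringsAsFactors = FALSE))
}

#' Tip/interior status of a clade within its nesting clade
#'
#' A clade is a tip when exactly one mutational connection leaves it toward
#' the other member clades of its nesting clade; otherwise it is interior.
#' Connections are counted on the full network, loops included (members of
#' a reticulation cycle are therefore all interior).
#'
#' @param design a [NestingDesign-class].
#' @param clade_id clade (or haplotype) identifier.
#' @return "tip" or "interior".
#' @export
classifyInteriorTip <- function(design, clade_id) {
  cl <- design@clades
  row <- match(clade_id, cl$clade_id)
  if (is.na(row)) stop("unknown clade id: ", clade_id)
  parent <- cl$parent[row]
  if (is.na(parent)) return("interior")
  sibs <- setdiff(design@members[[parent]], clade_id)
  if (!length(sibs)) return("interior")
  mine <- .hapsOf(design, clade_id)
  theirs <- unlist(lapply(sibs, .hapsOf, design = design), use.names = FALSE)
  tr <- if (nrow(design@network)) design@network else design@tree
  conn <- sum((tr$u %in% mine & tr$v %in% theirs) |
              (tr$v %in% mine & tr$u %in% theirs))
  if (conn == 1L) "tip" else "interior"
}

.hapsOf <- function(design, unit) {
  if (unit %in% names(design@haplotypes)) design@haplotypes[[unit]] else unit
}

#' Per-clade composition counts and percentages by population
#'
#' @param design a [NestingDesign-class].
#' @param t a [HaplotypeTable-class].
#' @return data.frame: clade_id, level, one column per population, n and
#'   percentage of the total sample.
#' @export
cladeCompositionTable <- function(design, t) {
  cnt <- haploCounts(t)
  ntot <- sum(cnt)
  cl <- design@clades[design@clades$level >= 1L, , drop = FALSE]
  rows <- lapply(cl$clade_id, function(cid) {
    hs <- intersect(.hapsOf(design, cid), rownames(cnt))
    byPop <- colSums(cnt[hs, , drop = FALSE])
    data.frame(clade_id = cid, level = cl$level[match(cid, cl$clade_id)],
               t(byPop), n = sum(byPop),
               percent = round(100 * sum(byPop) / ntot, 1),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
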