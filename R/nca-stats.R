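# Geographic engine for nested clade analysis.
#
# Individuals are carried as per-population count vectors; geographic
# centres are count-weighted means of the populations' unit vectors on the
# sphere, renormalised (well-defined at all longitudes), and spreads are
# count-weighted mean great-circle distances from the centre.

.popUnitVectors <- function(m) {
  st <- m@sites
  r <- pi / 180
  cbind(x = cos(st$lat * r) * cos(st$lon * r),
        y = cos(st$lat * r) * sin(st$lon * r),
        z = sin(st$lat * r)) -> uv
  rownames(uv) <- st$population
  uv
}

# centre of a weighted set of populations -> c(lat, lon)
.geoCentre <- function(w, uv) {
  v <- colSums(uv[names(w), , drop = FALSE] * w) / sum(w)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(lat = NA_real_, lon = NA_real_))
  v <- v / nv
  c(lat = asin(v[["z"]]) * 180 / pi,
    lon = atan2(v[["y"]], v[["x"]]) * 180 / pi)
}

# weighted mean distance of individuals (weights by population) from centre
.geoSpread <- function(w, centre, m) {
  if (any(is.na(centre))) return(NA_real_)
  st <- m@sites
  idx <- match(names(w), st$population)
  d <- greatCircleKm(st$lat[idx], st$lon[idx],
                     rep(centre[["lat"]], length(idx)),
                     rep(centre[["lon"]], length(idx)))
  sum(w * d) / sum(w)
}

# counts-by-population for an arbitrary unit (clade id or haplotype id)
.unitPopCounts <- function(design, unit, cnt) {
  hs <- intersect(.hapsOf(design, unit), rownames(cnt))
  colSums(cnt[hs, , drop = FALSE])
}

# observed Dc/Dn (+ I-T contrasts) for the members of one nesting clade
.ncaObserved <- function(wlist, status, m, uv) {
  wP <- Reduce(`+`, wlist)
  cP <- .geoCentre(wP, uv)
  k <- length(wlist)
  Dc <- Dn <- numeric(k)
  for (i in seq_len(k)) {
    w <- wlist[[i]]; w <- w[w > 0]
    if (!length(w)) { Dc[i] <- Dn[i] <- NA_real_; next }
    Dc[i] <- .geoSpread(w, .geoCentre(w, uv), m)
    Dn[i] <- .geoSpread(w, cP, m)
  }
  n <- vapply(wlist, sum, numeric(1))
  itDc <- itDn <- NA_real_
  ii <- status == "interior"; tt <- status == "tip"
  if (any(ii) && any(tt)) {
    itDc <- sum(n[ii] * Dc[ii]) / sum(n[ii]) - sum(n[tt] * Dc[tt]) / sum(n[tt])
    itDn <- sum(n[ii] * Dn[ii]) / sum(n[ii]) - sum(n[tt] * Dn[tt]) / sum(n[tt])
  }
  list(Dc = Dc, Dn = Dn, itDc = itDc, itDn = itDn, n = n)
}

#' Clade (Dc) and nested clade (Dn) distances
#'
#' For every nesting clade, each member unit's clade distance Dc (the
#' count-weighted mean great-circle distance of its individuals from the
#' unit's own geographic centre) and nested clade distance Dn (the same
#' individuals measured from the nesting clade's centre) are computed, in
#' kilometres.
#'
#' @param design a [NestingDesign-class].
#' @param t a [HaplotypeTable-class] (counts used).
#' @param m a [PopulationMap-class] georeferencing every population.
#' @return data.frame: nesting_clade, unit, status, n, Dc, Dn.
#' @export
cladeDistances <- function(design, t, m) {
  ps <- permutationSignificance(design, t, m, n_perm = 0L, seed = 1L)
  ps$units[, c("nesting_clade", "unit", "status", "n", "Dc", "Dn")]
}

#' Permutation significance of the NCA distance statistics
#'
#' Within each nesting clade, individuals' population labels are permuted
#' among the member units, holding unit sample sizes fixed. For every unit
#' and for the interior-minus-tip contrasts, \code{p_small} is the
#' proportion of permuted statistics less than or equal to the observed
#' value and \code{p_large} the proportion greater than or equal to it, in
#' both cases counting the observed arrangement (so p > 0). Nesting clades
#' with a single member are reported with NA p-values.
#'
#' @param design a [NestingDesign-class].
#' @param t a [HaplotypeTable-class].
#' @param m a [PopulationMap-class].
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param exact if TRUE, enumerate all permutations of the pooled label
#'   vector instead of sampling (only sensible for tiny nesting clades);
#'   p-values are then exact proportions over all arrangements.
#' @return list with data.frames \code{units} (per-unit Dc/Dn and p-values)
#'   and \code{contrasts} (interior-minus-tip contrasts and p-values).
#' @export
permutationSignificance <- function(design, t, m, n_perm = 10000L, seed,
                                    exact = FALSE) {
  stopifnot(is(design, "NestingDesign"), is(t, "HaplotypeTable"),
            is(m, "PopulationMap"))
  if (missing(seed)) stop("a seed is required for the permutation test")
  set.seed(seed)
  cnt <- haploCounts(t)
  uv <- .popUnitVectors(m)
  nests <- design@clades$clade_id[design@clades$level >= 1L]
  unit_rows <- list(); contrast_rows <- list()
  for (nc in nests) {
    mem <- design@members[[nc]]
    wlist <- lapply(mem, .unitPopCounts, design = design, cnt = cnt)
    status <- vapply(mem, function(u) classifyInteriorTip(design, u),
                     character(1))
    obs <- .ncaObserved(wlist, status, m, uv)
    k <- length(mem)
    pSc <- pLc <- pSn <- pLn <- rep(NA_real_, k)
    itp <- c(ps_dc = NA_real_, pl_dc = NA_real_,
             ps_dn = NA_real_, pl_dn = NA_real_)
    if (k >= 2L && n_perm > 0L) {
      pools <- rep(names(wlist[[1L]]), Reduce(`+`, wlist))
      sizes <- obs$n
      perms <- if (exact) .allPermutations(pools) else
        replicate(n_perm, sample(pools), simplify = FALSE)
      cntSc <- cntLc <- cntSn <- cntLn <- rep(0L, k)
      it_cnt <- c(0L, 0L, 0L, 0L)
      pops <- colnames(cnt)
      for (pp in perms) {
        off <- 0L
        wperm <- vector("list", k)
        for (i in seq_len(k)) {
          lab <- pp[seq.int(off + 1L, off + sizes[i])]
          off <- off + sizes[i]
          wperm[[i]] <- stats::setNames(
            tabulate(match(lab, pops), nbins = length(pops)), pops)
        }
        pm <- .ncaObserved(wperm, status, m, uv)
        cntSc <- cntSc + (pm$Dc <= obs$Dc + 1e-9)
        cntLc <- cntLc + (pm$Dc >= obs$Dc - 1e-9)
        cntSn <- cntSn + (pm$Dn <= obs$Dn + 1e-9)
        cntLn <- cntLn + (pm$Dn >= obs$Dn - 1e-9)
        if (!is.na(obs$itDc)) {
          it_cnt[1L] <- it_cnt[1L] + (pm$itDc <= obs$itDc + 1e-9)
          it_cnt[2L] <- it_cnt[2L] + (pm$itDc >= obs$itDc - 1e-9)
          it_cnt[3L] <- it_cnt[3L] + (pm$itDn <= obs$itDn + 1e-9)
          it_cnt[4L] <- it_cnt[4L] + (pm$itDn >= obs$itDn - 1e-9)
        }
      }
      np <- length(perms)
      if (exact) {  # observed arrangement is one of the enumerated ones
        pSc <- cntSc / np; pLc <- cntLc / np
        pSn <- cntSn / np; pLn <- cntLn / np
        if (!is.na(obs$itDc)) itp[] <- it_cnt / np
      } else {
        pSc <- (cntSc + 1L) / (np + 1L); pLc <- (cntLc + 1L) / (np + 1L)
        pSn <- (cntSn + 1L) / (np + 1L); pLn <- (cntLn + 1L) / (np + 1L)
        if (!is.na(obs$itDc)) itp[] <- (it_cnt + 1L) / (np + 1L)
      }
    }
    unit_rows[[nc]] <- data.frame(
      nesting_clade = nc, unit = mem, status = status, n = obs$n,
      Dc = obs$Dc, Dn = obs$Dn,
      p_small_Dc = pSc, p_large_Dc = pLc,
      p_small_Dn = pSn, p_large_Dn = pLn,
      stringsAsFactors = FALSE)
    contrast_rows[[nc]] <- data.frame(
      nesting_clade = nc, it_Dc = obs$itDc, it_Dn = obs$itDn,
      p_small_it_Dc = itp[[1L]], p_large_it_Dc = itp[[2L]],
      p_small_it_Dn = itp[[3L]], p_large_it_Dn = itp[[4L]],
      stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, unit_rows); rownames(units) <- NULL
  contrasts <- do.call(rbind, contrast_rows); rownames(contrasts) <- NULL
  list(units = units, contrasts = contrasts)
}

.allPermutations <- function(x) {
  n <- length(x)
  if (n > 9L) stop("exact enumeration limited to 9 individuals")
  idx <- .permIndices(n)
  lapply(seq_len(nrow(idx)), function(i) x[idx[i, ]])
}

.permIndices <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permIndices(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

#' Nested contingency test of clade-by-population association
#'
#' For every nesting clade with at least two member units and two
#' populations represented, the Pearson chi-square statistic of the member
#' unit x population count table is compared with its permutation null
#' (population labels permuted among the nesting clade's individuals,
#' member sizes held fixed); p is the proportion of permuted statistics
#' greater than or equal to the observed one, counting the observed table.
#'
#' @inheritParams permutationSignificance
#' @return data.frame: nesting_clade, chi_square, p_perm, n_perm, applicable.
#' @export
nestedContingencyTest <- function(design, t, n_perm = 10000L, seed) {
  if (missing(seed)) stop("a seed is required for the permutation test")
  set.seed(seed)
  cnt <- haploCounts(t)
  pops <- colnames(cnt)
  nests <- design@clades$clade_id[design@clades$level >= 1L]
  rows <- lapply(nests, function(nc) {
    mem <- design@members[[nc]]
    tab <- do.call(rbind, lapply(mem, .unitPopCounts, design = design,
                                 cnt = cnt))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      return(data.frame(nesting_clade = nc, chi_square = NA_real_,
                        p_perm = NA_real_, n_perm = n_perm,
                        applicable = FALSE, stringsAsFactors = FALSE))
    obs <- .chisqStat(tab)
    sizes <- rowSums(tab)
    pool <- rep(colnames(tab), colSums(tab))
    ge <- 0L
    for (b in seq_len(n_perm)) {
      lab <- sample(pool)
      off <- 0L
      ptab <- matrix(0L, nrow(tab), ncol(tab), dimnames = dimnames(tab))
      for (i in seq_len(nrow(tab))) {
        ll <- lab[seq.int(off + 1L, off + sizes[i])]
        off <- off + sizes[i]
        ptab[i, ] <- tabulate(match(ll, colnames(tab)), ncol(tab))
      }
      if (.chisqStat(ptab) >= obs - 1e-9) ge <- ge + 1L
    }
    data.frame(nesting_clade = nc, chi_square = obs,
               p_perm = (ge + 1L) / (n_perm + 1L), n_perm = n_perm,
               applicable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

.chisqStat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- E > 0
  sum((tab[ok] - E[ok])^2 / E[ok])
}
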