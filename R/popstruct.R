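#' Hudson-Slatkin-Maddison FST from sequence data
#'
#' FST = 1 - Hw/Hb, where Hw is the unweighted mean of the two
#' within-population mean pairwise differences and Hb the mean
#' between-population pairwise difference (differences counted per
#' comparable site, N-bearing site pairs excluded per pair). This is the
#' standard estimator for sequence data from mean pairwise differences.
#' Negative estimates are clamped to 0 and flagged via the "clamped"
#' attribute; Hb = 0 (no divergence at all) yields NA.
#'
#' @param seqs_a,seqs_b character vectors of aligned, gap-free sequences
#'   (>= 2 each).
#' @return FST in [0, 1] (or NA when undefined).
#' @export
hudsonFst <- function(seqs_a, seqs_b) {
  stopifnot(length(seqs_a) >= 2, length(seqs_b) >= 2)
  ma <- do.call(rbind, strsplit(toupper(seqs_a), ""))
  mb <- do.call(rbind, strsplit(toupper(seqs_b), ""))
  stopifnot(ncol(ma) == ncol(mb))
  hw_a <- .meanPairwise(ma, ma, within = TRUE)
  hw_b <- .meanPairwise(mb, mb, within = TRUE)
  hb <- .meanPairwise(ma, mb, within = FALSE)
  if (hb == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no between-population divergence"
    return(out)
  }
  fst <- 1 - mean(c(hw_a, hw_b)) / hb
  clamped <- fst < 0
  fst <- max(0, fst)
  attr(fst, "clamped") <- clamped
  fst
}

.meanPairwise <- function(mx, my, within) {
  tot <- 0; np <- 0L
  if (within) {
    n <- nrow(mx)
    if (n < 2) return(0)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      pd <- .pairDiff(mx[i, ], mx[j, ])
      if (pd[["len"]] > 0) tot <- tot + pd[["diff"]] / pd[["len"]]
      np <- np + 1L
    }
  } else {
    for (i in seq_len(nrow(mx))) for (j in seq_len(nrow(my))) {
      pd <- .pairDiff(mx[i, ], my[j, ])
      if (pd[["len"]] > 0) tot <- tot + pd[["diff"]] / pd[["len"]]
      np <- np + 1L
    }
  }
  tot / np
}

#' Island-model gene flow from FST
#'
#' Nm = (1 - FST) / (2 FST), from the haploid maternal island-model
#' relationship FST = 1/(1 + 2Nm).
#'
#' @param fst FST value(s) in (0, 1]; 0 maps to Inf (unbounded gene flow).
#' @return Nm (migrants per generation).
#' @export
nmFromFst <- function(fst) {
  if (any(fst > 1, na.rm = TRUE)) stop("FST cannot exceed 1")
  if (any(fst < 0, na.rm = TRUE)) stop("FST cannot be negative")
  ifelse(fst == 0, Inf, (1 - fst) / (2 * fst))
}

#' Pairwise FST and Nm matrices for all populations
#'
#' Populations with fewer than two sequences are excluded with a warning.
#'
#' @param a gap-free [HaploAlignment-class].
#' @param m a [PopulationMap-class].
#' @return list of class \code{FstNmMatrices}: \code{populations},
#'   \code{fst} (symmetric, 0 diagonal), \code{nm} (symmetric, Inf
#'   diagonal).
#' @export
fstNmMatrices <- function(a, m) {
  stopifnot(is(a, "HaploAlignment"), is(m, "PopulationMap"))
  ids <- names(a@seqs)
  pop <- m@samples$population[match(ids, m@samples$sample)]
  sizes <- table(pop)
  elig <- names(sizes)[sizes >= 2]
  if (length(elig) < length(sizes))
    warning("populations excluded (n < 2): ",
            paste(setdiff(names(sizes), elig), collapse = ", "))
  if (length(elig) < 2L)
    stop("need at least two populations with >= 2 sequences")
  elig <- intersect(m@sites$population, elig)   # stable, map order
  k <- length(elig)
  fst <- matrix(0, k, k, dimnames = list(elig, elig))
  seqs <- as.character(a@seqs)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    v <- hudsonFst(seqs[pop == elig[i]], seqs[pop == elig[j]])
    fst[i, j] <- fst[j, i] <- as.numeric(v)
  }
  nm <- suppressWarnings(matrix(nmFromFst(fst), k, k,
                                dimnames = dimnames(fst)))
  diag(nm) <- Inf
  structure(list(populations = elig, fst = fst, nm = nm),
            class = "FstNmMatrices")
}

#' Isolation-by-distance test
#'
#' Pearson correlation between pairwise Nm and pairwise great-circle
#' distance over all population pairs, with significance from a Mantel
#' permutation test (population identities permuted, matrix rows/columns
#' together). Pairs with non-finite Nm are excluded from the correlation.
#' A plain regression F-test p-value is also reported for fidelity with the
#' common "regression against distance" presentation.
#'
#' @param fm result of [fstNmMatrices()].
#' @param m a [PopulationMap-class].
#' @param n_perm number of Mantel permutations.
#' @param seed RNG seed.
#' @param transform "none" or "log-distance" (log10 of km before
#'   correlating).
#' @return list of class \code{IbdResult}: r, abs_r, p_perm (two-sided
#'   Mantel), p_ftest, n_pairs, transform.
#' @export
ibdTest <- function(fm, m, n_perm = 10000L, seed, transform = c("none",
                                                                "log-distance")) {
  transform <- match.arg(transform)
  if (missing(seed)) stop("a seed is required for the Mantel test")
  set.seed(seed)
  pops <- fm$populations
  if (length(pops) < 3L) stop("isolation by distance needs >= 3 populations")
  dm <- populationDistanceMatrix(m)[pops, pops]
  if (transform == "log-distance") {
    dm[dm > 0] <- log10(dm[dm > 0])   # diagonal zeros never enter the test
  }
  nm <- fm$nm
  lower <- lower.tri(nm)
  rFun <- function(perm) {
    x <- nm[lower]
    dperm <- dm[perm, perm]
    y <- dperm[lower]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  r_obs <- rFun(seq_along(pops))
  if (is.na(r_obs)) {
    return(structure(list(r = NA_real_, abs_r = NA_real_, p_perm = NA_real_,
                          p_ftest = NA_real_, n_pairs = sum(lower),
                          transform = transform), class = "IbdResult"))
  }
  ge <- 0L
  for (b in seq_len(n_perm)) {
    rp <- rFun(sample(seq_along(pops)))
    if (!is.na(rp) && abs(rp) >= abs(r_obs) - 1e-12) ge <- ge + 1L
  }
  x <- nm[lower]; y <- dm[lower]; ok <- is.finite(x) & is.finite(y)
  fit <- suppressWarnings(stats::lm(x[ok] ~ y[ok]))
  fp <- tryCatch(suppressWarnings(stats::anova(fit)[["Pr(>F)"]][1L]),
                 error = function(e) NA_real_)
  structure(list(r = r_obs, abs_r = abs(r_obs),
                 p_perm = (ge + 1L) / (n_perm + 1L),
                 p_ftest = fp, n_pairs = sum(ok), transform = transform),
            class = "IbdResult")
}

#' Write the paired Nm/FST matrix in the conventional layout
#'
#' Nm below the diagonal, FST above, one TSV.
#'
#' @param fm result of [fstNmMatrices()].
#' @param path output file.
#' @export
writeFstNmTable <- function(fm, path) {
  k <- length(fm$populations)
  out <- matrix("", k, k, dimnames = list(fm$populations, fm$populations))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) out[i, j] <- sprintf("%.2f", fm$fst[i, j])
    if (i > j) out[i, j] <- sprintf("%.2f", fm$nm[i, j])
  }
  utils::write.table(data.frame(population = rownames(out), out,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
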