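#' Nei's unbiased haplotype diversity
#'
#' h = n(1 - sum p_i^2)/(n - 1), the probability that two sequences drawn
#' without replacement carry different haplotypes, with the small-sample
#' correction n/(n-1).
#'
#' @param counts positive integer haplotype counts, n = sum(counts) >= 2.
#' @return haplotype diversity in [0, 1].
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (length(counts) < 1L || n < 2)
    stop("haplotype diversity undefined for fewer than 2 sequences")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Standard deviation of haplotype diversity (Nei 1987 sampling variance)
#'
#' V(h) = (2/(n(n-1))) * {2(n-2)[sum p^3 - (sum p^2)^2] + sum p^2 - (sum p^2)^2}
#'
#' @inheritParams haplotypeDiversity
#' @return sqrt(V(h)).
#' @export
haplotypeDiversitySD <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity SD undefined for fewer than 2 sequences")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  v <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  sqrt(max(0, v))
}

# pairwise difference count over unambiguous sites, plus comparable length
.pairDiff <- function(x, y) {
  ok <- x != "N" & y != "N"
  c(diff = sum(x[ok] != y[ok]), len = sum(ok))
}

#' Nucleotide diversity per site (pi)
#'
#' Mean pairwise difference over all C(n,2) sequence pairs, divided by the
#' per-pair number of comparable sites (sites where neither sequence is N).
#' Indel columns must already be excluded.
#'
#' @param a gap-free [HaploAlignment-class] with n >= 2.
#' @return nucleotide diversity per site.
#' @export
nucleotideDiversity <- function(a) {
  m <- alignmentMatrix(a)
  n <- nrow(m)
  if (n < 2) stop("nucleotide diversity undefined for fewer than 2 sequences")
  tot <- 0; npairs <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pd <- .pairDiff(m[i, ], m[j, ])
    if (pd["len"] > 0) tot <- tot + pd["diff"] / pd["len"]
    npairs <- npairs + 1L
  }
  unname(tot / npairs)
}

#' Watterson's estimate of the scaled mutation rate, per site
#'
#' theta_w = S / a_n / L with a_n = sum_{i=1}^{n-1} 1/i.
#'
#' @param S number of segregating sites.
#' @param n sample size (>= 2).
#' @param L number of sites (>= 1).
#' @return theta per site.
#' @export
wattersonTheta <- function(S, n, L) {
  stopifnot(n >= 2, L >= 1, S >= 0)
  S / sum(1 / seq_len(n - 1)) / L
}

#' Count segregating sites in a gap-free alignment (N ignored per site)
#' @param a a HaploAlignment
#' @export
segregatingSites <- function(a) {
  m <- alignmentMatrix(a)
  sum(apply(m, 2L, function(col) {
    b <- unique(col[col != "N"])
    length(b) > 1L
  }))
}

#' Per-population and overall diversity summary
#'
#' One row per population (in the order of the population map's site table)
#' plus a pooled "Overall" row. With sequences available, segregating sites,
#' nucleotide diversity and Watterson's theta are included; from a count-only
#' table, n, k, h and the SD of h are reported. Populations with n < 2 are
#' retained with the h fields set to NA.
#'
#' @param t a [HaplotypeTable-class].
#' @param a optional gap-free [HaploAlignment-class] of the individual
#'   sequences (required for S, pi, theta_w).
#' @param m optional [PopulationMap-class]; needed only when \code{a} is
#'   given, to place samples in populations.
#' @return data.frame with columns population, n, k, S, h, h_sd, pi, theta_w.
#' @export
populationSummary <- function(t, a = NULL, m = NULL) {
  stopifnot(is(t, "HaplotypeTable"))
  cnt <- haploCounts(t)
  pops <- colnames(cnt)
  if (!is.null(m)) {
    ord <- intersect(m@sites$population, pops)
    if (length(ord) == length(pops)) pops <- ord
  }
  rows <- lapply(c(pops, ".overall"), function(pp) {
    if (pp == ".overall") {
      cc <- rowSums(cnt); label <- "Overall"; ids <- NULL
    } else {
      cc <- cnt[, pp]; label <- pp
    }
    cc <- cc[cc > 0]
    n <- sum(cc); k <- length(cc)
    h <- if (n >= 2) haplotypeDiversity(cc) else NA_real_
    hsd <- if (n >= 2) haplotypeDiversitySD(cc) else NA_real_
    S <- NA_integer_; pi <- NA_real_; tw <- NA_real_
    if (!is.null(a)) {
      sub <- .subsetAlignmentByPop(a, m, if (pp == ".overall") NULL else pp)
      if (!is.null(sub) && length(sub@seqs) >= 2) {
        S <- segregatingSites(sub)
        pi <- nucleotideDiversity(sub)
        tw <- wattersonTheta(S, length(sub@seqs), alnLength(sub))
      } else if (!is.null(sub)) {
        S <- 0L; pi <- 0; tw <- 0
      }
    }
    data.frame(population = label, n = n, k = k, S = S, h = h, h_sd = hsd,
               pi = pi, theta_w = tw, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.subsetAlignmentByPop <- function(a, m, pop) {
  if (is.null(pop)) return(a)
  if (is.null(m)) return(NULL)
  ids <- m@samples$sample[m@samples$population == pop]
  ids <- intersect(names(a@seqs), ids)
  if (!length(ids)) return(NULL)
  newHaploAlignment(as.character(a@seqs[ids]))
}

#' Write a diversity summary as TSV
#' @param summary data.frame from [populationSummary()]
#' @param path output file
#' @export
writeDiversityTable <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
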