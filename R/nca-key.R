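# The 1995 inference key, shipped as an editable decision table
# (inst/extdata/inference_key.tsv): columns step, condition, yes, no, where
# yes/no are either a next step id or "CONCLUSION:<code>". The geography
# questions of the printed key are operationalised from the data at hand:
# range overlap is measured by shared populations between member units, and
# "deep" separation by the mutational steps on the connecting edges relative
# to the network-wide mean edge length.

.keyConclusions <- c(
  RGF_IBD = "restricted gene flow with isolation by distance",
  RGF_LDD = "restricted gene flow with some long-distance dispersal",
  LDC     = "long-distance colonization",
  PAST_FRAG = "past fragmentation",
  CRE     = "contiguous range expansion",
  INCONCLUSIVE = "inconclusive")

#' Load an inference-key decision table
#'
#' @param path TSV with columns step, condition, yes, no; defaults to the
#'   packaged 1995 key.
#' @return data.frame decision table.
#' @export
loadInferenceKey <- function(path = system.file("extdata",
                                                "inference_key.tsv",
                                                package = "cpPhylogeo")) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "", stringsAsFactors = FALSE)
}

# evaluate the named condition for one nesting clade
.keyConditionValue <- function(cond, ev) {
  if (!cond %in% names(ev)) stop("inference key condition not encoded: ", cond)
  isTRUE(ev[[cond]])
}

# assemble the logical evidence list for one nesting clade
.keyEvidence <- function(units, contrast, design, t, alpha) {
  sig <- function(p) !is.na(p) & p < alpha
  tips <- units$status == "tip"; ints <- units$status == "interior"
  small_dc <- sig(units$p_small_Dc)
  large_dc <- sig(units$p_large_Dc)
  small_dn <- sig(units$p_small_Dn)
  large_dn <- sig(units$p_large_Dn)
  any_sig <- any(small_dc | large_dc | small_dn | large_dn) ||
    any(sig(unlist(contrast[, grep("^p_", names(contrast))])))

  cnt <- haploCounts(t)
  popsOf <- function(u) {
    w <- .unitPopCounts(design, u, cnt)
    names(w)[w > 0]
  }
  allopatric <- function(flagged) {
    if (!any(flagged)) return(FALSE)
    fl <- units$unit[flagged]; rest <- setdiff(units$unit, fl)
    if (length(rest)) {
      rp <- unique(unlist(lapply(rest, popsOf)))
      return(!any(vapply(fl, function(u) any(popsOf(u) %in% rp), logical(1))))
    }
    # every member flagged: allopatric when the flagged clades fall into at
    # least two groups with mutually non-overlapping ranges (connected
    # components of the range-overlap graph)
    pl <- lapply(fl, popsOf)
    comp <- seq_along(pl)
    for (i in seq_along(pl)) for (j in seq_along(pl))
      if (i < j && any(pl[[i]] %in% pl[[j]]))
        comp[comp == comp[j]] <- comp[i]
    length(unique(comp)) >= 2L
  }
  deep <- function(flagged) {
    if (!any(flagged)) return(FALSE)
    tr <- design@tree
    fl <- units$unit[flagged]; rest <- setdiff(units$unit, fl)
    cross <- if (length(rest)) {
      fl_h <- unlist(lapply(fl, .hapsOf, design = design))
      rest_h <- unlist(lapply(rest, .hapsOf, design = design))
      (tr$u %in% fl_h & tr$v %in% rest_h) |
        (tr$v %in% fl_h & tr$u %in% rest_h)
    } else {
      # every member flagged: look at the connections between them instead
      of <- stats::setNames(rep(fl, lengths(lapply(fl, .hapsOf,
                                                   design = design))),
                            unlist(lapply(fl, .hapsOf, design = design)))
      tr$u %in% names(of) & tr$v %in% names(of) & of[tr$u] != of[tr$v]
    }
    if (!any(cross)) return(FALSE)
    max(tr$steps[cross]) > mean(tr$steps)
  }
  sig_dn_any <- small_dn | large_dn

  list(
    any_significant = any_sig,
    tip_dc_small_or_interior_dc_large =
      any(small_dc & tips) || any(large_dc & ints) ||
      sig(contrast$p_large_it_Dc),
    dn_reversed =
      any(large_dn & tips) || any(small_dn & ints) ||
      sig(contrast$p_small_it_Dn),
    small_dc_clades_allopatric = allopatric(small_dc),
    large_dn_clades_nonoverlapping = allopatric(large_dn),
    deep_branch_small_dc = deep(small_dc),
    deep_branch_sig_dn = deep(if (any(sig_dn_any)) sig_dn_any else small_dc),
    tip_dn_small_or_interior_dn_large =
      any(small_dn & tips) || any(large_dn & ints) ||
      sig(contrast$p_large_it_Dn),
    significant_clades_allopatric = allopatric(sig_dn_any | small_dc | large_dc)
  )
}

#' Apply the phylogeographic inference key to one nesting clade
#'
#' Deterministically traverses the encoded decision table given the
#' permutation significance pattern of a nesting clade, recording the key
#' path (e.g. \code{"1-2-3-4-No"}) and returning one of the enumerated
#' conclusions. A clade without significant values exits at step 1 as
#' inconclusive; a significance pattern that escapes the table is returned
#' as inconclusive with the partial path recorded.
#'
#' @param nca result of [permutationSignificance()].
#' @param contingency result of [nestedContingencyTest()] (optional; when
#'   supplied, a non-significant contingency test short-circuits to
#'   inconclusive).
#' @param design a [NestingDesign-class].
#' @param t a [HaplotypeTable-class].
#' @param nesting_clade id of the nesting clade to interpret (default
#'   \code{"total"}).
#' @param alpha significance level (default 0.05).
#' @param key decision table from [loadInferenceKey()].
#' @return list with elements \code{clade_id}, \code{key_path},
#'   \code{conclusion}.
#' @export
applyInferenceKey <- function(nca, contingency = NULL, design, t,
                              nesting_clade = "total", alpha = 0.05,
                              key = loadInferenceKey()) {
  units <- nca$units[nca$units$nesting_clade == nesting_clade, , drop = FALSE]
  contrast <- nca$contrasts[nca$contrasts$nesting_clade == nesting_clade, ,
                            drop = FALSE]
  if (!nrow(units)) stop("no NCA statistics for nesting clade ", nesting_clade)
  if (!is.null(contingency)) {
    ct <- contingency[contingency$nesting_clade == nesting_clade, , drop = FALSE]
    if (nrow(ct) && isTRUE(ct$applicable) && !is.na(ct$p_perm) &&
        ct$p_perm >= alpha)
      return(list(clade_id = nesting_clade, key_path = "contingency-NS",
                  conclusion = .keyConclusions[["INCONCLUSIVE"]]))
  }
  ev <- .keyEvidence(units, contrast, design, t, alpha)
  path <- character(0)
  step <- "1"
  for (guard in seq_len(nrow(key) + 1L)) {
    row <- key[key$step == step, , drop = FALSE]
    if (!nrow(row)) {
      return(list(clade_id = nesting_clade,
                  key_path = paste(path, collapse = "-"),
                  conclusion = .keyConclusions[["INCONCLUSIVE"]]))
    }
    ans <- .keyConditionValue(row$condition, ev)
    nxt <- if (ans) row$yes else row$no
    path <- c(path, step)
    if (startsWith(nxt, "CONCLUSION:")) {
      code <- sub("CONCLUSION:", "", nxt)
      path <- c(path, if (ans) "Yes" else "No")
      return(list(clade_id = nesting_clade,
                  key_path = paste(path, collapse = "-"),
                  conclusion = .keyConclusions[[code]]))
    }
    step <- nxt
  }
  list(clade_id = nesting_clade, key_path = paste(path, collapse = "-"),
       conclusion = .keyConclusions[["INCONCLUSIVE"]])
}
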