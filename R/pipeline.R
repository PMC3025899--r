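#' Configuration for a full pipeline run
#'
#' @param fasta path to an aligned FASTA (NULL in count-only mode).
#' @param popmap path to a population-map TSV (NULL when \code{map} given).
#' @param counts path to a haplotype-count TSV for count-only mode.
#' @param map optional [PopulationMap-class] built in code.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stochastic stage consumes an independent
#'   child seed derived as seed + stage counter (1 = permutations,
#'   2 = contingency, 3 = bootstrap, 4 = Mantel).
#' @param n_perm permutations for the NCA and Mantel tests.
#' @param n_bootstrap bootstrap replicates for the NJ tree.
#' @param mu mutation rate, substitutions/site/year (default 3e-9, a
#'   typical chloroplast spacer rate).
#' @param generation_time generation time in years (NULL reports
#'   N x generation time).
#' @param counts_only run only the stages computable from haplotype
#'   frequencies.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(fasta = NULL, popmap = NULL, counts = NULL, map = NULL,
                      out_dir, seed, n_perm = 10000L, n_bootstrap = 1000L,
                      mu = 3e-9, generation_time = NULL,
                      counts_only = is.null(fasta)) {
  if (missing(seed)) stop("a master seed is required")
  if (is.null(fasta) && is.null(counts))
    stop("either a FASTA alignment or a haplotype-count table is required")
  structure(list(fasta = fasta, popmap = popmap, counts = counts, map = map,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_perm = as.integer(n_perm),
                 n_bootstrap = as.integer(n_bootstrap), mu = mu,
                 generation_time = generation_time,
                 counts_only = counts_only),
            class = "RunConfig")
}

#' Run the full phylogeographic analysis
#'
#' Stages, in order: read, drop indel columns, collapse to haplotypes,
#' diversity table, mutational-step matrix, minimum spanning network,
#' nesting + Dc/Dn + contingency + inference key, FST/Nm, isolation by
#' distance, NJ tree with bootstrap, skyline. In count-only mode the subset
#' computable from haplotype frequencies runs (diversity; composition when a
#' fixture nesting is supplied via \code{design}). Every output is a TSV or
#' newick under \code{cfg$out_dir}; a structured log of parameters and
#' child seeds is written alongside.
#'
#' @param cfg a [runConfig()] object.
#' @param design optional [NestingDesign-class] overriding the one derived
#'   from the network (used for fixture-defined nestings).
#' @return invisible list of in-memory results.
#' @export
runPipeline <- function(cfg, design = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  log <- c(sprintf("seed\t%d", cfg$seed),
           sprintf("n_perm\t%d", cfg$n_perm),
           sprintf("n_bootstrap\t%d", cfg$n_bootstrap),
           sprintf("mu\t%g", cfg$mu))
  out <- function(f) file.path(cfg$out_dir, f)

  if (cfg$counts_only) {
    tab <- readHaplotypeCounts(cfg$counts)
    res$table <- tab
    res$diversity <- populationSummary(tab)
    writeDiversityTable(res$diversity, out("diversity.tsv"))
    if (!is.null(design)) {
      res$composition <- cladeCompositionTable(design, tab)
      utils::write.table(res$composition, out("clade_composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(log, out("run_log.tsv"))
    return(invisible(res))
  }

  aln <- readFastaAlignment(cfg$fasta)
  map <- if (!is.null(cfg$map)) cfg$map else readPopulationMap(cfg$popmap)
  dropped <- dropIndelColumns(aln)
  aln2 <- dropped$alignment
  log <- c(log, sprintf("n_sequences\t%d", length(aln2@seqs)),
           sprintf("aligned_sites\t%d", alnLength(aln)),
           sprintf("sites_after_indel_removal\t%d", alnLength(aln2)))

  tab <- collapseHaplotypes(aln2, map)
  res$table <- tab
  res$diversity <- populationSummary(tab, aln2, map)
  writeDiversityTable(res$diversity, out("diversity.tsv"))

  sm <- stepMatrix(tab)
  nw <- minimumSpanningNetwork(sm, haploCounts(tab))
  res$network <- nw
  exportNetwork(nw, out("network_edges.tsv"))

  if (is.null(design)) design <- buildNesting(nw)
  res$design <- design
  utils::write.table(cladeTable(design), out("nesting.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$composition <- cladeCompositionTable(design, tab)
  utils::write.table(res$composition, out("clade_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  res$nca <- permutationSignificance(design, tab, map, n_perm = cfg$n_perm,
                                     seed = cfg$seed + 1L)
  utils::write.table(res$nca$units, out("clade_distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$nca$contrasts, out("clade_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$contingency <- nestedContingencyTest(design, tab, n_perm = cfg$n_perm,
                                           seed = cfg$seed + 2L)
  utils::write.table(res$contingency, out("contingency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nests <- cladeTable(design)$clade_id[cladeTable(design)$level >= 1L]
  res$inference <- do.call(rbind, lapply(nests, function(nc) {
    inf <- applyInferenceKey(res$nca, res$contingency, design, tab,
                             nesting_clade = nc)
    data.frame(nesting_clade = nc, key_path = inf$key_path,
               conclusion = inf$conclusion, stringsAsFactors = FALSE)
  }))
  utils::write.table(res$inference, out("inference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  npop_ok <- sum(table(map@samples$population) >= 2) >= 2
  if (npop_ok) {
    res$fstnm <- tryCatch(fstNmMatrices(aln2, map), error = function(e) NULL)
    if (!is.null(res$fstnm)) {
      writeFstNmTable(res$fstnm, out("fst_nm.tsv"))
      if (length(res$fstnm$populations) >= 3L) {
        res$ibd <- ibdTest(res$fstnm, map, n_perm = cfg$n_perm,
                           seed = cfg$seed + 4L)
        utils::write.table(
          data.frame(r = res$ibd$r, abs_r = res$ibd$abs_r,
                     p_perm = res$ibd$p_perm, p_ftest = res$ibd$p_ftest,
                     n_pairs = res$ibd$n_pairs),
          out("ibd.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if (length(tab@sequences) >= 3L) {
    hap_aln <- newHaploAlignment(haploSequences(tab))
    bs <- bootstrapSupport(hap_aln, n_reps = cfg$n_bootstrap,
                           seed = cfg$seed + 3L)
    res$tree <- bs$tree
    writeNewick(bs$tree, out("tree.nwk"))
    um <- ultrametricize(bs$tree)
    ci <- coalescentIntervals(um)
    res$skyline <- classicSkyline(ci, mu = cfg$mu, L = alnLength(aln2),
                                  generation_time = cfg$generation_time)
    writeSkylineTable(res$skyline, out("skyline.tsv"))
  }
  writeLines(log, out("run_log.tsv"))
  invisible(res)
}

#' Compare a pipeline output bundle against the packaged fixture
#'
#' Recomputes per-population and overall haplotype diversity from the
#' fixture counts and reports the per-cell deltas against the bundle's
#' diversity table; when a composition table is present its percentages are
#' checked as well. Pass/fail at |delta| < 0.0005 for h (three printed
#' decimals) and 0.05 percentage points for composition.
#'
#' @param bundle_dir directory written by [runPipeline()].
#' @param fixture result of [makePaperFixture()].
#' @return data.frame of comparisons with a logical \code{pass} column.
#' @export
validateAgainstFixture <- function(bundle_dir, fixture) {
  f <- file.path(bundle_dir, "diversity.tsv")
  if (!file.exists(f)) stop("bundle lacks diversity.tsv")
  got <- utils::read.table(f, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  want <- populationSummary(fixture$table)
  rows <- lapply(seq_len(nrow(want)), function(i) {
    g <- got$h[got$population == want$population[i]]
    delta <- if (length(g)) abs(g[1L] - want$h[i]) else NA_real_
    data.frame(quantity = "h", unit = want$population[i],
               expected = want$h[i], observed = if (length(g)) g[1L] else NA,
               delta = delta, pass = !is.na(delta) && delta < 5e-4,
               stringsAsFactors = FALSE)
  })
  fc <- file.path(bundle_dir, "clade_composition.tsv")
  if (file.exists(fc)) {
    comp <- utils::read.table(fc, header = TRUE, sep = "\t", quote = "",
                              check.names = FALSE, stringsAsFactors = FALSE)
    des <- nestingFromFixture(fixture$clade_members, fixture$clade_nesting)
    want_c <- cladeCompositionTable(des, fixture$table)
    for (i in seq_len(nrow(want_c))) {
      g <- comp$percent[comp$clade_id == want_c$clade_id[i]]
      delta <- if (length(g)) abs(g[1L] - want_c$percent[i]) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(quantity = "composition_pct", unit = want_c$clade_id[i],
                   expected = want_c$percent[i],
                   observed = if (length(g)) g[1L] else NA,
                   delta = delta, pass = !is.na(delta) && delta < 0.05,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
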