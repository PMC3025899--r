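#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

setOldClass("phylo")

#' HaploAlignment: an aligned set of haplotype-locus sequences
#'
#' Thin S4 wrapper around a [Biostrings::DNAStringSet] that enforces the
#' invariants every downstream statistic assumes: all records share one
#' aligned length, sample identifiers are unique, and the alphabet is
#' restricted to A, C, G, T, N and the gap character.
#'
#' @slot seqs A \code{DNAStringSet} of equal-width, uniquely named records.
#' @export
setClass("HaploAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("HaploAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one record")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return(sprintf("unequal sequence lengths: record '%s' has width %d, expected %d",
                   names(s)[which(w != w[1L])[1L]], w[which(w != w[1L])[1L]], w[1L]))
  if (w[1L] < 1L) return("aligned length must be >= 1")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("sample identifiers must be present and unique")
  chars <- unique(strsplit(paste(as.character(s), collapse = ""), "")[[1L]])
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    return(sprintf("disallowed characters in alignment: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' PopulationMap: sample-to-population and population-to-site assignments
#'
#' @slot samples data.frame with columns \code{sample}, \code{population}.
#' @slot sites data.frame with columns \code{population}, \code{lat},
#'   \code{lon} (decimal degrees) and \code{elevation} (metres, may be NA).
#' @export
setClass("PopulationMap",
         slots = c(samples = "data.frame", sites = "data.frame"))

setValidity("PopulationMap", function(object) {
  sm <- object@samples; st <- object@sites
  if (!all(c("sample", "population") %in% names(sm)))
    return("samples must have columns 'sample' and 'population'")
  if (!all(c("population", "lat", "lon") %in% names(st)))
    return("sites must have columns 'population', 'lat', 'lon'")
  if (anyDuplicated(sm$sample)) return("duplicated sample identifiers")
  if (anyDuplicated(st$population)) return("duplicated population codes")
  miss <- setdiff(unique(sm$population), st$population)
  if (length(miss))
    return(sprintf("populations without site coordinates: %s",
                   paste(miss, collapse = ", ")))
  if (any(!is.na(st$lat) & (st$lat < -90 | st$lat > 90)))
    return("latitudes must lie in [-90, 90]")
  if (any(!is.na(st$lon) & (st$lon < -180 | st$lon > 180)))
    return("longitudes must lie in [-180, 180]")
  TRUE
})

#' HaplotypeTable: distinct haplotypes with per-population counts
#'
#' Houses the haplotype-by-population contingency table that is sufficient
#' input for haplotype diversity and all frequency-only statistics; when the
#' collapsed sequences are retained, sequence statistics become available
#' as well.
#'
#' @slot counts integer matrix, haplotypes x populations, with dimnames.
#' @slot sequences named character vector of haplotype sequences, or
#'   length-zero when the table was built from counts alone.
#' @export
setClass("HaplotypeTable",
         slots = c(counts = "matrix", sequences = "character"))

setValidity("HaplotypeTable", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry haplotype and population dimnames")
  if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
  if (any(rowSums(m) < 1)) return("every haplotype must be observed at least once")
  sq <- object@sequences
  if (length(sq)) {
    if (!identical(sort(names(sq)), sort(rownames(m))))
      return("sequence names must match haplotype ids")
    if (anyDuplicated(sq)) return("haplotype sequences must be pairwise distinct")
    if (length(unique(nchar(sq))) != 1L) return("haplotype sequences must share one length")
  }
  TRUE
})

#' HaplotypeNetwork: minimum spanning network over haplotypes
#'
#' Edges carry the number of mutational steps; each edge is flagged as part
#' of the primary minimum spanning tree or as an alternative co-minimal
#' connection (a MINSPNET-style loop edge whose length ties the minimax path
#' weight between its endpoints).
#'
#' @slot nodes character vector of haplotype ids.
#' @slot counts haplotype x population count matrix (as in the source table).
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{steps},
#'   \code{edge_class} (\code{"mst"} or \code{"alternative"}).
#' @export
setClass("HaplotypeNetwork",
         slots = c(nodes = "character", counts = "matrix", edges = "data.frame"))

setValidity("HaplotypeNetwork", function(object) {
  e <- object@edges
  need <- c("u", "v", "steps", "edge_class")
  if (!all(need %in% names(e))) return("edges must have u, v, steps, edge_class")
  if (!all(e$u %in% object@nodes) || !all(e$v %in% object@nodes))
    return("edge endpoints must be network nodes")
  if (any(e$steps < 1)) return("edge weights must be >= 1 mutational step")
  if (!all(e$edge_class %in% c("mst", "alternative")))
    return("edge_class must be 'mst' or 'alternative'")
  nm <- sum(e$edge_class == "mst")
  if (length(object@nodes) > 1L && nm != length(object@nodes) - 1L)
    return("primary MST edge count must equal nodes - 1")
  TRUE
})

#' NestingDesign: the hierarchical clade structure of a haplotype network
#'
#' @slot clades data.frame with columns \code{clade_id}, \code{level},
#'   \code{status} ("tip"/"interior"), \code{parent}.
#' @slot members named list: clade_id -> character vector of member unit ids
#'   (haplotype ids at level 1, sub-clade ids above).
#' @slot haplotypes named list: clade_id -> all haplotype ids ultimately
#'   contained in the clade.
#' @slot tree data.frame of the loop-broken haplotype tree used for nesting
#'   (columns \code{u}, \code{v}, \code{steps}).
#' @slot network data.frame of the full network edges (loops included),
#'   used for tip/interior classification.
#' @slot broken data.frame of edges removed to break reticulation loops.
#' @export
setClass("NestingDesign",
         slots = c(clades = "data.frame", members = "list",
                   haplotypes = "list", tree = "data.frame",
                   network = "data.frame", broken = "data.frame"))

setValidity("NestingDesign", function(object) {
  cl <- object@clades
  need <- c("clade_id", "level", "status", "parent")
  if (!all(need %in% names(cl))) return("clades must have clade_id, level, status, parent")
  if (anyDuplicated(cl$clade_id)) return("clade ids must be unique")
  if (sum(cl$level == max(cl$level)) != 1L)
    return("top level must be a single cladogram")
  TRUE
})

#' SkylinePlot: piecewise-constant effective-size history
#'
#' @slot segments data.frame with columns \code{t_start}, \code{t_end}
#'   (time before present, increasing into the past), \code{lineages},
#'   \code{N} (effective number of gene copies, or N x generation time when
#'   no generation time was supplied).
#' @slot mu mutation rate used for the time conversion (substitutions per
#'   site per year), NA when branch lengths were already in time units.
#' @slot L number of sites.
#' @slot generation_time generation time in years (NA when not supplied).
#' @export
setClass("SkylinePlot",
         slots = c(segments = "data.frame", mu = "numeric", L = "numeric",
                   generation_time = "numeric"))

setValidity("SkylinePlot", function(object) {
  sg <- object@segments
  if (!all(c("t_start", "t_end", "lineages", "N") %in% names(sg)))
    return("segments must have t_start, t_end, lineages, N")
  if (any(sg$N < 0)) return("effective sizes must be non-negative")
  if (nrow(sg) > 1L && any(abs(sg$t_start[-1L] - sg$t_end[-nrow(sg)]) >
                           1e-8 * max(sg$t_end)))
    return("segments must be contiguous")
  TRUE
})

## ---- accessors ----

#' Number of aligned sites
#' @param x a HaploAlignment
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))
#' @rdname alnLength
setMethod("alnLength", "HaploAlignment",
          function(x) Biostrings::width(x@seqs)[1L])

#' Sample identifiers
#' @param x a HaploAlignment
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname sampleIDs
setMethod("sampleIDs", "HaploAlignment", function(x) names(x@seqs))

#' Haplotype-by-population count matrix
#' @param x a HaplotypeTable or HaplotypeNetwork
#' @export
setGeneric("haploCounts", function(x) standardGeneric("haploCounts"))
#' @rdname haploCounts
setMethod("haploCounts", "HaplotypeTable", function(x) x@counts)
#' @rdname haploCounts
setMethod("haploCounts", "HaplotypeNetwork", function(x) x@counts)

#' Haplotype sequences (named character vector; length 0 when absent)
#' @param x a HaplotypeTable
#' @export
setGeneric("haploSequences", function(x) standardGeneric("haploSequences"))
#' @rdname haploSequences
setMethod("haploSequences", "HaplotypeTable", function(x) x@sequences)

#' Total number of sampled individuals
#' @param x a HaplotypeTable
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))
#' @rdname nTotal
setMethod("nTotal", "HaplotypeTable", function(x) sum(x@counts))

#' Network edge list
#' @param x a HaplotypeNetwork
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname networkEdges
setMethod("networkEdges", "HaplotypeNetwork", function(x) x@edges)

#' Clade table of a nesting design
#' @param x a NestingDesign
#' @export
setGeneric("cladeTable", function(x) standardGeneric("cladeTable"))
#' @rdname cladeTable
setMethod("cladeTable", "NestingDesign", function(x) x@clades)

#' Clade membership (haplotype ids per clade)
#' @param x a NestingDesign
#' @param clade_id optional clade id; all clades when missing
#' @export
setGeneric("cladeHaplotypes", function(x, clade_id) standardGeneric("cladeHaplotypes"))
#' @rdname cladeHaplotypes
setMethod("cladeHaplotypes", "NestingDesign", function(x, clade_id) {
  if (missing(clade_id)) return(x@haplotypes)
  if (!clade_id %in% names(x@haplotypes))
    stop("unknown clade id: ", clade_id)
  x@haplotypes[[clade_id]]
})

#' Skyline segments
#' @param x a SkylinePlot
#' @export
setGeneric("skylineSegments", function(x) standardGeneric("skylineSegments"))
#' @rdname skylineSegments
setMethod("skylineSegments", "SkylinePlot", function(x) x@segments)

## ---- show methods ----

setMethod("show", "HaploAlignment", function(object) {
  cat(sprintf("HaploAlignment: %d sequences x %d aligned sites\n",
              length(object@seqs), alnLength(object)))
})

setMethod("show", "PopulationMap", function(object) {
  cat(sprintf("PopulationMap: %d samples in %d populations\n",
              nrow(object@samples), nrow(object@sites)))
})

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes x %d populations, n = %d (%s)\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts),
              if (length(object@sequences)) "with sequences" else "counts only"))
})

setMethod("show", "HaplotypeNetwork", function(object) {
  e <- object@edges
  cat(sprintf("HaplotypeNetwork: %d haplotypes, %d MST edges + %d alternative\n",
              length(object@nodes), sum(e$edge_class == "mst"),
              sum(e$edge_class == "alternative")))
})

setMethod("show", "NestingDesign", function(object) {
  lv <- table(object@clades$level)
  cat("NestingDesign:",
      paste(sprintf("%s clade(s) at level %s", lv, names(lv)), collapse = ", "),
      "\n")
})

setMethod("show", "SkylinePlot", function(object) {
  sg <- object@segments
  cat(sprintf("SkylinePlot: %d segments spanning %.4g time units\n",
              nrow(sg), max(sg$t_end)))
})
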