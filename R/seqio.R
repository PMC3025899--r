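#' Read an aligned FASTA file
#'
#' Records are read in file order, uppercased, and U (RNA notation) is mapped
#' to T. All records must share one aligned length.
#'
#' @param path path to a FASTA file of equal-length aligned sequences.
#' @return a [HaploAlignment-class].
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("not a readable FASTA file: ",
                                         conditionMessage(e), call. = FALSE))
  if (length(s) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(s))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  # keep the identifier token only (up to first whitespace), FASTA convention
  names(seqs) <- sub("\\s.*$", "", names(s))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    off <- which(w != w[1L])[1L]
    stop(sprintf("unequal aligned lengths: record '%s' has %d sites, expected %d",
                 names(seqs)[off], w[off], w[1L]))
  }
  newHaploAlignment(seqs)
}

#' Construct a HaploAlignment from named character sequences
#'
#' @param seqs named character vector over the alphabet A,C,G,T,N,-.
#' @return a [HaploAlignment-class].
#' @export
newHaploAlignment <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  new("HaploAlignment", seqs = Biostrings::DNAStringSet(seqs))
}

#' Character matrix view of an alignment (samples x sites)
#' @param a a HaploAlignment
#' @export
alignmentMatrix <- function(a) {
  stopifnot(is(a, "HaploAlignment"))
  m <- do.call(rbind, strsplit(as.character(a@seqs), ""))
  rownames(m) <- names(a@seqs)
  m
}

#' Remove alignment columns containing gaps
#'
#' Every column in which any sequence carries '-' is excluded, following the
#' common practice of dropping indel positions before distance and diversity
#' computation.
#'
#' @param a a [HaploAlignment-class].
#' @return list with elements \code{alignment} (gap-free HaploAlignment) and
#'   \code{kept_columns} (0-based original indices of retained columns,
#'   strictly increasing).
#' @export
dropIndelColumns <- function(a) {
  m <- alignmentMatrix(a)
  keep <- colSums(m == "-") == 0L
  if (!any(keep))
    stop("degenerate alignment: every column contains a gap")
  m2 <- m[, keep, drop = FALSE]
  seqs <- apply(m2, 1L, paste, collapse = "")
  list(alignment = newHaploAlignment(seqs),
       kept_columns = which(keep) - 1L)
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical at every site share a haplotype. N is a wildcard for
#' identity: an N matches any base, and a sequence containing N is merged
#' into the first earlier haplotype it is compatible with. Haplotype ids
#' H01, H02, ... are assigned in order of first appearance; counts are
#' tabulated per population.
#'
#' @param a a gap-free [HaploAlignment-class].
#' @param m a [PopulationMap-class] resolving every sample.
#' @return a [HaplotypeTable-class] with sequences retained.
#' @export
collapseHaplotypes <- function(a, m) {
  stopifnot(is(a, "HaploAlignment"), is(m, "PopulationMap"))
  seqs <- as.character(a@seqs)
  ids <- names(seqs)
  missing <- setdiff(ids, m@samples$sample)
  if (length(missing))
    stop("samples missing from population map: ", paste(missing, collapse = ", "))
  pop <- m@samples$population[match(ids, m@samples$sample)]

  reps <- character(0)            # representative sequence per haplotype
  assign <- integer(length(seqs)) # haplotype index per sample
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (length(reps)) {
      cand <- which(vapply(reps, .seqCompatible, logical(1), seqs[[i]]))
      if (length(cand)) hit <- cand[1L]
    }
    if (hit == 0L) {
      reps <- c(reps, seqs[[i]])
      hit <- length(reps)
    } else if (grepl("N", reps[hit], fixed = TRUE) &&
               !grepl("N", seqs[[i]], fixed = TRUE)) {
      reps[hit] <- seqs[[i]]      # prefer a fully resolved representative
    }
    assign[i] <- hit
  }
  hids <- sprintf("H%02d", seq_along(reps))
  pops <- unique(m@samples$population[m@samples$sample %in% ids])
  counts <- matrix(0L, nrow = length(reps), ncol = length(pops),
                   dimnames = list(hids, pops))
  for (i in seq_along(seqs))
    counts[assign[i], pop[i]] <- counts[assign[i], pop[i]] + 1L
  names(reps) <- hids
  new("HaplotypeTable", counts = counts, sequences = reps)
}

.seqCompatible <- function(x, y) {
  if (identical(x, y)) return(TRUE)
  if (!grepl("N", x, fixed = TRUE) && !grepl("N", y, fixed = TRUE))
    return(FALSE)
  cx <- strsplit(x, "")[[1L]]; cy <- strsplit(y, "")[[1L]]
  all(cx == cy | cx == "N" | cy == "N")
}

#' Read a haplotype-by-population count table
#'
#' Expects a TSV with a header row of population codes, a first column of
#' haplotype ids, and non-negative integer cells. The resulting table has no
#' sequences attached; frequency-only statistics remain available.
#'
#' @param path TSV file path.
#' @return a [HaplotypeTable-class] with sequences absent.
#' @export
readHaplotypeCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("count table has no rows: ", path)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("count cells must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  new("HaplotypeTable", counts = m, sequences = character(0))
}

#' Parse a degrees-minutes coordinate string
#'
#' Accepts strings such as \code{"106°49'E 39°25'N"} (either token
#' order), returning decimal degrees signed by hemisphere
#' (decimal = degrees + minutes/60; S and W negative).
#'
#' @param text coordinate string with two degree-minute tokens.
#' @return named numeric vector \code{c(lat = ..., lon = ...)}.
#' @export
parseDmsCoordinate <- function(text) {
  toks <- regmatches(text,
    gregexpr("([0-9]+)°([0-9]+)'([NSEW])", text))[[1L]]
  if (length(toks) != 2L)
    stop("malformed coordinate string (expected two degree-minute tokens): ", text)
  lat <- NA_real_; lon <- NA_real_
  for (tk in toks) {
    p <- regmatches(tk, regexec("([0-9]+)°([0-9]+)'([NSEW])", tk))[[1L]]
    deg <- as.numeric(p[2L]); mn <- as.numeric(p[3L]); hemi <- p[4L]
    if (mn >= 60) stop("minutes must be < 60 in: ", tk)
    val <- deg + mn / 60
    if (hemi %in% c("S", "W")) val <- -val
    if (hemi %in% c("N", "S")) lat <- val else lon <- val
  }
  if (is.na(lat) || is.na(lon))
    stop("coordinate must contain one N/S and one E/W token: ", text)
  if (abs(lat) > 90) stop("latitude out of range: ", lat)
  if (abs(lon) > 180) stop("longitude out of range: ", lon)
  c(lat = lat, lon = lon)
}

#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance(s) in km.
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 180), all(abs(lon2) <= 180))
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Read a population map TSV
#'
#' Columns: \code{sample}, \code{population}, then either a single
#' \code{coordinate} column holding a degree-minute string (as printed in
#' field tables) or numeric \code{lat} and \code{lon} columns; optional
#' \code{elevation}.
#'
#' @param path TSV file path.
#' @return a [PopulationMap-class].
#' @export
readPopulationMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "population") %in% names(d)))
    stop("population map needs 'sample' and 'population' columns")
  if ("coordinate" %in% names(d)) {
    cc <- t(vapply(d$coordinate, parseDmsCoordinate, numeric(2)))
    d$lat <- cc[, "lat"]; d$lon <- cc[, "lon"]
  }
  if (!all(c("lat", "lon") %in% names(d)))
    stop("population map needs coordinates ('coordinate' or 'lat'/'lon')")
  if (!"elevation" %in% names(d)) d$elevation <- NA_real_
  sites <- unique(d[, c("population", "lat", "lon", "elevation")])
  newPopulationMap(d[, c("sample", "population")], sites)
}

#' Construct a PopulationMap from data frames
#'
#' @param samples data.frame with columns sample, population.
#' @param sites data.frame with columns population, lat, lon and optionally
#'   elevation.
#' @return a [PopulationMap-class].
#' @export
newPopulationMap <- function(samples, sites) {
  samples <- data.frame(sample = as.character(samples$sample),
                        population = as.character(samples$population),
                        stringsAsFactors = FALSE)
  if (!"elevation" %in% names(sites)) sites$elevation <- NA_real_
  sites <- data.frame(population = as.character(sites$population),
                      lat = as.numeric(sites$lat), lon = as.numeric(sites$lon),
                      elevation = as.numeric(sites$elevation),
                      stringsAsFactors = FALSE)
  new("PopulationMap", samples = samples, sites = sites)
}

#' Pairwise great-circle distances between populations
#' @param m a PopulationMap
#' @return symmetric matrix of km distances with population dimnames.
#' @export
populationDistanceMatrix <- function(m) {
  st <- m@sites
  n <- nrow(st)
  d <- matrix(0, n, n, dimnames = list(st$population, st$population))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d[i, j] <- d[j, i] <- greatCircleKm(st$lat[i], st$lon[i], st$lat[j], st$lon[j])
  }
  d
}
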