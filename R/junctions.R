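## Repeat junction discovery: k-mer seeded ungapped matching of queries
## against a repeat library, junction calling at match boundaries, and
## classification into the canonical junction categories.

.JUNCTION_CATEGORIES <- c("retrotransposon-unknown", "dna_transposon-unknown",
                          "retrotransposon-retrotransposon",
                          "dna_transposon-dna_transposon",
                          "dna_transposon-retrotransposon")

#' Build a k-mer index over a repeat library
#'
#' Precomputes the seed index used by [findRepeatMatches()]; build it once
#' when scanning many reads against the same library.
#'
#' @param library A [RepeatLibrary-class].
#' @param k Seed length.
#' @return An opaque index object.
#' @export
buildRepeatIndex <- function(library, k = 16L) {
  stopifnot(is(library, "RepeatLibrary"))
  k <- as.integer(k)
  fwd <- as.character(sequencesOf(library))
  rev <- if (length(fwd)) .revComp(fwd) else character()
  cls <- repeatClass(library)
  ids <- names(fwd)

  entries <- list()
  oriented <- list()
  for (i in seq_along(ids)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd[[i]] else rev[[i]]
      key <- paste0(ids[i], strand)
      oriented[[key]] <- strsplit(s, "", fixed = TRUE)[[1]]
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      kmers <- substring(s, starts, starts + k - 1L)
      entries[[key]] <- data.frame(kmer = kmers, elt = i,
                                   strand = strand, pos = starts - 1L,
                                   stringsAsFactors = FALSE)
    }
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (length(entries)) {
    all <- do.call(rbind, entries)
    sp <- split(seq_len(nrow(all)), all$kmer)
    for (km in names(sp)) {
      rows <- sp[[km]]
      assign(km, cbind(elt = all$elt[rows],
                       strandMinus = as.integer(all$strand[rows] == "-"),
                       pos = all$pos[rows]), envir = env)
    }
  }
  structure(list(env = env, k = k, ids = ids, cls = cls,
                 oriented = oriented,
                 widths = nchar(fwd)),
            class = "repeatIndex")
}

## Greedy ungapped extension of a seed run along one diagonal. The endpoint
## only advances (always onto a match) while the identity of the extension
## itself stays at or above minIdentity; judging the extension rather than
## the whole segment stops a long perfect prefix from buying its way across
## an element boundary into unrelated sequence.
## m: logical match vector; s,e: 1-based seed bounds; returns c(start, end).
.extendSeed <- function(m, s, e, minIdentity) {
  n <- length(m)
  bestE <- e
  cm <- 0L; cl <- 0L
  j <- e + 1L
  while (j <= n) {
    cl <- cl + 1L; cm <- cm + m[j]
    if (m[j] && cm / cl >= minIdentity) { bestE <- j; cm <- 0L; cl <- 0L }
    j <- j + 1L
  }
  bestS <- s
  cm <- 0L; cl <- 0L
  j <- s - 1L
  while (j >= 1L) {
    cl <- cl + 1L; cm <- cm + m[j]
    if (m[j] && cm / cl >= minIdentity) { bestS <- j; cm <- 0L; cl <- 0L }
    j <- j - 1L
  }
  c(bestS, bestE)
}

#' Find repeat-library matches in a query sequence
#'
#' k-mer seeded, ungapped extension against both strands of every library
#' element. A match is a maximal extended segment on one (element, strand,
#' diagonal) with length `>= minMatchLen` and identity `>= minIdentity`;
#' overlapping segments on the same diagonal are merged. This self-contained
#' matcher replaces external BLAST-style machinery; the default thresholds
#' (k = 16, 30 bp, 90% identity) play the role of a stringent e-value cutoff.
#'
#' @param query A single nucleotide string (A/C/G/T).
#' @param library A [RepeatLibrary-class] (ignored when `index` is given).
#' @param minMatchLen Minimum reported match length.
#' @param minIdentity Minimum match identity fraction.
#' @param k Seed length (`k <= minMatchLen`).
#' @param index Optional prebuilt [buildRepeatIndex()] result.
#' @return data.frame with columns query_start, query_end (0-based half-open),
#'   element_id, element_class, strand, identity, diag.
#' @export
findRepeatMatches <- function(query, library = NULL, minMatchLen = 30L,
                              minIdentity = 0.9, k = 16L, index = NULL) {
  if (length(query) != 1L) stop("query must be a single sequence", call. = FALSE)
  query <- toupper(as.character(query))
  .assertDNA(query, "query")
  if (is.null(index)) {
    if (is.null(library)) stop("either library or index is required", call. = FALSE)
    index <- buildRepeatIndex(library, k)
  }
  k <- index$k
  if (k > minMatchLen) stop("k must not exceed minMatchLen", call. = FALSE)
  Lq <- nchar(query)
  if (Lq < minMatchLen)
    stop("query shorter than minMatchLen", call. = FALSE)

  empty <- data.frame(query_start = integer(), query_end = integer(),
                      element_id = character(), element_class = character(),
                      strand = character(), identity = numeric(),
                      diag = integer(), stringsAsFactors = FALSE)
  if (length(index$ids) == 0) return(empty)

  starts <- seq_len(Lq - k + 1L)
  qk <- substring(query, starts, starts + k - 1L)
  hits <- mget(qk, envir = index$env, ifnotfound = list(NULL))
  found <- !vapply(hits, is.null, logical(1))
  if (!any(found)) return(empty)

  qpos <- rep(starts[found] - 1L,
              vapply(hits[found], nrow, integer(1)))
  hm <- do.call(rbind, hits[found])
  diag <- qpos - hm[, "pos"]
  cand <- unique(data.frame(elt = hm[, "elt"], strandMinus = hm[, "strandMinus"],
                            diag = diag))

  qchars <- strsplit(query, "", fixed = TRUE)[[1]]
  out <- list()
  for (r in seq_len(nrow(cand))) {
    elt <- cand$elt[r]; sm <- cand$strandMinus[r]; d <- cand$diag[r]
    strand <- if (sm == 1L) "-" else "+"
    echars <- index$oriented[[paste0(index$ids[elt], strand)]]
    Le <- length(echars)
    qs0 <- max(0L, d); qe0 <- min(Lq, d + Le)   # overlap on this diagonal
    if (qe0 - qs0 < minMatchLen) next
    qi <- (qs0 + 1L):qe0
    m <- qchars[qi] == echars[qi - d]
    ## seeds: exact runs of length >= k
    rl <- rle(m)
    ends <- cumsum(rl$lengths); startsR <- ends - rl$lengths + 1L
    segs <- list()
    if (minIdentity >= 1) {
      keep <- rl$values & rl$lengths >= minMatchLen
      for (i in which(keep)) segs[[length(segs) + 1L]] <- c(startsR[i], ends[i])
    } else {
      seedIdx <- which(rl$values & rl$lengths >= k)
      for (i in seedIdx)
        segs[[length(segs) + 1L]] <- .extendSeed(m, startsR[i], ends[i], minIdentity)
    }
    if (!length(segs)) next
    ## merge overlapping segments on this diagonal
    sm2 <- do.call(rbind, segs)
    o <- order(sm2[, 1])
    sm2 <- sm2[o, , drop = FALSE]
    merged <- list(sm2[1, ])
    if (nrow(sm2) > 1) {
      for (i in 2:nrow(sm2)) {
        last <- merged[[length(merged)]]
        if (sm2[i, 1] <= last[2] + 1L) {
          merged[[length(merged)]] <- c(last[1], max(last[2], sm2[i, 2]))
        } else merged[[length(merged) + 1L]] <- sm2[i, ]
      }
    }
    for (seg in merged) {
      len <- seg[2] - seg[1] + 1L
      ident <- sum(m[seg[1]:seg[2]]) / len
      if (len >= minMatchLen && ident >= minIdentity) {
        out[[length(out) + 1L]] <- data.frame(
          query_start = qs0 + seg[1] - 1L, query_end = qs0 + seg[2],
          element_id = index$ids[elt], element_class = index$cls[[elt]],
          strand = strand, identity = ident, diag = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$query_start, res$query_end, res$element_id, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call repeat junctions from the matches of one query
#'
#' A junction is a match boundary with at least `minFlank` supporting bases on
#' each side: either unmatched query sequence (class "unknown") or another
#' match. Two matches whose facing edges are within `gapTol` bases are fused
#' into a single element-element junction at the floor of the mean of the two
#' edges. Midpoints strictly inside the query only.
#'
#' @param queryId Query identifier carried into the output.
#' @param matches data.frame from [findRepeatMatches()].
#' @param queryLength Length of the query.
#' @param minFlank Minimum supporting bases on each side of a junction.
#' @param gapTol Maximum gap (or overlap) between "abutting" matches, in bp.
#' @return data.frame: query_id, midpoint, left_class, right_class, category,
#'   flank_left, flank_right.
#' @export
detectJunctions <- function(queryId, matches, queryLength, minFlank = 30L,
                            gapTol = 5L) {
  if (minFlank < 1L) stop("minFlank must be >= 1", call. = FALSE)
  empty <- data.frame(query_id = character(), midpoint = integer(),
                      left_class = character(), right_class = character(),
                      category = character(), flank_left = integer(),
                      flank_right = integer(), stringsAsFactors = FALSE)
  if (is.null(matches) || nrow(matches) == 0) return(empty)
  mt <- matches[order(matches$query_start, matches$query_end), , drop = FALSE]
  n <- nrow(mt)
  len <- mt$query_end - mt$query_start
  leftDone <- rep(FALSE, n); rightDone <- rep(FALSE, n)
  out <- list()
  emit <- function(mid, lc, rc, fl, fr) {
    if (mid <= 0L || mid >= queryLength) return()
    if (fl < minFlank || fr < minFlank) return()
    out[[length(out) + 1L]] <<- data.frame(
      query_id = queryId, midpoint = as.integer(mid), left_class = lc,
      right_class = rc, category = classifyJunction(lc, rc),
      flank_left = as.integer(fl), flank_right = as.integer(fr),
      stringsAsFactors = FALSE)
  }
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      gap <- mt$query_start[i + 1L] - mt$query_end[i]
      if (abs(gap) <= gapTol) {
        emit(floor((mt$query_end[i] + mt$query_start[i + 1L]) / 2),
             mt$element_class[i], mt$element_class[i + 1L], len[i], len[i + 1L])
        rightDone[i] <- TRUE; leftDone[i + 1L] <- TRUE
      }
    }
  }
  for (i in seq_len(n)) {
    if (!leftDone[i]) {
      prevEnd <- if (i > 1) max(mt$query_end[seq_len(i - 1L)]) else 0L
      un <- mt$query_start[i] - prevEnd
      if (un >= minFlank)
        emit(mt$query_start[i], "unknown", mt$element_class[i], un, len[i])
    }
    if (!rightDone[i]) {
      nextStart <- if (i < n) min(mt$query_start[seq(i + 1L, n)]) else queryLength
      un <- min(nextStart, queryLength) - mt$query_end[i]
      if (un >= minFlank)
        emit(mt$query_end[i], mt$element_class[i], "unknown", len[i], un)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$midpoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a junction by the repeat classes of its two sides
#'
#' Order-insensitive canonical labels over the three-valued class enum; a
#' junction with two unknown sides is not a repeat junction and is rejected.
#'
#' @param leftClass,rightClass One of "retrotransposon", "dna_transposon",
#'   "unknown".
#' @return One of the five canonical category labels.
#' @examples
#' classifyJunction("unknown", "retrotransposon")  # "retrotransposon-unknown"
#' @export
classifyJunction <- function(leftClass, rightClass) {
  cls <- c(leftClass, rightClass)
  if (!all(cls %in% .JUNCTION_CLASSES))
    stop("classes must be retrotransposon, dna_transposon or unknown",
         call. = FALSE)
  if (all(cls == "unknown"))
    stop("a junction with two unknown sides is not a repeat junction",
         call. = FALSE)
  if (any(cls == "unknown")) {
    paste0(cls[cls != "unknown"], "-unknown")
  } else if (leftClass == rightClass) {
    paste0(leftClass, "-", rightClass)
  } else {
    "dna_transposon-retrotransposon"
  }
}

#' Tabulate detected junctions by category
#'
#' @param junctions data.frame with a `category` column (or a truth table from
#'   [junctionTruth()] whose categories are derived from left/right classes).
#' @return Named integer vector over the five canonical categories; counts sum
#'   to the number of classified junctions.
#' @export
tabulateCategories <- function(junctions) {
  if (is.null(junctions) || nrow(junctions) == 0)
    return(stats::setNames(integer(length(.JUNCTION_CATEGORIES)),
                           .JUNCTION_CATEGORIES))
  cat <- if ("category" %in% names(junctions)) junctions$category
         else mapply(classifyJunction, junctions$left_class, junctions$right_class)
  tab <- table(factor(cat, levels = .JUNCTION_CATEGORIES))
  stats::setNames(as.integer(tab), .JUNCTION_CATEGORIES)
}

#' Scan a read set for repeat junctions
#'
#' Runs [findRepeatMatches()] and [detectJunctions()] over every read,
#' building the library index once. Junction coordinates are on the forward
#' strand of each read.
#'
#' @param reads A [ReadSet-class] or named `DNAStringSet`.
#' @param library A [RepeatLibrary-class].
#' @inheritParams findRepeatMatches
#' @inheritParams detectJunctions
#' @return data.frame of junctions across all reads.
#' @export
scanReadsForJunctions <- function(reads, library, minMatchLen = 30L,
                                  minIdentity = 0.9, k = 16L, minFlank = 30L,
                                  gapTol = 5L) {
  seqs <- if (is(reads, "ReadSet")) sequencesOf(reads) else reads
  idx <- buildRepeatIndex(library, k)
  chars <- as.character(seqs)
  out <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    mt <- findRepeatMatches(chars[[i]], minMatchLen = minMatchLen,
                            minIdentity = minIdentity, index = idx)
    out[[i]] <- detectJunctions(names(chars)[i], mt, nchar(chars[[i]]),
                                minFlank = minFlank, gapTol = gapTol)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map read-coordinate junctions back to genome coordinates
#'
#' Uses the read-origin bookkeeping of a simulated [ReadSet-class]: a boundary
#' at read position m maps to `start + m` for a forward read and to
#' `start + readLength - m` for a reverse-complemented read.
#'
#' @param junctions data.frame from [scanReadsForJunctions()].
#' @param reads The [ReadSet-class] the junctions were detected in.
#' @return The input with `chrom` and `genome_position` columns appended.
#' @export
junctionGenomeCoords <- function(junctions, reads) {
  stopifnot(is(reads, "ReadSet"))
  org <- readOrigins(reads)
  i <- match(junctions$query_id, org$read_id)
  if (anyNA(i)) stop("junctions refer to unknown reads", call. = FALSE)
  fwd <- org$strand[i] == "+"
  junctions$chrom <- org$chrom[i]
  junctions$genome_position <- ifelse(
    fwd, org$start[i] + junctions$midpoint,
    org$start[i] + reads@readLength - junctions$midpoint)
  junctions
}
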