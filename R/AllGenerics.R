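## Accessor generics. Slot access from user code should go through these.

#' @rdname accessors
#' @param x An object from this package.
#' @export
setGeneric("repeatClass", function(x) standardGeneric("repeatClass"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("chromSequences", function(x) standardGeneric("chromSequences"))

#' @rdname accessors
#' @export
setGeneric("armFraction", function(x) standardGeneric("armFraction"))

#' @rdname accessors
#' @export
setGeneric("junctionTruth", function(x) standardGeneric("junctionTruth"))

#' @rdname accessors
#' @export
setGeneric("teInsertions", function(x) standardGeneric("teInsertions"))

#' @rdname accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname accessors
#' @export
setGeneric("readOrigins", function(x) standardGeneric("readOrigins"))

#' @rdname accessors
#' @export
setGeneric("panelLines", function(x) standardGeneric("panelLines"))

#' @rdname accessors
#' @export
setGeneric("probeTable", function(x) standardGeneric("probeTable"))

#' @rdname accessors
#' @export
setGeneric("accounting", function(x) standardGeneric("accounting"))

#' Accessors for rjmap objects
#'
#' Small read-only accessors returning the underlying vectors/data.frames of
#' the package's S4 containers.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("repeatClass", "RepeatLibrary", function(x)
  stats::setNames(x@repeatClass, names(x@sequences)))

#' @rdname accessors
#' @export
setMethod("chromSequences", "GenomeModel", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x)
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences)))

#' @rdname accessors
#' @export
setMethod("armFraction", "GenomeModel", function(x) x@armFraction)

#' @rdname accessors
#' @export
setMethod("junctionTruth", "GenomeModel", function(x) x@junctionTruth)

#' @rdname accessors
#' @export
setMethod("teInsertions", "GenomeModel", function(x) x@teInsertions)

#' @rdname accessors
#' @export
setMethod("geneAnnotation", "GenomeModel", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("readOrigins", "ReadSet", function(x) x@origins)

#' @rdname accessors
#' @export
setMethod("panelLines", "LinePanel", function(x) x@lines)

#' @rdname accessors
#' @export
setMethod("probeTable", "ProbeSet", function(x) x@probes)

#' @rdname accessors
#' @export
setMethod("accounting", "ProbeSet", function(x) x@accounting)

#' @rdname accessors
#' @export
setMethod("length", "RepeatLibrary", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setMethod("length", "ReadSet", function(x) length(x@sequences))

#' Extract read or element sequences
#'
#' @param x A `RepeatLibrary` or `ReadSet`.
#' @return A [Biostrings::DNAStringSet].
#' @export
setGeneric("sequencesOf", function(x) standardGeneric("sequencesOf"))

#' @rdname sequencesOf
#' @export
setMethod("sequencesOf", "RepeatLibrary", function(x) x@sequences)

#' @rdname sequencesOf
#' @export
setMethod("sequencesOf", "ReadSet", function(x) x@sequences)
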