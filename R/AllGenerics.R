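# Accessor generics. Slot access from user code should go through these.

#' @rdname accessors
#' @param x an alleleKDE object.
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))
#' @rdname accessors
#' @export
setGeneric("detectedAlleles", function(x) standardGeneric("detectedAlleles"))
#' @rdname accessors
#' @export
setGeneric("mutationNumber", function(x) standardGeneric("mutationNumber"))
#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname accessors
#' @export
setGeneric("multiplicities", function(x) standardGeneric("multiplicities"))
#' @rdname accessors
#' @export
setGeneric("freqMass", function(x) standardGeneric("freqMass"))
#' @rdname accessors
#' @export
setGeneric("perSequenceMass", function(x) standardGeneric("perSequenceMass"))
#' @rdname accessors
#' @export
setGeneric("selectedBandwidth", function(x) standardGeneric("selectedBandwidth"))
#' @rdname accessors
#' @export
setGeneric("piValue", function(x) standardGeneric("piValue"))

#' Accessors for alleleKDE objects
#'
#' Small read-only accessors: `alignmentLength()` and `nSequences()` on
#' alignments; `alleles()`, `alleleCounts()`, `sampleSize()` on allele
#' tables; `detectedAlleles()`, `mutationNumber()`, `coordinates()`,
#' `multiplicities()` on distance spaces; `freqMass()` /
#' `perSequenceMass()` on frequency estimates (masses on the natural
#' scale, exponentiated from the internal log representation);
#' `selectedBandwidth()` on CV results; `piValue()` on diversity results.
#'
#' @name accessors
#' @return the corresponding slot content on the natural scale.
NULL

#' @rdname accessors
setMethod("alignmentLength", "AlleleAlignment",
          function(x) nchar(x@seqs[1L]))
#' @rdname accessors
setMethod("nSequences", "AlleleAlignment", function(x) length(x@seqs))
#' @rdname accessors
setMethod("sequences", "AlleleAlignment", function(x) x@seqs)
#' @rdname accessors
setMethod("seqIds", "AlleleAlignment", function(x) x@ids)

#' @rdname accessors
setMethod("alleles", "AlleleTable", function(x) x@alleles)
#' @rdname accessors
setMethod("alleleCounts", "AlleleTable",
          function(x) stats::setNames(x@counts, x@alleles))
#' @rdname accessors
setMethod("sampleSize", "AlleleTable", function(x) x@n)

#' @rdname accessors
setMethod("sequences", "SequenceSpace", function(x) x@sequences)

#' @rdname accessors
setMethod("detectedAlleles", "DistanceSpace", function(x) x@detected)
#' @rdname accessors
setMethod("mutationNumber", "DistanceSpace", function(x) x@m)
#' @rdname accessors
setMethod("coordinates", "DistanceSpace", function(x) x@coords)
#' @rdname accessors
setMethod("multiplicities", "DistanceSpace", function(x) x@multiplicity)

#' @rdname accessors
setMethod("freqMass", "FrequencyEstimate", function(x) x@mass)
#' @rdname accessors
setMethod("perSequenceMass", "FrequencyEstimate", function(x) x@perSeq)

#' @rdname accessors
setMethod("selectedBandwidth", "CVResult", function(x) x@selectedP)

#' @rdname accessors
setMethod("piValue", "DiversityResult", function(x) x@pi)
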