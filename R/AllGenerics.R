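#' @include AllClasses.R
NULL

#' @rdname GeneModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("txId", function(x) standardGeneric("txId"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("cdsSpan", function(x) standardGeneric("cdsSpan"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("nExons", function(x) standardGeneric("nExons"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))

#' @rdname JunctionLibrary-accessors
#' @export
setGeneric("junctionInfo", function(x) standardGeneric("junctionInfo"))
#' @rdname JunctionLibrary-accessors
#' @export
setGeneric("junctionSeqs", function(x) standardGeneric("junctionSeqs"))
#' @rdname JunctionLibrary-accessors
#' @export
setGeneric("readLengthX", function(x) standardGeneric("readLengthX"))

#' @rdname FusionCandidate-accessors
#' @export
setGeneric("supportCount", function(x) standardGeneric("supportCount"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("duplicateCount", function(x) standardGeneric("duplicateCount"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("mismatchCount", function(x) standardGeneric("mismatchCount"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("pefs", function(x) standardGeneric("pefs"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("spanningReads", function(x) standardGeneric("spanningReads"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("predictedJunction", function(x) standardGeneric("predictedJunction"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("isoforms", function(x) standardGeneric("isoforms"))
#' @rdname FusionCandidate-accessors
#' @export
setGeneric("inFrame", function(x) standardGeneric("inFrame"))

#' Compute the paired-end fusion score of a candidate
#'
#' @param x a \code{\linkS4class{FusionCandidate}}.
#' @param ... passed to methods; typically \code{config}.
#' @return numeric PEFS score.
#' @export
setGeneric("computePEFS", function(x, ...) standardGeneric("computePEFS"))

#' Accessors for GeneModel
#'
#' @param x a \code{\linkS4class{GeneModel}}.
#' @return \code{geneId}, \code{txId}, \code{chrom}, \code{geneStrand}:
#'   character scalars; \code{exons}: an \code{IRanges} in transcript order;
#'   \code{cdsSpan}: an \code{IRanges} of length 0 or 1; \code{nExons},
#'   \code{txLength}: integers.
#' @name GeneModel-accessors
NULL

#' @rdname GeneModel-accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)
#' @rdname GeneModel-accessors
setMethod("txId", "GeneModel", function(x) x@txId)
#' @rdname GeneModel-accessors
setMethod("chrom", "GeneModel", function(x) x@chrom)
#' @rdname GeneModel-accessors
setMethod("geneStrand", "GeneModel", function(x) x@strand)
#' @rdname GeneModel-accessors
setMethod("exons", "GeneModel", function(x) x@exons)
#' @rdname GeneModel-accessors
setMethod("cdsSpan", "GeneModel", function(x) x@cds)
#' @rdname GeneModel-accessors
setMethod("nExons", "GeneModel", function(x) length(x@exons))
#' @rdname GeneModel-accessors
setMethod("txLength", "GeneModel", function(x) sum(width(x@exons)))

#' Accessors for JunctionLibrary
#'
#' @param x a \code{\linkS4class{JunctionLibrary}}.
#' @return \code{junctionInfo}: a \code{DataFrame} of junction provenance;
#'   \code{junctionSeqs}: the \code{DNAStringSet} of junction sequences;
#'   \code{readLengthX}: the read length the library was built for.
#' @name JunctionLibrary-accessors
NULL

#' @rdname JunctionLibrary-accessors
setMethod("junctionInfo", "JunctionLibrary", function(x) x@info)
#' @rdname JunctionLibrary-accessors
setMethod("junctionSeqs", "JunctionLibrary", function(x) x@sequences)
#' @rdname JunctionLibrary-accessors
setMethod("readLengthX", "JunctionLibrary", function(x) x@readLength)

#' Accessors for FusionCandidate
#'
#' \code{supportCount} is P (number of supporting pairs), \code{duplicateCount}
#' is D (supporting reads sharing a start coordinate with another supporting
#' read), \code{mismatchCount} is M (total mismatches across supporting reads).
#'
#' @param x a \code{\linkS4class{FusionCandidate}}.
#' @return integer counts, the numeric \code{pefs}, \code{DataFrame}s of
#'   spanning reads/isoforms, the integer(2) predicted junction, or the
#'   in-frame call.
#' @name FusionCandidate-accessors
NULL

#' @rdname FusionCandidate-accessors
setMethod("supportCount", "FusionCandidate", function(x) nrow(x@supportPairs))
#' @rdname FusionCandidate-accessors
setMethod("duplicateCount", "FusionCandidate",
          function(x) sum(x@supportPairs$dup1) + sum(x@supportPairs$dup2))
#' @rdname FusionCandidate-accessors
setMethod("mismatchCount", "FusionCandidate",
          function(x) sum(x@supportPairs$mm1) + sum(x@supportPairs$mm2))
#' @rdname FusionCandidate-accessors
setMethod("pefs", "FusionCandidate", function(x) x@pefs)
#' @rdname FusionCandidate-accessors
setMethod("spanningReads", "FusionCandidate", function(x) x@spanningReads)
#' @rdname FusionCandidate-accessors
setMethod("predictedJunction", "FusionCandidate", function(x) x@predictedJunction)
#' @rdname FusionCandidate-accessors
setMethod("isoforms", "FusionCandidate", function(x) x@isoforms)
#' @rdname FusionCandidate-accessors
setMethod("inFrame", "FusionCandidate", function(x) x@inFrame)
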