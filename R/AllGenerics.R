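# Generics for accessors shared across classes.

#' Extract the node-level annotation table
#' @param x an object
#' @return a \link[S4Vectors]{DataFrame}
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' Cluster membership of an SSN
#' @param x an \linkS4class{SSNGraph}
#' @return named integer vector of cluster numbers (1 = largest cluster)
#' @export
setGeneric("ssnClusters", function(x) standardGeneric("ssnClusters"))

#' Alignment-score threshold of an SSN
#' @param x an \linkS4class{SSNGraph}
#' @return numeric(1)
#' @export
setGeneric("ssnThreshold", function(x) standardGeneric("ssnThreshold"))

#' Selected threshold of a sweep
#' @param x a \linkS4class{ThresholdSweep}
#' @return numeric(1), NA if no threshold was selectable
#' @export
setGeneric("selectedThreshold",
           function(x) standardGeneric("selectedThreshold"))

#' Sweep table of a threshold sweep
#' @param x a \linkS4class{ThresholdSweep}
#' @return data.frame
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' Profile score matrix
#' @param x a \linkS4class{SequenceProfile}
#' @return numeric matrix (positions x 20)
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))

#' Fitted kinetic parameters
#' @param x a \linkS4class{KineticFit}
#' @return named numeric vector
#' @export
setGeneric("kineticParameters",
           function(x) standardGeneric("kineticParameters"))

#' Standard errors of fitted kinetic parameters
#' @param x a \linkS4class{KineticFit}
#' @return named numeric vector
#' @export
setGeneric("kineticSE", function(x) standardGeneric("kineticSE"))

#' Element counts of a formula
#' @param x a \linkS4class{ChemFormula}
#' @return named integer vector over C, H, D, N, O, S
#' @export
setGeneric("formulaCounts", function(x) standardGeneric("formulaCounts"))

#' Atom table of a structure
#' @param x a \linkS4class{Structure}
#' @return data.frame of atoms
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Features of a gene neighbourhood
#' @param x a \linkS4class{GeneNeighborhood}
#' @return a \link[GenomicRanges]{GRanges}
#' @export
setGeneric("neighborhoodFeatures",
           function(x) standardGeneric("neighborhoodFeatures"))

#' Pathway label of a classification call
#' @param x a \linkS4class{PathwayCall}
#' @return character(1)
#' @export
setGeneric("pathwayLabel", function(x) standardGeneric("pathwayLabel"))
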