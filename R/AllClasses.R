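# S4 class definitions for the package's central objects.

setOldClass("igraph")

#' SSNGraph: a thresholded sequence similarity network
#'
#' Nodes are proteins, edges are pairwise alignments whose alignment score
#' (AS, the negative decadic logarithm of an E-value-like quantity) is at or
#' above \code{threshold}.  Connected components are the SSN clusters,
#' numbered deterministically by decreasing size with ties broken by the
#' lexicographically smallest member id.
#'
#' @slot graph an \pkg{igraph} undirected graph with vertex attribute
#'   \code{name} and edge attribute \code{AS}.
#' @slot threshold numeric(1), the AS threshold applied.
#' @slot nodeData a \link[S4Vectors]{DataFrame} with one row per node
#'   (id, cluster, plus any annotation columns).
#' @exportClass SSNGraph
setClass("SSNGraph",
         representation(graph = "igraph",
                        threshold = "numeric",
                        nodeData = "DataFrame"))

setValidity("SSNGraph", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || is.na(object@threshold))
    msg <- c(msg, "'threshold' must be a single non-NA number")
  if (igraph::vcount(object@graph) != nrow(object@nodeData))
    msg <- c(msg, "nodeData must have one row per graph vertex")
  if (igraph::ecount(object@graph) > 0) {
    as <- igraph::edge_attr(object@graph, "AS")
    if (is.null(as) || any(as < object@threshold - 1e-9))
      msg <- c(msg, "every retained edge must have AS >= threshold")
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdSweep: an alignment-score threshold sweep over an SSN
#'
#' @slot table data.frame with one row per grid threshold: \code{threshold},
#'   \code{n_clusters}, \code{n_singletons}, \code{mean_degree},
#'   \code{mean_betweenness}.
#' @slot selected numeric(1); selected AS threshold, \code{NA} if none.
#' @slot status character(1): \code{"ok"}, \code{"no-plateau"} or
#'   \code{"degenerate"}.
#' @exportClass ThresholdSweep
setClass("ThresholdSweep",
         representation(table = "data.frame",
                        selected = "numeric",
                        status = "character"))

#' SequenceProfile: a position-specific scoring model
#'
#' Log-odds scores (log2 of pseudocount-regularised observed frequency over
#' background) per kept alignment column, built with Henikoff position-based
#' sequence weighting.  Columns with more than 50\% gaps are masked out.
#'
#' @slot scores numeric matrix, length x 20, columns named by residue.
#' @slot background numeric(20) background frequencies.
#' @slot pseudocount numeric(1), effective pseudo-observations added per
#'   column.
#' @slot msaIds character, ids of the sequences the model was built from.
#' @slot keptColumns integer, indices of the unmasked MSA columns.
#' @exportClass SequenceProfile
setClass("SequenceProfile",
         representation(scores = "matrix",
                        background = "numeric",
                        pseudocount = "numeric",
                        msaIds = "character",
                        keptColumns = "integer"))

setValidity("SequenceProfile", function(object) {
  msg <- character()
  if (ncol(object@scores) != 20L)
    msg <- c(msg, "score matrix must have 20 residue columns")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "all profile scores must be finite")
  if (nrow(object@scores) != length(object@keptColumns))
    msg <- c(msg, "profile length must equal number of kept columns")
  if (length(msg)) msg else TRUE
})

#' KineticDataset: initial-rate observations
#'
#' @slot conc numeric, substrate (or cofactor) concentrations in mM.
#' @slot rate numeric, initial rates (same length as \code{conc}).
#' @slot e0 numeric(1), enzyme concentration used, or \code{NA}.
#' @slot xLabel character(1), \code{"substrate"} or \code{"cofactor"}.
#' @slot label character(1), free-text substrate description.
#' @exportClass KineticDataset
setClass("KineticDataset",
         representation(conc = "numeric", rate = "numeric", e0 = "numeric",
                        xLabel = "character", label = "character"))

setValidity("KineticDataset", function(object) {
  msg <- character()
  if (length(object@conc) != length(object@rate))
    msg <- c(msg, "conc and rate must have equal length")
  if (any(object@conc <= 0))
    msg <- c(msg, "all concentrations must be > 0")
  if (length(msg)) msg else TRUE
})

#' KineticFit: a fitted saturation (Michaelis-Menten or activation) model
#'
#' @slot parameters named numeric: \code{vmax} and \code{km} (substrate
#'   mode) or \code{ka} (cofactor-activation mode).
#' @slot se named numeric standard errors from the linearised covariance at
#'   the optimum.
#' @slot e0 numeric(1) enzyme concentration (NA if unknown).
#' @slot kcat numeric(1) turnover number Vmax/e0 (NA if e0 unknown).
#' @slot kcatOverKm numeric(1) catalytic efficiency kcat/KM.
#' @slot residualSS numeric(1) residual sum of squares.
#' @slot converged logical(1).
#' @slot status character(1).
#' @slot data the \linkS4class{KineticDataset} that was fitted.
#' @exportClass KineticFit
setClass("KineticFit",
         representation(parameters = "numeric", se = "numeric",
                        e0 = "numeric", kcat = "numeric",
                        kcatOverKm = "numeric", residualSS = "numeric",
                        converged = "logical", status = "character",
                        data = "KineticDataset"))

setValidity("KineticFit", function(object) {
  msg <- character()
  p <- object@parameters
  if (!"vmax" %in% names(p))
    msg <- c(msg, "parameters must contain 'vmax'")
  if (!any(c("km", "ka") %in% names(p)))
    msg <- c(msg, "parameters must contain 'km' or 'ka'")
  if (object@converged && any(p <= 0))
    msg <- c(msg, "converged fits must have strictly positive parameters")
  if (length(msg)) msg else TRUE
})

#' ChemFormula: an elemental formula over C, H, D, N, O, S
#'
#' Deuterium is tracked separately from protium so that labelling
#' experiments can be represented exactly.
#'
#' @slot counts named integer over elements C, H, D, N, O, S (all >= 0).
#' @slot charge integer(1), net charge of the species.
#' @exportClass ChemFormula
setClass("ChemFormula",
         representation(counts = "integer", charge = "integer"))

setValidity("ChemFormula", function(object) {
  msg <- character()
  if (!identical(names(object@counts), c("C", "H", "D", "N", "O", "S")))
    msg <- c(msg, "counts must be named C, H, D, N, O, S in that order")
  if (any(object@counts < 0L))
    msg <- c(msg, "element counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FragmentIon: a fragment with declared carbon coverage
#'
#' \code{coverage} declares which carbons of the parent sugar skeleton the
#' fragment retains; it is input data (e.g. transcribed from a fragmentation
#' scheme), not computed from chemistry.
#'
#' @slot label character(1).
#' @slot formula a \linkS4class{ChemFormula} (typically an anion).
#' @slot coverage character subset of \code{C1..C6}.
#' @exportClass FragmentIon
setClass("FragmentIon",
         representation(label = "character", formula = "ChemFormula",
                        coverage = "character"))

setValidity("FragmentIon", function(object) {
  ok <- object@coverage %in% paste0("C", 1:6)
  if (all(ok)) TRUE else "coverage must be a subset of C1..C6"
})

#' Structure: an atomic coordinate set
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety} (atom
#'   name), \code{elesy} (element symbol), \code{resid} (residue name),
#'   \code{chain}, \code{resno}, \code{x}, \code{y}, \code{z}, \code{o}
#'   (occupancy) and \code{het} (logical, hetero/ligand record).
#' @slot title character(1).
#' @exportClass Structure
setClass("Structure",
         representation(atoms = "data.frame", title = "character"))

setValidity("Structure", function(object) {
  need <- c("eleno", "elety", "elesy", "resid", "chain", "resno",
            "x", "y", "z", "o", "het")
  msg <- character()
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(object@atoms) &&
           !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' InterfaceReport: buried surface area of a two-chain interface
#'
#' Buried area is the total over both protomers:
#' SASA(A) + SASA(B) - SASA(AB).
#'
#' @slot sasaA,sasaB,sasaDimer numeric(1), solvent-accessible surface areas
#'   in square Angstroms.
#' @slot buriedTotal numeric(1), A + B - AB.
#' @slot buriedFractionOfMonomer numeric(1), percent of the summed monomer
#'   surface buried.
#' @exportClass InterfaceReport
setClass("InterfaceReport",
         representation(sasaA = "numeric", sasaB = "numeric",
                        sasaDimer = "numeric", buriedTotal = "numeric",
                        buriedFractionOfMonomer = "numeric"))

setValidity("InterfaceReport", function(object) {
  msg <- character()
  if (object@buriedTotal < -1e-6)
    msg <- c(msg, "buried area must be >= 0")
  if (object@buriedFractionOfMonomer < -1e-9 ||
      object@buriedFractionOfMonomer > 100 + 1e-9)
    msg <- c(msg, "buried fraction must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' GeneNeighborhood: the ORF window around a seed gene
#'
#' @slot features a \link[GenomicRanges]{GRanges} of the window's gene
#'   features, in genomic order, with metadata columns \code{locus_id},
#'   \code{domain_tags} and \code{product}.
#' @slot seed character(1), locus id of the seed gene.
#' @slot k integer(1), requested half-window size in ORFs.
#' @exportClass GeneNeighborhood
setClass("GeneNeighborhood",
         representation(features = "GRanges", seed = "character",
                        k = "integer"))

#' PathwayCall: the pathway classification of a neighbourhood
#'
#' @slot pathway character(1): a pathway label, \code{"unclassified"}, or
#'   \code{"ambiguous"}.
#' @slot status character(1): \code{"ok"}, \code{"unclassified"} or
#'   \code{"ambiguous"}.
#' @slot matchedLoci named list: per satisfied rule group, the locus ids
#'   that matched.
#' @slot candidates character, all satisfied pathways (for ambiguous calls).
#' @slot gh31Present,gh188Present logical(1) SQase-family presence flags.
#' @exportClass PathwayCall
setClass("PathwayCall",
         representation(pathway = "character", status = "character",
                        matchedLoci = "list", candidates = "character",
                        gh31Present = "logical", gh188Present = "logical"))
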