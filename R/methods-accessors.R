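# Accessor and show methods.

#' @describeIn SSNGraph node annotation table
#' @param x an SSNGraph
#' @export
setMethod("nodeData", "SSNGraph", function(x) x@nodeData)

#' @describeIn SSNGraph cluster membership (1 = largest cluster)
#' @export
setMethod("ssnClusters", "SSNGraph", function(x)
  setNames(x@nodeData$cluster, x@nodeData$id))

#' @describeIn SSNGraph the applied AS threshold
#' @export
setMethod("ssnThreshold", "SSNGraph", function(x) x@threshold)

setMethod("show", "SSNGraph", function(object) {
  cl <- object@nodeData$cluster
  cat("SSNGraph with", igraph::vcount(object@graph), "nodes,",
      igraph::ecount(object@graph), "edges at AS threshold",
      format(object@threshold), "\n")
  cat("  clusters:", max(c(cl, 0L)), " singletons:",
      sum(tabulate(cl) == 1L), "\n")
})

#' @describeIn ThresholdSweep the selected AS threshold (NA if none)
#' @param x a ThresholdSweep
#' @export
setMethod("selectedThreshold", "ThresholdSweep", function(x) x@selected)

#' @describeIn ThresholdSweep the per-threshold sweep table
#' @export
setMethod("sweepTable", "ThresholdSweep", function(x) x@table)

setMethod("show", "ThresholdSweep", function(object) {
  cat("ThresholdSweep over", nrow(object@table), "grid points; selected =",
      ifelse(is.na(object@selected), "none", format(object@selected)),
      sprintf("(%s)\n", object@status))
})

#' @describeIn SequenceProfile the position x residue score matrix
#' @param x a SequenceProfile
#' @export
setMethod("profileScores", "SequenceProfile", function(x) x@scores)

setMethod("length", "SequenceProfile", function(x) nrow(x@scores))

setMethod("show", "SequenceProfile", function(object) {
  cat("SequenceProfile of length", nrow(object@scores), "positions, built",
      "from", length(object@msaIds), "sequences",
      sprintf("(pseudocount %.2f)\n", object@pseudocount))
})

setMethod("length", "KineticDataset", function(x) length(x@conc))

setMethod("show", "KineticDataset", function(object) {
  cat(sprintf("KineticDataset '%s': %d rates over %s %g-%g mM\n",
              object@label, length(object@conc), object@xLabel,
              min(object@conc), max(object@conc)))
})

#' @describeIn KineticFit fitted parameters (vmax and km or ka)
#' @param x a KineticFit
#' @export
setMethod("kineticParameters", "KineticFit", function(x) x@parameters)

#' @describeIn KineticFit standard errors of the fitted parameters
#' @export
setMethod("kineticSE", "KineticFit", function(x) x@se)

setMethod("show", "KineticFit", function(object) {
  p <- object@parameters
  se <- object@se
  kname <- intersect(c("km", "ka"), names(p))
  cat(sprintf("KineticFit (%s): Vmax = %.4g +/- %.2g; %s = %.4g +/- %.2g mM\n",
              object@status, p[["vmax"]], se[["vmax"]],
              toupper(kname), p[[kname]], se[[kname]]))
  if (is.finite(object@kcat))
    cat(sprintf("  kcat = %.4g s-1; kcat/KM = %.4g mM-1 s-1\n",
                object@kcat, object@kcatOverKm))
})

#' @describeIn ChemFormula element counts
#' @param x a ChemFormula
#' @export
setMethod("formulaCounts", "ChemFormula", function(x) x@counts)

setMethod("show", "ChemFormula", function(object) {
  cts <- object@counts[object@counts > 0L]
  txt <- paste0(names(cts), ifelse(cts > 1L, cts, ""), collapse = "")
  ch <- object@charge
  chTxt <- if (ch == 0L) "" else
    paste0(" [", if (abs(ch) > 1L) abs(ch) else "",
           if (ch > 0L) "+" else "-", "]")
  cat("ChemFormula ", txt, chTxt, "\n", sep = "")
})

setMethod("show", "FragmentIon", function(object) {
  cat(sprintf("FragmentIon '%s' (coverage %s), nominal m/z %d\n",
              object@label, paste(object@coverage, collapse = ","),
              formulaMass(object@formula, "nominal")))
})

#' @describeIn Structure atom table
#' @param x a Structure
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure '%s': %d atoms, %d chains (%s)%s\n",
              object@title, nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              if (any(a$het)) sprintf(", %d hetero atoms", sum(a$het))
              else ""))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf(paste0("InterfaceReport: buried %.0f A^2 total ",
                     "(%.1f%% of summed monomer surface; %.0f A^2 per side)\n"),
              object@buriedTotal, object@buriedFractionOfMonomer,
              object@buriedTotal / 2))
})

#' @describeIn GeneNeighborhood features in genomic order
#' @param x a GeneNeighborhood
#' @export
setMethod("neighborhoodFeatures", "GeneNeighborhood", function(x) x@features)

setMethod("length", "GeneNeighborhood", function(x) length(x@features))

setMethod("show", "GeneNeighborhood", function(object) {
  cat(sprintf("GeneNeighborhood around '%s': %d ORFs (k = %d)\n",
              object@seed, length(object@features), object@k))
})

#' @describeIn PathwayCall the assigned pathway label
#' @param x a PathwayCall
#' @export
setMethod("pathwayLabel", "PathwayCall", function(x) x@pathway)

setMethod("show", "PathwayCall", function(object) {
  cat(sprintf("PathwayCall: %s (%s); GH31 %s, GH188 %s\n",
              object@pathway, object@status,
              ifelse(object@gh31Present, "present", "absent"),
              ifelse(object@gh188Present, "present", "absent")))
})
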