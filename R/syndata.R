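# Synthetic-data generators: protein families, decoys, annotated genomes,
# initial-rate kinetics and toy coordinate sets.  Every generator is
# deterministic for a fixed seed and leaves the caller's RNG state intact.

#' Generate a synthetic protein family
#'
#' Draws a random ancestor of the given length and derives \code{nMembers}
#' sequences from it by i.i.d. substitutions, uniform over the 19
#' alternative residues.  The per-site substitution probability \eqn{p} is
#' solved from the target mean pairwise identity \eqn{t} by inverting the
#' expected-identity relation for two independently mutated copies,
#' \eqn{t = (1-p)^2 + p^2/19}, so that the realised mean pairwise identity
#' is close to \code{targetIdentity} (within a few points for lengths of
#' 200 residues and more).
#'
#' Identities below the 5\% floor attainable under this model are clamped
#' to the maximal mutation rate.
#'
#' @param nMembers integer, number of family members (>= 1).
#' @param targetIdentity target mean pairwise identity, percent in (0, 100].
#' @param length sequence length in residues (>= 30).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param prefix id prefix for member names.
#' @param taxonomy optional character(1) taxonomy label stored in
#'   \code{mcols}.
#' @param ancestor optional ancestor sequence string; when supplied (e.g.
#'   a founder derived with \code{\link{mutateSequence}} to control
#'   between-family identity) it is used instead of a random draw and
#'   \code{length} is taken from it.
#' @return an \link[Biostrings]{AAStringSet} named \code{<prefix>_1..n} with
#'   metadata columns \code{family} and \code{taxonomy}.
#' @examples
#' fam <- makeFamily(5, 80, 100, seed = 1)
#' @export
makeFamily <- function(nMembers, targetIdentity, length, seed,
                       prefix = "fam", taxonomy = prefix,
                       ancestor = NULL) {
  if (!is.null(ancestor)) length <- nchar(ancestor)
  stopifnotScalarNumber(nMembers, "nMembers", positive = TRUE)
  stopifnotScalarNumber(length, "length", positive = TRUE)
  if (!is.numeric(targetIdentity) || length(targetIdentity) != 1L ||
      targetIdentity <= 0 || targetIdentity > 100)
    stop("'targetIdentity' must be a percent in (0, 100]", call. = FALSE)
  if (length < 30) stop("'length' must be >= 30", call. = FALSE)

  t <- targetIdentity / 100
  disc <- 1 - (20 / 19) * (1 - t)
  p <- if (disc <= 0) 19 / 20 else (19 / 20) * (1 - sqrt(disc))

  withSeed(seed, {
    anc <- if (is.null(ancestor)) sample(AA_ALPHABET20, length,
                                         replace = TRUE)
    else strsplit(ancestor, "")[[1]]
    seqs <- vapply(seq_len(nMembers), function(i) {
      s <- anc
      hit <- runif(length) < p
      if (any(hit)) {
        # uniform over the 19 non-ancestral residues
        repl <- vapply(which(hit), function(j)
          sample(setdiff(AA_ALPHABET20, s[j]), 1L), character(1))
        s[hit] <- repl
      }
      paste(s, collapse = "")
    }, character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- paste0(prefix, "_", seq_len(nMembers))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      family = prefix, taxonomy = taxonomy)
    S4Vectors::metadata(out) <- list(ancestor = paste(anc, collapse = ""),
                                     substitution_prob = p)
    out
  })
}

#' Mutate a sequence to a target identity
#'
#' Substitutes each site with probability \code{1 - identity/100}
#' (uniform over the 19 alternatives), so the expected identity of the
#' result to the input is \code{identity} percent.  Useful for deriving
#' family founders at a controlled between-family identity.
#'
#' @param sequence protein sequence string.
#' @param identity target percent identity to the input, in (0, 100].
#' @param seed RNG seed.
#' @return character(1) mutated sequence.
#' @export
mutateSequence <- function(sequence, identity, seed) {
  if (identity <= 0 || identity > 100)
    stop("'identity' must be in (0, 100]", call. = FALSE)
  p <- 1 - identity / 100
  withSeed(seed, {
    s <- strsplit(sequence, "")[[1]]
    hit <- runif(length(s)) < p
    if (any(hit))
      s[hit] <- vapply(which(hit), function(j)
        sample(setdiff(AA_ALPHABET20, s[j]), 1L), character(1))
    paste(s, collapse = "")
  })
}

#' Generate shuffled decoy sequences
#'
#' Decoys are Fisher-Yates shuffles of source sequences, preserving length
#' and residue composition — the null model used for E-value calibration.
#'
#' @param pool an \link[Biostrings]{AAStringSet} of source sequences
#'   (recycled if \code{n} exceeds its length).
#' @param n number of decoys.
#' @param seed integer RNG seed.
#' @param prefix id prefix.
#' @return an \link[Biostrings]{AAStringSet} of \code{n} decoys.
#' @export
makeDecoys <- function(pool, n, seed, prefix = "decoy") {
  if (!length(pool)) stop("'pool' must be non-empty", call. = FALSE)
  withSeed(seed, {
    src <- rep(seq_along(pool), length.out = n)
    seqs <- vapply(src, function(i) {
      ch <- strsplit(as.character(pool[[i]]), "")[[1]]
      paste(sample(ch), collapse = "")
    }, character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- paste0(prefix, "_", seq_len(n))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      family = "decoy", taxonomy = "decoy")
    out
  })
}

# Signature gene complements per pathway; tags match the shipped rule file.
#' @noRd
pathwaySignatureTags <- function() {
  list(
    "sulfo-EMP" = c("SQ_isomerase", "SF_kinase", "SFP_aldolase",
                    "SLA_dehydrogenase"),
    "sulfo-ED"  = c("SQ_dehydrogenase", "SGL_lactonase", "SG_dehydratase",
                    "KDSG_aldolase"),
    "sulfo-SFT" = "SF_transaldolase",
    "sulfo-SMO" = "SQ_monooxygenase",
    "sulfo-SDO" = "SQ_dioxygenase")
}

#' Generate a synthetic annotated genome
#'
#' Lays out non-overlapping ORFs on a single contig (1-based inclusive
#' coordinates, explicit strand, GenBank convention) with a seed SQase gene
#' in the middle.  When \code{pathway} is not \code{"none"}, the pathway's
#' signature genes are placed within 10 ORFs of the seed so that
#' \code{\link{classifyNeighborhood}} recovers the generating label.
#' Background genes carry decoy domain tags (\code{DUF}xxxx).
#'
#' @param pathway one of \code{"sulfo-EMP"}, \code{"sulfo-ED"},
#'   \code{"sulfo-SFT"}, \code{"sulfo-SMO"}, \code{"sulfo-SDO"},
#'   \code{"none"}.
#' @param nBackground number of background genes.
#' @param includeGH31 place a GH31 SQase gene in the neighbourhood?
#' @param includeGH188 tag the seed gene as a GH188 SQase? (default TRUE)
#' @param seed integer RNG seed.
#' @param genomeId genome identifier used for the contig name and loci.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{locus_id}, \code{domain_tags} (comma-separated), \code{product}
#'   and \code{genome_id}; the seed gene has product \code{"sqgA"}.
#' @examples
#' g <- makeGenome("sulfo-EMP", nBackground = 20, seed = 3)
#' @export
makeGenome <- function(pathway = c("sulfo-EMP", "sulfo-ED", "sulfo-SFT",
                                   "sulfo-SMO", "sulfo-SDO", "none"),
                       nBackground = 30, includeGH31 = FALSE,
                       includeGH188 = TRUE, seed, genomeId = "synth") {
  pathway <- match.arg(pathway)
  stopifnotScalarNumber(nBackground, "nBackground")

  sig <- if (pathway == "none") character() else
    pathwaySignatureTags()[[pathway]]

  withSeed(seed, {
    extras <- c(sig, if (includeGH31) "GH31")
    nGenes <- nBackground + 1L + length(extras)
    seedIdx <- max(1L, nBackground %/% 2L + 1L)

    # slots in the +/-10 window (excluding the seed slot itself)
    windowSlots <- setdiff(
      seq(max(1L, seedIdx - 10L), min(nGenes, seedIdx + 10L)), seedIdx)
    if (length(extras) > length(windowSlots))
      stop("window too small to place all signature genes", call. = FALSE)
    sigSlots <- sort(sample(windowSlots, length(extras)))

    tags <- character(nGenes)
    prods <- character(nGenes)
    decoyTags <- paste0("DUF", sample(1000:9999, nGenes, replace = TRUE))
    for (i in seq_len(nGenes)) {
      if (i == seedIdx) {
        tags[i] <- if (includeGH188) "GH188" else "SDR_like"
        prods[i] <- "sqgA"
      } else if (i %in% sigSlots) {
        tag <- extras[match(i, sigSlots)]
        tags[i] <- tag
        prods[i] <- tolower(gsub("_", " ", tag))
      } else {
        tags[i] <- decoyTags[i]
        prods[i] <- "hypothetical protein"
      }
    }

    lens <- sample(300:3000, nGenes, replace = TRUE)
    gaps <- sample(20:200, nGenes, replace = TRUE)
    starts <- cumsum(c(1L, head(lens + gaps, -1L)))
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), nGenes, replace = TRUE)

    gr <- GenomicRanges::GRanges(
      seqnames = paste0(genomeId, "_contig1"),
      ranges = IRanges::IRanges(start = starts, end = ends),
      strand = strands)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      locus_id = sprintf("%s_%04d", genomeId, seq_len(nGenes)),
      domain_tags = tags, product = prods, genome_id = genomeId)
    S4Vectors::metadata(gr) <- list(pathway = pathway,
                                    seed_locus = gr$locus_id[seedIdx])
    gr
  })
}

#' Constructor for initial-rate datasets
#'
#' @param conc concentrations in mM (substrate or cofactor).
#' @param rate initial rates.
#' @param e0 enzyme concentration (same units as Vmax numerator), or NA.
#' @param xLabel \code{"substrate"} or \code{"cofactor"}.
#' @param label free-text description.
#' @return a \linkS4class{KineticDataset}
#' @export
kineticDataset <- function(conc, rate, e0 = NA_real_,
                           xLabel = c("substrate", "cofactor"),
                           label = "") {
  new("KineticDataset", conc = as.numeric(conc), rate = as.numeric(rate),
      e0 = as.numeric(e0), xLabel = match.arg(xLabel), label = label)
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' Rates follow \eqn{v_i = V_{max} s_i / (K_M + s_i) + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}; \code{noiseSd = 0} gives the exact
#' curve.  The same generator serves cofactor-activation data (set
#' \code{xLabel = "cofactor"}; the half-saturation constant is then the
#' activation constant KA).
#'
#' @param vmax limiting rate (> 0).
#' @param km half-saturation constant in mM (> 0).
#' @param sValues concentration grid in mM (all > 0).
#' @param noiseSd Gaussian noise standard deviation, in rate units (>= 0).
#' @param seed RNG seed (only used when \code{noiseSd > 0}).
#' @param e0,xLabel,label passed to \code{\link{kineticDataset}}.
#' @return a \linkS4class{KineticDataset}
#' @examples
#' d <- makeKineticData(1, 3.7, sValues = c(0.5, 1, 2, 4, 8, 16))
#' @export
makeKineticData <- function(vmax, km, sValues, noiseSd = 0, seed = NULL,
                            e0 = NA_real_, xLabel = "substrate",
                            label = "synthetic") {
  stopifnotScalarNumber(vmax, "vmax", positive = TRUE)
  stopifnotScalarNumber(km, "km", positive = TRUE)
  if (any(sValues <= 0)) stop("all sValues must be > 0", call. = FALSE)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  v <- vmax * sValues / (km + sValues)
  if (noiseSd > 0)
    v <- withSeed(seed, v + rnorm(length(sValues), 0, noiseSd))
  kineticDataset(sValues, v, e0 = e0, xLabel = xLabel, label = label)
}

#' Generate toy coordinate sets with known geometry
#'
#' Fixtures with analytically known distances, rotations and surface areas:
#' \describe{
#'   \item{\code{"single-atom"}}{one carbon-like atom; SASA is
#'     \eqn{4\pi(r + probe)^2} exactly. Params: \code{radiusElement}.}
#'   \item{\code{"sphere-pair"}}{two atoms separated by \code{separation}
#'     Angstroms along z.}
#'   \item{\code{"helix-dimer"}}{two parallel CA-only helical chains A and B
#'     with axis separation \code{separation} (default 6) and
#'     \code{nResidues} (default 18) per chain.}
#'   \item{\code{"rotated-copy"}}{a list of two structures: a four-atom
#'     residue (N, CA, CB, CG) and a copy with CG rotated by \code{angle}
#'     degrees about the CA-CB bond axis.}
#'   \item{\code{"cage"}}{a central atom fully enclosed by a shell of
#'     \code{nShell} atoms at radius \code{shellRadius}; the central atom's
#'     SASA is 0.}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param separation,angle,nResidues,nShell,shellRadius,radiusElement
#'   kind-specific parameters.
#' @return a \linkS4class{Structure}, or a list of two for
#'   \code{"rotated-copy"}.
#' @export
makeToyStructure <- function(kind = c("sphere-pair", "helix-dimer",
                                      "rotated-copy", "cage", "single-atom"),
                             separation = 3.4, angle = 72, nResidues = 18,
                             nShell = 120, shellRadius = 3.0,
                             radiusElement = "C") {
  kind <- match.arg(kind)
  mk <- function(df, title) {
    df$eleno <- seq_len(nrow(df))
    df$o <- 1
    if (is.null(df$het)) df$het <- FALSE
    new("Structure",
        atoms = df[, c("eleno", "elety", "elesy", "resid", "chain",
                       "resno", "x", "y", "z", "o", "het")],
        title = title)
  }
  switch(kind,
    "single-atom" = mk(data.frame(
      elety = radiusElement, elesy = radiusElement, resid = "TOY",
      chain = "A", resno = 1L, x = 0, y = 0, z = 0), "single-atom"),
    "sphere-pair" = mk(data.frame(
      elety = c("C1", "C2"), elesy = "C", resid = "TOY", chain = "A",
      resno = c(1L, 2L), x = 0, y = 0, z = c(0, separation)),
      "sphere-pair"),
    "helix-dimer" = {
      i <- seq_len(nResidues)
      # idealised CA trace: radius 2.3 A, 100 deg turn, 1.5 A rise
      th <- (i - 1) * 100 * pi / 180
      zi <- (i - 1) * 1.5
      a <- data.frame(elety = "CA", elesy = "C", resid = "ALA", chain = "A",
                      resno = i, x = 2.3 * cos(th), y = 2.3 * sin(th),
                      z = zi)
      b <- a
      b$chain <- "B"
      b$x <- b$x + separation
      mk(rbind(a, b), "helix-dimer")
    },
    "rotated-copy" = {
      base <- data.frame(
        elety = c("N", "CA", "CB", "CG"), elesy = c("N", "C", "C", "C"),
        resid = "TYR", chain = "A", resno = 1L,
        x = c(-1.45, 0, 0, 1.42),
        y = c(0.50, 0, 0, 0.53),
        z = c(0, 0, 1.53, 2.10))
      rot <- base
      # rotate CG about the CA-CB axis (the z axis here) by `angle`
      ca <- c(0, 0, 0)
      ax <- c(0, 0, 1)
      th <- angle * pi / 180
      v <- as.numeric(rot[4, c("x", "y", "z")]) - c(0, 0, 0)
      # Rodrigues rotation about unit axis `ax`
      vrot <- v * cos(th) + pracmaCross(ax, v) * sin(th) +
        ax * sum(ax * v) * (1 - cos(th))
      rot[4, c("x", "y", "z")] <- vrot
      list(reference = mk(base, "rotated-copy/ref"),
           rotated = mk(rot, "rotated-copy/rot"))
    },
    "cage" = {
      pts <- fibonacciSphere(nShell)
      shell <- data.frame(
        elety = "C", elesy = "C", resid = "TOY", chain = "B",
        resno = seq_len(nShell) + 1L,
        x = shellRadius * pts[, 1], y = shellRadius * pts[, 2],
        z = shellRadius * pts[, 3])
      centre <- data.frame(elety = "C", elesy = "C", resid = "TOY",
                           chain = "A", resno = 1L, x = 0, y = 0, z = 0)
      mk(rbind(centre, shell), "cage")
    })
}

# cross product (pracma has one, but three lines keep geometry local)
#' @noRd
pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
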