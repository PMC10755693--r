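# Elemental-formula mass arithmetic for sulfoquinovose (SQ) species,
# deuterium substitution, fragment-ion bookkeeping and constraint
# propagation to infer the labelled carbon position from observed m/z
# shift patterns.

# nominal (integer mass number) and monoisotopic masses per element
#' @noRd
ELEMENT_MASSES <- list(
  nominal = c(C = 12, H = 1, D = 2, N = 14, O = 16, S = 32),
  monoisotopic = c(C = 12.0, H = 1.00782503207, D = 2.0141017778,
                   N = 14.0030740048, O = 15.9949146196,
                   S = 31.97207100))

#' @noRd
ELECTRON_MASS <- 0.000548579909

#' Construct an elemental formula
#'
#' Accepts a Hill-style formula string over C, H, D, N, O, S (e.g.
#' \code{"C6H12O8S"}) or a named count vector.  Deuterium (\code{D}) is
#' tracked separately from protium.
#'
#' @param x formula string or named numeric vector.
#' @param charge net charge (default 0).
#' @return a \linkS4class{ChemFormula}
#' @examples
#' sq <- chemFormula("C6H12O8S")   # sulfoquinovose
#' @export
chemFormula <- function(x, charge = 0L) {
  counts <- setNames(integer(6), c("C", "H", "D", "N", "O", "S"))
  if (is.character(x)) {
    if (nchar(x)) {
      m <- gregexpr("([CHDNOS])([0-9]*)", x)[[1]]
      parts <- regmatches(x, gregexpr("([CHDNOS])([0-9]*)", x))[[1]]
      if (sum(nchar(parts)) != nchar(x))
        stop("unknown element in formula '", x, "'", call. = FALSE)
      for (p in parts) {
        el <- substr(p, 1, 1)
        n <- if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L
        counts[el] <- counts[el] + n
      }
    }
  } else if (is.numeric(x)) {
    bad <- setdiff(names(x), names(counts))
    if (length(bad))
      stop("unknown element(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    counts[names(x)] <- as.integer(x)
  } else stop("'x' must be a formula string or named counts",
              call. = FALSE)
  new("ChemFormula", counts = counts, charge = as.integer(charge))
}

#' Mass (or m/z) of a formula
#'
#' Nominal mode sums integer mass numbers; monoisotopic mode sums standard
#' isotope masses and accounts for electrons gained or lost by the charge
#' state.  For charged species the value returned is m/z
#' (mass over \code{|charge|}); for neutral species it is the plain mass.
#'
#' @param formula a \linkS4class{ChemFormula}.
#' @param mode \code{"nominal"} or \code{"monoisotopic"}.
#' @return numeric(1)
#' @examples
#' formulaMass(deprotonate(chemFormula("C6H12O8S")), "nominal")  # 243
#' @export
formulaMass <- function(formula, mode = c("nominal", "monoisotopic")) {
  stopifnot(is(formula, "ChemFormula"))
  mode <- match.arg(mode)
  masses <- ELEMENT_MASSES[[mode]]
  m <- sum(masses[names(formula@counts)] * formula@counts)
  z <- formula@charge
  if (mode == "monoisotopic")
    m <- m - z * ELECTRON_MASS   # anion gains electrons
  if (z != 0L) m / abs(z) else m
}

#' Deprotonate a formula to its [M-H]- anion
#'
#' @param formula a neutral \linkS4class{ChemFormula} with at least one H.
#' @return a \linkS4class{ChemFormula} with one H fewer and charge -1.
#' @export
deprotonate <- function(formula) {
  stopifnot(is(formula, "ChemFormula"))
  if (formula@counts[["H"]] < 1L)
    stop("no proton to remove", call. = FALSE)
  cts <- formula@counts
  cts[["H"]] <- cts[["H"]] - 1L
  new("ChemFormula", counts = cts, charge = formula@charge - 1L)
}

#' Replace protium by deuterium
#'
#' Replaces \code{n} H atoms by \code{n} D atoms; the nominal mass
#' increases by exactly \code{n}.
#'
#' @param formula a \linkS4class{ChemFormula}.
#' @param n number of positions to label (0 <= n <= H count).
#' @return a \linkS4class{ChemFormula}
#' @export
deuterate <- function(formula, n = 1L) {
  stopifnot(is(formula, "ChemFormula"))
  n <- as.integer(n)
  if (n < 0L || n > formula@counts[["H"]])
    stop("cannot label ", n, " positions: only ",
         formula@counts[["H"]], " H present", call. = FALSE)
  cts <- formula@counts
  cts[["H"]] <- cts[["H"]] - n
  cts[["D"]] <- cts[["D"]] + n
  new("ChemFormula", counts = cts, charge = formula@charge)
}

#' Construct a fragment ion
#'
#' @param label fragment name.
#' @param formula a \linkS4class{ChemFormula} (charged for ions).
#' @param coverage carbons of the parent sugar retained by the fragment, a
#'   subset of \code{"C1".."C6"}.
#' @return a \linkS4class{FragmentIon}
#' @export
fragmentIon <- function(label, formula, coverage) {
  if (is.character(formula)) formula <- chemFormula(formula, charge = -1L)
  new("FragmentIon", label = label, formula = formula,
      coverage = as.character(coverage))
}

#' Apply neutral losses to a fragment ion
#'
#' Sequential elemental subtraction; masses follow from the updated
#' formula.  Negative element counts (a loss the ion cannot afford) are an
#' error.
#'
#' @param ion a \linkS4class{FragmentIon}.
#' @param losses list of neutral-loss formulas (\linkS4class{ChemFormula}
#'   or strings such as \code{"H2O"}, \code{"HDO"}).
#' @return a \linkS4class{FragmentIon} with the losses subtracted.
#' @examples
#' sqD <- deuterate(chemFormula("C6H12O8S"), 1)
#' ion <- fragmentIon("[M-H]-", deprotonate(sqD), paste0("C", 1:6))
#' formulaMass(applyLosses(ion, list("HDO", "H2O"))@formula)  # 207
#' @export
applyLosses <- function(ion, losses) {
  stopifnot(is(ion, "FragmentIon"))
  cts <- ion@formula@counts
  for (l in losses) {
    lf <- if (is.character(l)) chemFormula(l) else l
    cts <- cts - lf@counts
    if (any(cts < 0L))
      stop("loss ", paste(names(lf@counts)[lf@counts > 0], collapse = ""),
           " not subtractable: negative element count", call. = FALSE)
  }
  new("FragmentIon", label = ion@label,
      formula = new("ChemFormula", counts = cts,
                    charge = ion@formula@charge),
      coverage = ion@coverage)
}

#' Reference fragment set for SQ [M-H]- ions
#'
#' The molecular ion (nominal m/z 243) plus the sulfonate-retaining
#' fragment series at nominal m/z 183, 153 and 123.  The elemental
#' compositions and carbon-coverage sets of the fragment series are
#' fixture data transcribed from a CID fragmentation scheme (not computed
#' from fragmentation chemistry): the three fragments jointly cover
#' C3-C6, which is what makes them diagnostic for label positions on the
#' lower half of the sugar.
#'
#' @return named list of \linkS4class{FragmentIon}s:
#'   \code{molecular} (C1-C6), \code{frag183} (C3-C6),
#'   \code{frag153} (C4-C6), \code{frag123} (C5-C6).
#' @export
sqFragmentIons <- function() {
  list(
    molecular = fragmentIon("[M-H]-",
                            deprotonate(chemFormula("C6H12O8S")),
                            paste0("C", 1:6)),
    frag183 = fragmentIon("frag183",
                          chemFormula("C4H7O6S", charge = -1L),
                          paste0("C", 3:6)),
    frag153 = fragmentIon("frag153",
                          chemFormula("C3H5O5S", charge = -1L),
                          paste0("C", 4:6)),
    frag123 = fragmentIon("frag123",
                          chemFormula("C2H3O4S", charge = -1L),
                          paste0("C", 5:6)))
}

#' A labelled-versus-unlabelled fragment observation
#'
#' @param fragment fragment label (must match a supplied fragment ion).
#' @param deltaMz integer m/z shift between labelled and unlabelled
#'   spectra (0 or 1 for single-label experiments).
#' @param lossCarbons carbons participating in neutral losses on the
#'   fragmentation route to this ion (character vector, or NULL when no
#'   loss is involved).
#' @return one-row data.frame
#' @export
labelObservation <- function(fragment, deltaMz, lossCarbons = NULL) {
  if (!deltaMz %in% c(0L, 1L))
    stop("deltaMz must be 0 or 1 for single-label experiments",
         call. = FALSE)
  data.frame(fragment = fragment, delta_mz = as.integer(deltaMz),
             loss_carbons = if (is.null(lossCarbons)) NA_character_
             else paste(lossCarbons, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Infer the labelled carbon position from fragment shift patterns
#'
#' Single-label constraint propagation over the six carbon hypotheses:
#' \itemize{
#'   \item a shifted ion (\eqn{\Delta m/z = 1}) restricts the label to the
#'     carbons the fragment retains (minus any carbons whose hydrogens
#'     left in neutral losses);
#'   \item an unshifted ion (\eqn{\Delta m/z = 0}) with no losses excludes
#'     every carbon in its coverage;
#'   \item an unshifted ion reached through a loss pathway (labelled and
#'     unlabelled precursors converge on the same product m/z) restricts
#'     the label to carbons outside the coverage or inside the loss set.
#' }
#' The result is the intersection over all observations.  Only
#' carbon-bound (non-exchangeable) positions are considered: OH and SO3H
#' protons exchange back in water and cannot carry the label.
#'
#' @param fragments named list of \linkS4class{FragmentIon}s (e.g.
#'   \code{\link{sqFragmentIons}()}).
#' @param observations data.frame of \code{\link{labelObservation}} rows.
#' @return list with \code{feasible} (character vector of carbons) and
#'   \code{status}: \code{"ok"}, \code{"no label detected"} (no shifted
#'   ion at all) or \code{"inconsistent"} (empty intersection).
#' @examples
#' obs <- rbind(
#'   labelObservation("[M-H]-", 1),
#'   labelObservation("frag183", 0),
#'   labelObservation("frag153", 0),
#'   labelObservation("frag123", 0),
#'   labelObservation("product207", 0, lossCarbons = c("C2", "C3", "C4", "C5")))
#' frags <- sqFragmentIons()
#' frags$product207 <- frags$molecular
#' inferLabelPosition(frags, obs)   # C2
#' @export
inferLabelPosition <- function(fragments, observations) {
  carbons <- paste0("C", 1:6)
  # observations may reference fragments by list name or by ion label
  labels <- vapply(fragments, function(f) f@label, character(1))
  lookup <- function(key) {
    if (key %in% names(fragments)) return(fragments[[key]])
    hit <- which(labels == key)
    if (length(hit)) return(fragments[[hit[1L]]])
    stop("observation references unknown fragment: ", key,
         call. = FALSE)
  }
  for (key in observations$fragment) lookup(key)
  if (!any(observations$delta_mz == 1L))
    return(list(feasible = character(0), status = "no label detected"))

  feasible <- carbons
  for (i in seq_len(nrow(observations))) {
    frag <- lookup(observations$fragment[i])
    cov <- frag@coverage
    loss <- observations$loss_carbons[i]
    loss <- if (is.na(loss)) character(0)
    else strsplit(loss, ",")[[1]]
    allowed <- if (observations$delta_mz[i] == 1L)
      setdiff(cov, loss)            # label retained in the product
    else
      union(setdiff(carbons, cov), loss)  # label absent from the product
    feasible <- intersect(feasible, allowed)
  }
  if (!length(feasible))
    return(list(feasible = character(0), status = "inconsistent"))
  list(feasible = feasible, status = "ok")
}
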