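# Coordinate geometry: structure I/O, atomic distances, side-chain
# rotation about Calpha-Cbeta, Kabsch superposition RMSD, Shrake-Rupley
# SASA with a deterministic sphere lattice, and dimer interface area.

# van der Waals radii (Angstrom) used for SASA; fixed so results are
# explainable when they deviate from other tools' (different) tables.
#' @noRd
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# deterministic, RNG-free unit-sphere lattice (golden-section spiral)
#' @noRd
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Read a structure from PDB or mmCIF
#'
#' Parses with \pkg{bio3d} (\code{read.pdb}/\code{read.cif}, chosen by
#' file extension).  Alternate locations are resolved to the highest
#' occupancy; waters are dropped unless \code{keepWaters = TRUE}.
#'
#' @param path coordinate file (\code{.pdb}, \code{.ent}, \code{.cif}).
#' @param keepWaters retain water molecules (resid HOH/WAT)?
#' @return a \linkS4class{Structure}
#' @export
readStructure <- function(path, keepWaters = FALSE) {
  ext <- tolower(tools::file_ext(path))
  # minimal coordinate-only files legitimately lack secondary-structure
  # records; bio3d warns about them, which is noise here
  pdb <- if (ext == "cif") suppressWarnings(bio3d::read.cif(path))
  else suppressWarnings(bio3d::read.pdb(path))
  a <- pdb$atom
  if (!nrow(a)) stop("empty model in '", path, "'", call. = FALSE)
  df <- data.frame(
    eleno = a$eleno, elety = a$elety,
    elesy = ifelse(is.na(a$elesy) | a$elesy == "",
                   substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    alt = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    stringsAsFactors = FALSE)
  if (!keepWaters)
    df <- df[!df$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  # altloc: keep the highest-occupancy conformer of each atom
  key <- paste(df$chain, df$resno, df$resid, df$elety)
  df <- df[order(key, -df$o), , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resno, df$resid, df$elety)), ,
           drop = FALSE]
  df <- df[order(df$eleno), , drop = FALSE]
  df$alt <- NULL
  rownames(df) <- NULL
  new("Structure", atoms = df, title = basename(path))
}

#' Write a structure as PDB
#'
#' @param s a \linkS4class{Structure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(s, path) {
  a <- s@atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$elety[i]
    # PDB atom-name column convention: 1-char elements start in column 14
    nmFmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$het[i]) "HETATM" else "ATOM", a$eleno[i], nmFmt,
            a$resid[i], a$chain[i], a$resno[i], a$x[i], a$y[i], a$z[i],
            a$o[i], 0, a$elesy[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure as minimal mmCIF
#'
#' Emits a single \code{atom_site} loop sufficient for round-tripping
#' through \code{\link{readStructure}}.
#'
#' @param s a \linkS4class{Structure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructureCIF <- function(s, path) {
  a <- s@atoms
  hdr <- c("data_sqgsuite", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(a)), function(i)
    paste(if (a$het[i]) "HETATM" else "ATOM", a$eleno[i], a$elesy[i],
          a$elety[i], ".", a$resid[i], a$chain[i], "1", a$resno[i], "?",
          sprintf("%.3f", a$x[i]), sprintf("%.3f", a$y[i]),
          sprintf("%.3f", a$z[i]), sprintf("%.2f", a$o[i]), "0.00", "?",
          a$resno[i], a$resid[i], a$chain[i], a$elety[i], "1"),
    character(1))
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' @noRd
resolveSelection <- function(s, sel) {
  a <- s@atoms
  keep <- rep(TRUE, nrow(a))
  for (f in intersect(names(sel), c("chain", "resno", "elety", "resid",
                                    "eleno")))
    keep <- keep & a[[f]] %in% sel[[f]]
  which(keep)
}

#' Distance between two atoms
#'
#' @param s a \linkS4class{Structure}.
#' @param sel1,sel2 named lists selecting exactly one atom each, e.g.
#'   \code{list(chain = "A", resno = 401, elety = "C3")}.
#' @return Euclidean distance in Angstroms.
#' @examples
#' toy <- makeToyStructure("sphere-pair", separation = 3.4)
#' atomDistance(toy, list(eleno = 1), list(eleno = 2))
#' @export
atomDistance <- function(s, sel1, sel2) {
  stopifnot(is(s, "Structure"))
  i <- resolveSelection(s, sel1)
  j <- resolveSelection(s, sel2)
  if (length(i) != 1L || length(j) != 1L)
    stop("selection must resolve to exactly one atom (got ",
         length(i), " and ", length(j), ")", call. = FALSE)
  sqrt(sum((unlist(s@atoms[i, c("x", "y", "z")]) -
              unlist(s@atoms[j, c("x", "y", "z")]))^2))
}

# dihedral angle (degrees, in (-180, 180]) over four points
#' @noRd
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracmaCross(b1, b2)
  n2 <- pracmaCross(b2, b3)
  m1 <- pracmaCross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Side-chain rotation about the Calpha-Cbeta bond
#'
#' Computes the chi1 dihedral (N-CA-CB-CG, falling back to OG/OG1/CG1/SG
#' for non-CG residues) in each structure for the selected residue and
#' returns the minimal absolute angular difference on the circle, in
#' degrees (range [0, 180]).
#'
#' @param s1,s2 \linkS4class{Structure} objects containing the residue.
#' @param chain chain id.
#' @param resno residue number.
#' @return numeric(1) rotation in degrees.
#' @export
sidechainRotation <- function(s1, s2, chain, resno) {
  chi1 <- function(s) {
    getXYZ <- function(name) {
      i <- resolveSelection(s, list(chain = chain, resno = resno,
                                    elety = name))
      if (length(i) == 1L) unlist(s@atoms[i, c("x", "y", "z")]) else NULL
    }
    n <- getXYZ("N"); ca <- getXYZ("CA"); cb <- getXYZ("CB")
    g <- NULL
    for (cand in c("CG", "OG", "OG1", "CG1", "SG")) {
      g <- getXYZ(cand)
      if (!is.null(g)) break
    }
    if (is.null(n) || is.null(ca) || is.null(cb) || is.null(g))
      stop("residue ", chain, ":", resno,
           " lacks N/CA/CB or a first side-chain atom", call. = FALSE)
    dihedralAngle(n, ca, cb, g)
  }
  d <- abs(chi1(s1) - chi1(s2)) %% 360
  min(d, 360 - d)
}

# Kabsch optimal rotation: returns the rotation matrix (det +1) aligning
# centred Y onto centred X
#' @noRd
kabschRotation <- function(X, Y) {
  H <- t(Y) %*% X
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Superpose two structures and report backbone RMSD
#'
#' Least-squares rigid superposition (Kabsch SVD, reflection excluded by
#' forcing the rotation determinant to +1) over the backbone atoms
#' (N, CA, C, O by default) of residues common to both structures,
#' matched by (chain, residue number, atom name).
#'
#' @param s1,s2 \linkS4class{Structure} objects.
#' @param atomNames backbone atom names used for matching.
#' @param chains optional chain subset.
#' @param chainMap optional named character vector mapping chains of
#'   \code{s2} onto chains of \code{s1} (e.g. \code{c(B = "A")}).
#' @return list with \code{rmsd} (Angstroms), \code{n_residues},
#'   \code{n_atoms} and the \code{rotation} matrix.
#' @export
superposeRmsd <- function(s1, s2, atomNames = c("N", "CA", "C", "O"),
                          chains = NULL, chainMap = NULL) {
  a1 <- s1@atoms[!s1@atoms$het, , drop = FALSE]
  a2 <- s2@atoms[!s2@atoms$het, , drop = FALSE]
  if (!is.null(chainMap)) {
    m <- match(a2$chain, names(chainMap))
    a2$chain[!is.na(m)] <- unname(chainMap[m[!is.na(m)]])
  }
  if (!is.null(chains)) {
    a1 <- a1[a1$chain %in% chains, , drop = FALSE]
    a2 <- a2[a2$chain %in% chains, , drop = FALSE]
  }
  a1 <- a1[a1$elety %in% atomNames, , drop = FALSE]
  a2 <- a2[a2$elety %in% atomNames, , drop = FALSE]
  k1 <- paste(a1$chain, a1$resno, a1$elety)
  k2 <- paste(a2$chain, a2$resno, a2$elety)
  common <- intersect(k1, k2)
  if (length(unique(sub(" [^ ]+$", "", common))) < 3L)
    stop("need at least 3 common residues to superpose", call. = FALSE)
  X <- as.matrix(a1[match(common, k1), c("x", "y", "z")])
  Y <- as.matrix(a2[match(common, k2), c("x", "y", "z")])
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  R <- kabschRotation(Xc, Yc)
  Yr <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xc - Yr)^2)))
  list(rmsd = rmsd,
       n_residues = length(unique(sub(" [^ ]+$", "", common))),
       n_atoms = length(common), rotation = R)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-sampling SASA with a deterministic golden-section lattice (no
#' RNG): each atom's accessible fraction is the share of its
#' \code{nPoints} test points (on the atom's van der Waals sphere expanded
#' by the probe radius) not buried inside any neighbour's expanded
#' sphere.  Radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 A.
#'
#' @param s a \linkS4class{Structure}.
#' @param probe probe radius in Angstroms (water: 1.4).
#' @param nPoints test points per atom (default 960).
#' @param includeHet include hetero atoms (ligands/ions)?
#' @param radii named radius table overriding the default.
#' @return list with \code{total} (A^2) and \code{per_atom}.
#' @export
sasa <- function(s, probe = 1.4, nPoints = 960, includeHet = FALSE,
                 radii = VDW_RADII) {
  stopifnot(is(s, "Structure"))
  a <- s@atoms
  if (!includeHet) a <- a[!a$het, , drop = FALSE]
  if (!nrow(a)) return(list(total = 0, per_atom = numeric(0)))
  el <- a$elesy
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("no radius configured for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  r <- radii[el] + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- fibonacciSphere(nPoints)
  area <- numeric(n)
  # pairwise neighbour prefilter
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & dj > r[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / nPoints
    } else frac <- 1
    area[i] <- 4 * pi * r[i]^2 * frac
  }
  list(total = sum(area), per_atom = area)
}

#' Buried surface area of a two-chain interface
#'
#' Computes the SASA of each chain in isolation and of the assembled
#' dimer; the buried area is the total over both protomers,
#' \eqn{A + B - AB}, reported with the percent of the summed monomer
#' surface it represents.  Ligands, waters and ions are excluded by
#' default.
#'
#' @param s a \linkS4class{Structure} containing both chains.
#' @param chainA,chainB chain identifiers.
#' @param probe,nPoints,includeHet passed to \code{\link{sasa}}.
#' @return an \linkS4class{InterfaceReport}
#' @export
interfaceReport <- function(s, chainA, chainB, probe = 1.4,
                            nPoints = 960, includeHet = FALSE) {
  stopifnot(is(s, "Structure"))
  a <- s@atoms
  if (!chainA %in% a$chain || !chainB %in% a$chain)
    stop("chain missing from structure", call. = FALSE)
  sub <- function(ch) new("Structure",
                          atoms = a[a$chain %in% ch, , drop = FALSE],
                          title = paste(s@title, paste(ch, collapse = "")))
  sA <- sasa(sub(chainA), probe, nPoints, includeHet)$total
  sB <- sasa(sub(chainB), probe, nPoints, includeHet)$total
  sAB <- sasa(sub(c(chainA, chainB)), probe, nPoints, includeHet)$total
  buried <- max(0, sA + sB - sAB)
  new("InterfaceReport", sasaA = sA, sasaB = sB, sasaDimer = sAB,
      buriedTotal = buried,
      buriedFractionOfMonomer = if (sA + sB > 0)
        100 * buried / (sA + sB) else 0)
}
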