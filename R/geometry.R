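# Base-pair geometry from 3D coordinates: H-bond detection with
# donor/acceptor chemistry, Leontis-Westhof edge/orientation classification,
# sheared (trans Sugar/Hoogsteen) G.A detection, idealized N6-methyl
# placement with a ribose clash check, and Kabsch least-squares
# superposition.
#
# Conventions used throughout:
#  * Hydrogens are assumed absent (typical crystal structures); donor
#    plausibility is enforced via the antecedent-donor-acceptor angle.
#  * Edge assignment is by weighted voting of the H-bonded atoms over fixed
#    per-base edge sets; atoms on an edge boundary (N6/O6, N4/O4, O2) split
#    their vote.
#  * cis/trans: the glycosidic bond vectors (C1' -> N9/N1), with their
#    components along the C1'-C1' axis removed, point to the same side of
#    the axis for cis pairs and to opposite sides for trans pairs.

RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O2'", "O3'", "O4'", "O5'")
PURINES <- c("A", "G")

# Donor atom -> heavy antecedents used to estimate the N-H direction (the
# H points opposite their centroid). The whole ring is used for every base
# donor -- exocyclic amines and ring NH alike -- because the ring centroid
# is a far more noise-robust estimate of the direction the proton points
# away from than one or two bonded neighbors (for a ring NH the two
# adjacent atoms nearly cancel, leaving a short, noise-dominated mean).
PURINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")
BASE_DONORS <- list(
  A = list(N6 = PURINE_RING),
  G = list(N1 = PURINE_RING, N2 = PURINE_RING),
  C = list(N4 = PYRIMIDINE_RING),
  U = list(N3 = PYRIMIDINE_RING))
BASE_ACCEPTORS <- list(
  A = list(N1 = c("C2", "C6"), N3 = c("C2", "C4"), N7 = c("C5", "C8")),
  G = list(O6 = "C6", N3 = c("C2", "C4"), N7 = c("C5", "C8")),
  C = list(N3 = c("C2", "C4"), O2 = "C2"),
  U = list(O2 = "C2", O4 = "C4"))

# Edge-vote weights per base: named list atom -> c(WC, HG, SU).
EDGE_WEIGHTS <- list(
  A = list(N1 = c(1, 0, 0), N7 = c(0, 1, 0), N3 = c(0, 0, 1),
           N6 = c(0.5, 0.5, 0), "O2'" = c(0, 0, 1)),
  G = list(N1 = c(1, 0, 0), O6 = c(0.5, 0.5, 0), N7 = c(0, 1, 0),
           N3 = c(0, 0, 1), N2 = c(0, 0, 1), "O2'" = c(0, 0, 1)),
  C = list(N3 = c(1, 0, 0), N4 = c(0.5, 0.5, 0), O2 = c(0.5, 0, 0.5),
           "O2'" = c(0, 0, 1)),
  U = list(N3 = c(1, 0, 0), O4 = c(0.5, 0.5, 0), O2 = c(0.5, 0, 0.5),
           "O2'" = c(0, 0, 1)))
EDGE_NAMES <- c("WC", "Hoogsteen", "Sugar")

# Residue-name normalization: modified bases are mapped onto a parent for
# edge chemistry. N6-methyladenine variants behave as adenine (the N6 methyl
# is carried as an extra atom); brominated cytosines behave as cytosine.
BASE_ALIASES <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
                  DA = "A", DC = "C", DG = "G", DT = "U", DU = "U",
                  RA = "A", RC = "C", RG = "G", RU = "U",
                  `6MA` = "A", `6MZ` = "A", M6A = "A",
                  CBR = "C", `5BC` = "C", BRC = "C")

#' Construct a nucleotide residue
#'
#' @param chain chain identifier.
#' @param resno residue number.
#' @param base one of `"A","C","G","U"` (parent base for modified residues).
#' @param atoms data.frame with columns `name`, `x`, `y`, `z` (and optionally
#'   `element`); atom names use the `O2'` prime dialect.
#' @param resid original residue name (default `base`).
#' @return object of class `nt_residue`; `complete` is TRUE when all ring
#'   atoms and C1' are present.
#' @export
nt_residue <- function(chain, resno, base, atoms, resid = base) {
  stopifnot(base %in% c("A", "C", "G", "U"),
            all(c("name", "x", "y", "z") %in% names(atoms)))
  atoms$name <- gsub("\\*", "'", atoms$name)
  if (anyDuplicated(atoms$name))
    stop("duplicate atom names in residue ", chain, ":", resno)
  need <- c("N1", "C2", "N3", "C4", "C5", "C6",
            if (base %in% PURINES) c("N7", "C8", "N9"), "C1'")
  structure(list(chain = chain, resno = as.integer(resno), base = base,
                 resid = resid, atoms = atoms,
                 complete = all(need %in% atoms$name)),
            class = "nt_residue")
}

# xyz of one named atom (NULL when absent).
atom_xyz <- function(res, name) {
  i <- match(name, res$atoms$name)
  if (is.na(i)) return(NULL)
  c(res$atoms$x[i], res$atoms$y[i], res$atoms$z[i])
}

res_label <- function(res) paste0(res$chain, ":", res$resno, res$base)

#' Read nucleotide residues from a PDB or mmCIF file
#'
#' Atom-name dialects are unified (`O2*` -> `O2'`); for alternate locations
#' the highest-occupancy record wins, ties broken by altloc letter.
#' Residues missing required base atoms or C1' are flagged incomplete and a
#' warning names them; they are excluded from pair classification.
#'
#' @param path PDB or mmCIF file (`.cif` extension selects mmCIF).
#' @param model_index model to read from multi-model files (default 1).
#' @return list of [nt_residue] objects.
#' @export
read_structure <- function(path, model_index = 1L) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model ", model_index, " not present")
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$resid <- trimws(at$resid)
  at$elety <- gsub("\\*", "'", trimws(at$elety))
  at <- at[at$resid %in% names(BASE_ALIASES), , drop = FALSE]
  at <- at[!grepl("^H", at$elety), , drop = FALSE]
  if (nrow(at) == 0L) return(list())
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert %||% "")
  res_list <- lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                     function(idx) {
    r <- at[idx, , drop = FALSE]
    # altloc policy: highest occupancy, ties by altloc letter
    alt <- if (is.null(r$alt)) rep(NA_character_, nrow(r)) else r$alt
    alt[is.na(alt)] <- ""
    r <- r[order(r$elety, -r$o, alt), , drop = FALSE]
    r <- r[!duplicated(r$elety), , drop = FALSE]
    nt_residue(chain = r$chain[1], resno = r$resno[1],
               base = unname(BASE_ALIASES[r$resid[1]]),
               atoms = data.frame(name = r$elety, element = r$elesy %||% NA,
                                  x = r$x, y = r$y, z = r$z),
               resid = r$resid[1])
  })
  names(res_list) <- NULL
  bad <- vapply(res_list, function(r) !r$complete, logical(1))
  if (any(bad))
    warning("incomplete residue(s) excluded from classification: ",
            paste(vapply(res_list[bad], res_label, character(1)),
                  collapse = ", "))
  res_list
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Donor and acceptor atom tables for one residue (base atoms + ribose O2').
donor_atoms <- function(res) {
  d <- BASE_DONORS[[res$base]]
  d[["O2'"]] <- "C2'"
  d
}
acceptor_atoms <- function(res) {
  a <- BASE_ACCEPTORS[[res$base]]
  a[["O2'"]] <- "C2'"
  a
}

#' Detect hydrogen bonds between residues
#'
#' All donor-acceptor heavy-atom pairs between distinct residues with
#' distance `<= d_max`. Hydrogens are assumed absent; instead the angle at
#' the donor between each bonded heavy antecedent and the acceptor must be
#' `>= angle_min` (the geometric condition for the donated H to point toward
#' the acceptor).
#'
#' @param residues list of [nt_residue] objects.
#' @param d_max distance cutoff in angstroms (default 3.5, the smallest
#'   cutoff consistent with observed long bonds of 3.4).
#' @param angle_min minimum antecedent-donor-acceptor angle in degrees.
#'   The antecedent direction is the mean of the unit vectors from the
#'   donor to its bonded/ring antecedents, so nominal angles range from
#'   about 120 (exocyclic amines) to 180 (ring NH donors); the default 90
#'   rejects acceptors on the covalent side while leaving every genuine
#'   bond a wide margin under thermal coordinate noise.
#' @return data.frame sorted by distance: donor/acceptor residue indices,
#'   chains, residue numbers, atom names, `distance`, `angle` (minimum over
#'   antecedents) and `base_base` (neither atom is the ribose O2').
#' @export
find_hbonds <- function(residues, d_max = 3.5, angle_min = 90) {
  stopifnot(d_max > 0)
  out <- list()
  n <- length(residues)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ri <- residues[[i]]; rj <- residues[[j]]
    for (dname in names(donor_atoms(ri))) {
      dpos <- atom_xyz(ri, dname)
      if (is.null(dpos)) next
      ante <- setdiff(donor_atoms(ri)[[dname]], dname)
      apos_list <- lapply(ante, atom_xyz, res = ri)
      apos_list <- apos_list[!vapply(apos_list, is.null, logical(1))]
      for (aname in names(acceptor_atoms(rj))) {
        acc <- atom_xyz(rj, aname)
        if (is.null(acc)) next
        d <- sqrt(sum((dpos - acc)^2))
        if (d > d_max || d < 0.5) next
        # donor-antecedent angle: between the acceptor direction and the
        # mean antecedent direction (the donated H points opposite the
        # antecedent centroid in standard protonation)
        angs <- if (length(apos_list) > 0) {
          cen <- Reduce(`+`, lapply(apos_list, function(p)
            normalize3(p - dpos))) / length(apos_list)
          vec_angle(cen, acc - dpos)
        } else numeric(0)
        if (length(angs) > 0 && min(angs) < angle_min) next
        out[[length(out) + 1L]] <- data.frame(
          donor_idx = i, acceptor_idx = j,
          donor_chain = ri$chain, donor_resno = ri$resno, donor_atom = dname,
          acceptor_chain = rj$chain, acceptor_resno = rj$resno,
          acceptor_atom = aname, distance = d,
          angle = if (length(angs) > 0) min(angs) else NA_real_,
          base_base = dname != "O2'" && aname != "O2'")
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor_idx = integer(), acceptor_idx = integer(),
                      donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      distance = numeric(), angle = numeric(),
                      base_base = logical()))
  hb <- do.call(rbind, out)
  # the same physical contact found in both donor->acceptor directions
  # (O2'-O2') is kept once
  key <- apply(hb, 1, function(r) {
    a <- paste(r[["donor_chain"]], r[["donor_resno"]], r[["donor_atom"]])
    b <- paste(r[["acceptor_chain"]], r[["acceptor_resno"]], r[["acceptor_atom"]])
    paste(sort(c(a, b)), collapse = "|")
  })
  hb <- hb[!duplicated(key), , drop = FALSE]
  hb <- hb[order(hb$distance), , drop = FALSE]
  rownames(hb) <- NULL
  hb
}

# Sugar-to-base direction used for the cis/trans decision. When ribose
# atoms are present the direction is taken between the ribose and base-ring
# centroids, which averages coordinate noise over many atoms; the bare
# glycosidic bond C1' -> N9/N1 is the fallback for base-only records.
glycosidic_vec <- function(res) {
  ring <- if (res$base %in% PURINES) PURINE_RING else PYRIMIDINE_RING
  rib <- intersect(RIBOSE_ATOMS, res$atoms$name)
  bas <- intersect(ring, res$atoms$name)
  if (length(rib) >= 3L && length(bas) >= 3L) {
    bc <- colMeans(do.call(rbind, lapply(bas, atom_xyz, res = res)))
    rc <- colMeans(do.call(rbind, lapply(rib, atom_xyz, res = res)))
    return(bc - rc)
  }
  n <- if (res$base %in% PURINES) "N9" else "N1"
  atom_xyz(res, n) - atom_xyz(res, "C1'")
}

# Edge vote for one residue given the atom names it H-bonds through.
# `scales` damps individual votes: a bond whose opposite atom is the
# partner's ribose O2' says less about which of this base's edges faces the
# partner BASE than a base-base bond does, so such votes count half.
edge_vote <- function(res, atom_names, bond_dists, scales = NULL) {
  if (is.null(scales)) scales <- rep(1, length(atom_names))
  w <- EDGE_WEIGHTS[[res$base]]
  score <- c(WC = 0, Hoogsteen = 0, Sugar = 0)
  for (k in seq_along(atom_names)) {
    a <- atom_names[k]
    if (!is.null(w[[a]])) score <- score + scales[k] * w[[a]]
  }
  top <- which(score == max(score))
  ambiguous <- length(top) > 1L
  if (ambiguous) {
    # tie-break toward the edge containing the shortest H-bond's atom,
    # then by fixed priority WC > Hoogsteen > Sugar
    ord <- order(bond_dists)
    pick <- NA_integer_
    for (k in ord) {
      a <- atom_names[k]
      if (is.null(w[[a]])) next
      cand <- which(w[[a]] > 0)
      cand <- intersect(cand, top)
      if (length(cand) > 0) { pick <- min(cand); break }
    }
    if (is.na(pick)) pick <- min(top)
    top <- pick
  }
  list(edge = EDGE_NAMES[top], ambiguous = ambiguous, score = score)
}

#' Classify the geometry of one base pair
#'
#' Assigns each residue's interacting edge (Watson-Crick, Hoogsteen or
#' Sugar) by weighted voting of its H-bonded atoms over fixed per-base edge
#' sets, and the cis/trans orientation from the glycosidic-bond directions
#' relative to the C1'-C1' axis. `paired` is FALSE when no base-base H-bond
#' links the two residues, in which case no edges are assigned.
#'
#' @param r1,r2 complete [nt_residue] objects.
#' @param hbonds optional precomputed H-bond table from [find_hbonds()] run
#'   on a residue list containing `r1`, `r2`; recomputed when missing.
#' @param d_max,angle_min H-bond parameters used when recomputing.
#' @param vote_slack extra distance (angstroms) beyond `d_max` within which
#'   contacts still contribute to edge voting (not to the `paired`
#'   decision); makes edge assignment robust to thermal coordinate noise
#'   around the cutoff.
#' @return object of class `base_pair`: residues, `hbonds` (rows linking the
#'   two residues), `edge1`, `edge2`, `orientation` (`"cis"`/`"trans"`),
#'   `paired`, `ambiguous`, and a human-readable `class` label such as
#'   `"trans Sugar/Hoogsteen G·A"`.
#' @export
classify_pair <- function(r1, r2, hbonds = NULL, d_max = 3.5, angle_min = 90,
                          vote_slack = 0.6) {
  stopifnot(inherits(r1, "nt_residue"), inherits(r2, "nt_residue"))
  if (!r1$complete || !r2$complete)
    stop("both residues must be complete for classification")
  if (is.null(hbonds)) hbonds <- find_hbonds(list(r1, r2), d_max, angle_min)
  sel <- function(hb, a, b)
    (hb$donor_chain == a$chain & hb$donor_resno == a$resno &
     hb$acceptor_chain == b$chain & hb$acceptor_resno == b$resno)
  hb <- hbonds[sel(hbonds, r1, r2) | sel(hbonds, r2, r1), , drop = FALSE]
  vb <- find_hbonds(list(r1, r2), d_max + vote_slack, angle_min)
  vb <- vb[sel(vb, r1, r2) | sel(vb, r2, r1), , drop = FALSE]
  paired <- any(hb$base_base)
  if (!paired) {
    return(structure(list(r1 = r1, r2 = r2, hbonds = hb,
                          edge1 = NA_character_, edge2 = NA_character_,
                          orientation = NA_character_, paired = FALSE,
                          ambiguous = FALSE,
                          class = paste0("unpaired ", r1$base, "·", r2$base)),
                     class = "base_pair"))
  }
  atoms_for <- function(res) {
    don <- sel(vb, res, if (identical(res, r1)) r2 else r1)
    acc <- sel(vb, if (identical(res, r1)) r2 else r1, res)
    nm <- c(vb$donor_atom[don], vb$acceptor_atom[acc])
    ds <- c(vb$distance[don], vb$distance[acc])
    other <- c(vb$acceptor_atom[don], vb$donor_atom[acc])
    # one vote per distinct atom (an atom engaged in two contacts still
    # marks the same edge once); keep its shortest contact for tie-breaks.
    # Contacts through the partner's O2' count half (see edge_vote).
    o <- order(ds)
    nm <- nm[o]; ds <- ds[o]; other <- other[o]
    keep <- !duplicated(nm)
    list(names = nm[keep], dists = ds[keep],
         scales = ifelse(other[keep] == "O2'", 0.5, 1))
  }
  a1 <- atoms_for(r1); a2 <- atoms_for(r2)
  v1 <- edge_vote(r1, a1$names, a1$dists, a1$scales)
  v2 <- edge_vote(r2, a2$names, a2$dists, a2$scales)
  axis <- atom_xyz(r2, "C1'") - atom_xyz(r1, "C1'")
  axis <- axis / sqrt(sum(axis^2))
  perp <- function(u) u - sum(u * axis) * axis
  u1 <- perp(glycosidic_vec(r1))
  u2 <- perp(glycosidic_vec(r2))
  orientation <- if (sum(u1 * u2) > 0) "cis" else "trans"
  edge_label <- function(e) if (e == "WC") "WC" else e
  cls <- paste0(orientation, " ", edge_label(v1$edge), "/", edge_label(v2$edge),
                " ", r1$base, "·", r2$base)
  structure(list(r1 = r1, r2 = r2, hbonds = hb, edge1 = v1$edge,
                 edge2 = v2$edge, orientation = orientation, paired = TRUE,
                 ambiguous = v1$ambiguous || v2$ambiguous, class = cls),
            class = "base_pair")
}

#' @export
print.base_pair <- function(x, ...) {
  cat(sprintf("<base_pair> %s -- %s: %s (%d H-bond%s%s)\n",
              res_label(x$r1), res_label(x$r2), x$class, nrow(x$hbonds),
              if (nrow(x$hbonds) == 1L) "" else "s",
              if (x$ambiguous) ", ambiguous edge" else ""))
  invisible(x)
}

#' Filter sheared (trans Sugar/Hoogsteen) G·A pairs
#'
#' Keeps pairs classified trans with guanine on the Sugar edge and adenine
#' on the Hoogsteen edge, and counts tandem occurrences: two sheared pairs
#' whose residues are sequence-adjacent on both strands.
#'
#' @param pairs list of `base_pair` objects.
#' @return list with `sheared` (the matching sublist) and `tandem_count`.
#' @export
detect_sheared_GA <- function(pairs) {
  is_sheared <- vapply(pairs, function(p) {
    if (!p$paired || is.na(p$orientation) || p$orientation != "trans")
      return(FALSE)
    (p$r1$base == "G" && p$edge1 == "Sugar" &&
       p$r2$base == "A" && p$edge2 == "Hoogsteen") ||
    (p$r2$base == "G" && p$edge2 == "Sugar" &&
       p$r1$base == "A" && p$edge1 == "Hoogsteen")
  }, logical(1))
  sheared <- pairs[is_sheared]
  tandem <- 0L
  if (length(sheared) >= 2L) {
    key <- lapply(sheared, function(p)
      list(c1 = p$r1$chain, n1 = p$r1$resno, c2 = p$r2$chain, n2 = p$r2$resno))
    for (i in seq_along(key)) for (j in seq_along(key)) {
      if (i >= j) next
      a <- key[[i]]; b <- key[[j]]
      adj <- function(ca, na, cb, nb) ca == cb && abs(na - nb) == 1L
      if ((adj(a$c1, a$n1, b$c1, b$n1) && adj(a$c2, a$n2, b$c2, b$n2)) ||
          (adj(a$c1, a$n1, b$c2, b$n2) && adj(a$c2, a$n2, b$c1, b$n1)))
        tandem <- tandem + 1L
    }
  }
  list(sheared = sheared, tandem_count = tandem)
}

# Least-squares plane normal of a point matrix (n x 3).
plane_normal <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  svd(Pc)$v[, 3]
}

#' Add an idealized N6-methyl carbon to an adenine
#'
#' Places a carbon 1.45 angstroms from N6 in the base plane with sp2
#' geometry (~120 degrees from the C6 direction). `anti` puts the methyl
#' trans to N1 across the C6-N6 bond (pointing into the major groove of a
#' Watson-Crick pair); `syn` puts it cis to N1, where in a sheared G·A pair
#' it approaches the partner guanine's ribose.
#'
#' @param residue an adenine [nt_residue] with N6, C6, N1 and ring atoms.
#' @param rotamer `"anti"` or `"syn"`.
#' @return the residue with an added atom `"CM6"` and attribute-free
#'   bookkeeping fields `methyl_rotamer`.
#' @export
add_n6_methyl <- function(residue, rotamer = c("anti", "syn")) {
  rotamer <- match.arg(rotamer)
  stopifnot(inherits(residue, "nt_residue"))
  if (residue$base != "A") stop("N6 methylation applies to adenine residues")
  n6 <- atom_xyz(residue, "N6"); c6 <- atom_xyz(residue, "C6")
  n1 <- atom_xyz(residue, "N1")
  if (is.null(n6) || is.null(c6) || is.null(n1))
    stop("residue lacks anchor atoms N6/C6/N1")
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  P <- do.call(rbind, lapply(ring, atom_xyz, res = residue))
  nrm <- plane_normal(P)
  w <- c6 - n6; w <- w / sqrt(sum(w^2))
  p <- pracma_cross(nrm, w); p <- p / sqrt(sum(p^2))
  cand <- lapply(c(1, -1), function(s)
    n6 + 1.45 * (cos(2 * pi / 3) * w + s * sin(2 * pi / 3) * p))
  d_n1 <- vapply(cand, function(x) sqrt(sum((x - n1)^2)), numeric(1))
  pos <- if (rotamer == "anti") cand[[which.max(d_n1)]] else cand[[which.min(d_n1)]]
  residue$atoms <- rbind(residue$atoms,
                         data.frame(name = "CM6",
                                    element = if ("element" %in% names(residue$atoms))
                                      "C" else NULL,
                                    x = pos[1], y = pos[2], z = pos[3]))
  residue$methyl_rotamer <- rotamer
  residue
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Check an N6-methyl for steric clash with the partner ribose
#'
#' Minimum heavy-atom distance from the methyl carbon (`CM6`) to the
#' partner's ribose atoms; a clash is called below `cutoff` (default 3.0
#' angstroms, roughly a C/O van der Waals contact).
#'
#' @param residue_aug an adenine processed by [add_n6_methyl()].
#' @param partner the opposing [nt_residue].
#' @param cutoff clash distance in angstroms, `> 0`.
#' @return list `(min_distance, clashing, closest)` where `closest` names
#'   the methyl atom and the partner ribose atom.
#' @export
clash_check <- function(residue_aug, partner, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  m <- atom_xyz(residue_aug, "CM6")
  if (is.null(m)) stop("residue carries no N6-methyl (run add_n6_methyl first)")
  rib <- partner$atoms[partner$atoms$name %in% RIBOSE_ATOMS, , drop = FALSE]
  if (nrow(rib) == 0L) stop("partner residue has no ribose atoms")
  d <- sqrt((rib$x - m[1])^2 + (rib$y - m[2])^2 + (rib$z - m[3])^2)
  i <- which.min(d)
  list(min_distance = d[i], clashing = d[i] < cutoff,
       closest = c(methyl = "CM6", partner_atom = rib$name[i]))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% x + t` against the reference, via singular value decomposition of
#' the cross-covariance with determinant correction.
#'
#' @param mobile,reference n x 3 coordinate matrices, matched rows, n >= 3.
#' @param atom_selection free-text description echoed in the result.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (over the fitted selection), `atom_selection`.
#' @export
superpose <- function(mobile, reference, atom_selection = "all input atoms") {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  sv_x <- svd(X)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1e-12))
    stop("degenerate (collinear) atom selection; superposition is not unique")
  s <- svd(crossprod(X, Y))           # t(X) %*% Y = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cr - as.vector(R %*% cm)
  fitted <- t(R %*% t(mobile)) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 atom_selection = atom_selection),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  coords <- as.matrix(coords)
  t(sp$rotation %*% t(coords)) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

#' RMSD between matched coordinate sets
#'
#' @param a,b n x 3 matrices.
#' @return root-mean-square deviation.
#' @export
rmsd_of <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over %s\n",
              x$rmsd, x$atom_selection))
  invisible(x)
}
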