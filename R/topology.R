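# Topology construction: virtual bonds, bond angles, dihedrals, native /
# nonnative contact partition, and ligand restraint pairs. The reference
# structure is the minimum of every structure-based term.
#
# Conventions:
#   * a native pair requires at least one heavy-atom pair closer than `cutoff`
#     (4.5 A) in the reference structure; within a chain the sequence
#     separation must be at least `min_seq_sep` (default 4); across chains or
#     subunits of the same molecule there is no separation condition;
#   * residues flagged flexible keep their bond-length constraints and
#     nonnative repulsion but contribute no angle, dihedral or native terms
#     (they fluctuate without the guidance of the structure-based potential);
#   * the native/nonnative partition never crosses the myosin-actin
#     interface, which interacts only through electrostatics and van der
#     Waals terms.

.bead_table <- function(x) {
  if (inherits(x, "reference_structure")) {
    b <- x$beads
    b$chain_uid <- b$chain
    list(beads = b, heavy = {
      h <- x$heavy
      h$chain_uid <- h$chain
      h
    }, ligand = x$ligand)
  } else if (inherits(x, "filament_model")) {
    b <- x$beads
    b$chain_uid <- paste0(b$chain, ".", b$subunit)
    h <- x$heavy
    h$chain_uid <- paste0(h$chain, ".", h$subunit)
    list(beads = b, heavy = h,
         ligand = data.frame(atom = character(), parent = character(),
                             x = numeric(), y = numeric(), z = numeric(),
                             charge = numeric(), stringsAsFactors = FALSE))
  } else stop("expected a reference_structure or filament_model")
}

.angle0 <- function(xyz, tri) {
  a <- xyz[tri[, 1], , drop = FALSE] - xyz[tri[, 2], , drop = FALSE]
  b <- xyz[tri[, 3], , drop = FALSE] - xyz[tri[, 2], , drop = FALSE]
  cosv <- rowSums(a * b) / sqrt(rowSums(a * a) * rowSums(b * b))
  acos(pmin(1, pmax(-1, cosv)))
}

.dihedral0 <- function(xyz, quad) {
  b1 <- xyz[quad[, 2], , drop = FALSE] - xyz[quad[, 1], , drop = FALSE]
  b2 <- xyz[quad[, 3], , drop = FALSE] - xyz[quad[, 2], , drop = FALSE]
  b3 <- xyz[quad[, 4], , drop = FALSE] - xyz[quad[, 3], , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2 * b2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Detect native contact pairs and build a structure topology
#'
#' Classifies every eligible residue pair of one molecule (myosin S1 or the
#' actin filament) as native or nonnative from the heavy-atom geometry of the
#' reference structure, and collects the bonded terms (virtual bonds, bond
#' angles, dihedrals) and ligand restraint pairs.
#'
#' @param x a [reference_structure()] or [filament_model()].
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param min_seq_sep minimum intra-chain sequence separation `|i - j|` for a
#'   native pair (default 4).
#' @param heavy_atom_source optional data.frame overriding the heavy atoms
#'   stored in `x` (columns `chain`/`chain_uid`, `resno`, `x`, `y`, `z`).
#' @return A list of class `cg_topology` with elements `bonds` (`i`, `j`,
#'   `b0`), `angles` (`i`, `j`, `k`, `theta0`), `dihedrals` (`i`..`l`,
#'   `phi0`), `native` (`i`, `j`, `r0`), `nonnative` (`i`, `j`),
#'   `ligand_pairs` (`i`, `j`, `r0`; indices into the combined
#'   bead-then-ligand particle list), plus the particle bookkeeping table.
#'   All indices are 1-based rows of `particles`.
#' @export
detect_native_pairs <- function(x, cutoff = 4.5, min_seq_sep = 4L,
                                heavy_atom_source = NULL) {
  build_topology(x, cutoff = cutoff, min_seq_sep = min_seq_sep,
                 heavy_atom_source = heavy_atom_source)
}

#' @rdname detect_native_pairs
#' @export
build_topology <- function(x, cutoff = 4.5, min_seq_sep = 4L,
                           heavy_atom_source = NULL) {
  parts <- .bead_table(x)
  beads <- parts$beads
  heavy <- if (is.null(heavy_atom_source)) parts$heavy else {
    h <- heavy_atom_source
    if (is.null(h$chain_uid)) h$chain_uid <- h$chain
    h
  }
  ligand <- parts$ligand
  nb <- nrow(beads)
  xyz <- as.matrix(beads[, c("x", "y", "z")])

  key <- paste(beads$chain_uid, beads$resno)
  bead_of <- setNames(seq_len(nb), key)
  hkey <- paste(heavy$chain_uid, heavy$resno)
  hidx <- bead_of[hkey]
  if (anyNA(hidx)) {
    warning(sum(is.na(hidx)), " heavy atom(s) with no matching residue ignored")
    heavy <- heavy[!is.na(hidx), , drop = FALSE]
    hidx <- hidx[!is.na(hidx)]
  }
  no_heavy <- setdiff(seq_len(nb), unique(hidx))
  if (length(no_heavy))
    warning("residue(s) without heavy atoms contribute no native pairs: ",
            paste(key[no_heavy], collapse = ", "))

  # bonded terms, per chain
  bonds <- angles <- dihedrals <- NULL
  for (ch in unique(beads$chain_uid)) {
    idx <- which(beads$chain_uid == ch)
    n <- length(idx)
    flex <- beads$flexible[idx]
    if (n >= 2)
      bonds <- rbind(bonds, cbind(idx[-n], idx[-1]))
    if (n >= 3) {
      ok <- !(flex[1:(n - 2)] | flex[2:(n - 1)] | flex[3:n])
      if (any(ok))
        angles <- rbind(angles, cbind(idx[1:(n - 2)], idx[2:(n - 1)],
                                      idx[3:n])[ok, , drop = FALSE])
    }
    if (n >= 4) {
      ok <- !(flex[1:(n - 3)] | flex[2:(n - 2)] | flex[3:(n - 1)] | flex[4:n])
      if (any(ok))
        dihedrals <- rbind(dihedrals, cbind(idx[1:(n - 3)], idx[2:(n - 2)],
                                            idx[3:(n - 1)], idx[4:n])[ok, , drop = FALSE])
    }
  }

  # native pairs from the heavy-atom scan (C++ brute force over atoms)
  contact <- heavy_contact_pairs_cpp(as.matrix(heavy[, c("x", "y", "z")]),
                                     as.integer(hidx - 1L), nb, cutoff)
  native <- NULL
  if (nrow(contact)) {
    i <- contact[, 1] + 1L; j <- contact[, 2] + 1L
    same_chain <- beads$chain_uid[i] == beads$chain_uid[j]
    seq_ok <- abs(beads$resno[i] - beads$resno[j]) >= min_seq_sep
    keep <- (!same_chain | seq_ok) &
      !beads$flexible[i] & !beads$flexible[j]
    if (any(keep)) {
      i <- i[keep]; j <- j[keep]
      r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
      native <- cbind(i, j, r0)
    }
  }

  # nonnative pairs: every remaining eligible pair within the molecule
  natkey <- if (is.null(native)) character() else
    paste(native[, 1], native[, 2])
  if (nb >= 2) {
    cmb <- t(utils::combn(nb, 2L))
    i <- cmb[, 1]; j <- cmb[, 2]
    same_chain <- beads$chain_uid[i] == beads$chain_uid[j]
    eligible <- (!same_chain) |
      (abs(beads$resno[i] - beads$resno[j]) >= min_seq_sep)
    nonnat <- cmb[eligible & !(paste(i, j) %in% natkey), , drop = FALSE]
  } else nonnat <- matrix(0L, 0, 2)

  # ligand restraint pairs (spring to the reference distance)
  lig_pairs <- NULL
  nl <- nrow(ligand)
  if (nl) {
    lxyz <- as.matrix(ligand[, c("x", "y", "z")])
    # ligand-ligand atom pairs within cutoff
    if (nl >= 2) {
      lc <- t(utils::combn(nl, 2L))
      d <- sqrt(rowSums((lxyz[lc[, 1], , drop = FALSE] -
                           lxyz[lc[, 2], , drop = FALSE])^2))
      sel <- d < cutoff
      if (any(sel))
        lig_pairs <- rbind(lig_pairs,
                           cbind(nb + lc[sel, 1], nb + lc[sel, 2], d[sel]))
    }
    # residue-ligand pairs: any heavy atom of the residue within cutoff of the
    # ligand atom couples that residue's bead to the atom
    hxyz <- as.matrix(heavy[, c("x", "y", "z")])
    for (a in seq_len(nl)) {
      d2 <- (hxyz[, 1] - lxyz[a, 1])^2 + (hxyz[, 2] - lxyz[a, 2])^2 +
        (hxyz[, 3] - lxyz[a, 3])^2
      res <- unique(hidx[d2 < cutoff^2])
      if (length(res)) {
        r0 <- sqrt((xyz[res, 1] - lxyz[a, 1])^2 + (xyz[res, 2] - lxyz[a, 2])^2 +
                     (xyz[res, 3] - lxyz[a, 3])^2)
        lig_pairs <- rbind(lig_pairs, cbind(res, nb + a, r0))
      }
    }
  }

  particles <- rbind(
    data.frame(kind = "bead", chain = beads$chain_uid, resno = beads$resno,
               name = beads$resid, charge = beads$charge,
               flexible = beads$flexible,
               x = beads$x, y = beads$y, z = beads$z,
               stringsAsFactors = FALSE),
    if (nl) data.frame(kind = "ligand", chain = "LIG", resno = seq_len(nl),
                       name = ligand$atom, charge = ligand$charge,
                       flexible = FALSE,
                       x = ligand$x, y = ligand$y, z = ligand$z,
                       stringsAsFactors = FALSE))
  rownames(particles) <- NULL

  topo <- list(
    particles = particles,
    n_beads = nb,
    bonds = if (is.null(bonds)) NULL else
      data.frame(i = bonds[, 1], j = bonds[, 2],
                 b0 = sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                                      xyz[bonds[, 2], , drop = FALSE])^2))),
    angles = if (is.null(angles)) NULL else
      data.frame(i = angles[, 1], j = angles[, 2], k = angles[, 3],
                 theta0 = .angle0(xyz, angles)),
    dihedrals = if (is.null(dihedrals)) NULL else
      data.frame(i = dihedrals[, 1], j = dihedrals[, 2], k = dihedrals[, 3],
                 l = dihedrals[, 4], phi0 = .dihedral0(xyz, dihedrals)),
    native = if (is.null(native)) NULL else
      data.frame(i = native[, 1], j = native[, 2], r0 = native[, 3]),
    nonnative = if (nrow(nonnat)) data.frame(i = nonnat[, 1], j = nonnat[, 2])
      else NULL,
    ligand_pairs = if (is.null(lig_pairs)) NULL else
      data.frame(i = lig_pairs[, 1], j = lig_pairs[, 2], r0 = lig_pairs[, 3]),
    cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep))
  class(topo) <- "cg_topology"
  topo
}

#' @export
print.cg_topology <- function(x, ...) {
  nr <- function(d) if (is.null(d)) 0L else nrow(d)
  cat(sprintf(paste0("cg_topology: %d particles (%d beads); %d bonds, ",
                     "%d angles, %d dihedrals, %d native pairs, ",
                     "%d nonnative pairs, %d ligand pairs\n"),
              nrow(x$particles), x$n_beads, nr(x$bonds), nr(x$angles),
              nr(x$dihedrals), nr(x$native), nr(x$nonnative),
              nr(x$ligand_pairs)))
  invisible(x)
}
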