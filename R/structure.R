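# Coarse-grained reference structures: one bead per residue at the C-alpha
# position, plus all non-hydrogen atoms of any bound ligands (ADP, Pi, Mg).

STATE_LABELS <- c("M_pre", "M_post", "M_closed", "actin_subunit", "custom")

#' Construct a coarse-grained reference structure
#'
#' A `reference_structure` bundles the residue beads (one per residue, at the
#' C-alpha coordinate), the heavy-atom coordinates used for native-contact
#' detection, and the heavy atoms of any bound ligands.
#'
#' @param beads data.frame with columns `chain`, `resno` (1-based, contiguous
#'   per chain), `resid` (3-letter code), `x`, `y`, `z` (Angstrom), and
#'   optionally `charge` and `flexible`.
#' @param heavy data.frame of heavy (non-hydrogen) atoms with columns `chain`,
#'   `resno`, `elety`, `x`, `y`, `z`; defaults to the beads themselves.
#' @param ligand data.frame of ligand heavy atoms with columns `atom`,
#'   `parent` (one of `"ADP"`, `"Pi"`, `"Mg"`), `x`, `y`, `z`, and optionally
#'   `charge`; may be empty.
#' @param label one of `r paste(STATE_LABELS, collapse = ", ")`.
#' @return An object of class `reference_structure`.
#' @export
reference_structure <- function(beads, heavy = NULL, ligand = NULL,
                                label = "custom") {
  label <- match.arg(label, STATE_LABELS)
  stopifnot(is.data.frame(beads),
            all(c("chain", "resno", "resid", "x", "y", "z") %in% names(beads)))
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("bead positions must be finite")
  if (is.null(beads$charge)) beads$charge <- 0
  if (is.null(beads$flexible)) beads$flexible <- FALSE
  # per-chain residue indices must be contiguous and ordered
  for (ch in unique(beads$chain)) {
    rn <- beads$resno[beads$chain == ch]
    if (any(diff(rn) != 1L))
      stop("bead ordering not contiguous in residue index for chain ", ch)
  }
  if (anyDuplicated(beads[, c("chain", "resno")]))
    stop("overlapping chains: duplicated (chain, resno)")
  if (is.null(ligand))
    ligand <- data.frame(atom = character(), parent = character(),
                         x = numeric(), y = numeric(), z = numeric(),
                         charge = numeric(), stringsAsFactors = FALSE)
  if (nrow(ligand) && is.null(ligand$charge)) ligand$charge <- 0
  if (is.null(heavy))
    heavy <- data.frame(chain = beads$chain, resno = beads$resno,
                        elety = "CA", x = beads$x, y = beads$y, z = beads$z,
                        stringsAsFactors = FALSE)
  structure(list(beads = beads, heavy = heavy, ligand = ligand, label = label),
            class = "reference_structure")
}

#' @export
print.reference_structure <- function(x, ...) {
  cat("reference_structure <", x$label, ">: ",
      nrow(x$beads), " beads in ", length(unique(x$beads$chain)), " chain(s), ",
      nrow(x$ligand), " ligand atom(s), ",
      sum(x$beads$flexible), " flexible residue(s)\n", sep = "")
  invisible(x)
}

# parent classification of a HETATM residue name
.ligand_parent <- function(resid) {
  up <- toupper(resid)
  ifelse(up %in% c("ADP"), "ADP",
         ifelse(up %in% c("PO4", "PI", "2HP", "IPO"), "Pi",
                ifelse(up %in% c("MG"), "Mg", NA_character_)))
}

#' Load a reference structure from a PDB file
#'
#' Parses ATOM/HETATM records, coarse-grains each residue to its C-alpha bead,
#' keeps all non-hydrogen atoms for contact detection, captures ligand heavy
#' atoms (ADP, phosphate, Mg), flags flexible residues (disordered regions
#' that fluctuate without the guidance of the structure-based potential) and
#' assigns residue charges.
#'
#' @param path path to a PDB file.
#' @param label structure label (see [reference_structure()]).
#' @param flexible_regions list of integer vectors of residue numbers (or a
#'   single vector), optionally named by chain id; unnamed entries apply to
#'   the first chain.
#' @param charge_opts charge configuration, see [charge_options()].
#' @return A [reference_structure()].
#' @export
load_structure <- function(path, label = "custom", flexible_regions = NULL,
                           charge_opts = charge_options()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  is_h <- grepl("^H|^[0-9]H", trimws(at$elety))
  prot <- at[at$type == "ATOM" & !is_h, , drop = FALSE]
  het <- at[at$type == "HETATM" & !is_h, , drop = FALSE]
  het <- het[!toupper(het$resid) %in% c("HOH", "WAT"), , drop = FALSE]

  ca <- prot[trimws(prot$elety) == "CA", , drop = FALSE]
  # every protein residue must have a C-alpha record
  res_all <- unique(prot[, c("chain", "resno")])
  res_ca <- unique(ca[, c("chain", "resno")])
  missing <- !paste(res_all$chain, res_all$resno) %in%
    paste(res_ca$chain, res_ca$resno)
  if (any(missing))
    stop("missing C-alpha for residue(s): ",
         paste(res_all$chain[missing], res_all$resno[missing],
               sep = ":", collapse = ", "))

  beads <- data.frame(chain = ca$chain, resno = ca$resno,
                      resid = toupper(ca$resid),
                      x = ca$x, y = ca$y, z = ca$z,
                      stringsAsFactors = FALSE)
  beads <- beads[order(beads$chain, beads$resno), , drop = FALSE]
  rownames(beads) <- NULL

  beads$flexible <- FALSE
  if (!is.null(flexible_regions)) {
    if (!is.list(flexible_regions)) flexible_regions <- list(flexible_regions)
    chains <- unique(beads$chain)
    nms <- names(flexible_regions)
    for (i in seq_along(flexible_regions)) {
      ch <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else chains[1]
      rr <- flexible_regions[[i]]
      bad <- setdiff(rr, beads$resno[beads$chain == ch])
      if (length(bad))
        stop("flexible_regions outside sequence for chain ", ch, ": ",
             paste(bad, collapse = ", "))
      beads$flexible[beads$chain == ch & beads$resno %in% rr] <- TRUE
    }
  }

  ligand <- data.frame(atom = character(), parent = character(),
                       x = numeric(), y = numeric(), z = numeric(),
                       stringsAsFactors = FALSE)
  if (nrow(het)) {
    parent <- .ligand_parent(het$resid)
    keep <- !is.na(parent)
    if (any(!keep))
      warning("ignoring unrecognized HETATM residue(s): ",
              paste(unique(het$resid[!keep]), collapse = ", "))
    ligand <- data.frame(atom = trimws(het$elety[keep]), parent = parent[keep],
                         x = het$x[keep], y = het$y[keep], z = het$z[keep],
                         stringsAsFactors = FALSE)
  }

  heavy <- data.frame(chain = prot$chain, resno = prot$resno,
                      elety = trimws(prot$elety),
                      x = prot$x, y = prot$y, z = prot$z,
                      stringsAsFactors = FALSE)

  ref <- reference_structure(beads, heavy = heavy, ligand = ligand,
                             label = label)
  assign_charges(ref, charge_opts)
}

#' Charge assignment configuration
#'
#' Residue charges follow the Debye-Hueckel term of the interface
#' electrostatics: Asp/Glu carry -1, Lys/Arg +1, His a configurable partial
#' charge, and all other amino acids 0. Ligand charges: the three designated
#' ADP oxygens carry -1 each, the three phosphate oxygens carry `q_pi_o`
#' each, and Mg carries +2.
#'
#' @param q_his histidine charge (default +0.5).
#' @param q_pi_o charge per designated phosphate oxygen (default -1).
#' @param adp_oxygens atom names of the charged ADP oxygens.
#' @param pi_oxygens atom names of the charged phosphate oxygens.
#' @return A list of class `charge_options`.
#' @export
charge_options <- function(q_his = 0.5, q_pi_o = -1,
                           adp_oxygens = c("O1B", "O2B", "O3B"),
                           pi_oxygens = c("O1", "O2", "O3")) {
  structure(list(q_his = q_his, q_pi_o = q_pi_o,
                 adp_oxygens = adp_oxygens, pi_oxygens = pi_oxygens),
            class = "charge_options")
}

#' Assign residue and ligand charges
#'
#' @param ref a [reference_structure()].
#' @param opts a [charge_options()] configuration.
#' @return The structure with `beads$charge` and `ligand$charge` filled in.
#' @export
assign_charges <- function(ref, opts = charge_options()) {
  stopifnot(inherits(ref, "reference_structure"))
  rn <- ref$beads$resid
  q <- rep(0, length(rn))
  q[rn %in% c("ASP", "GLU")] <- -1
  q[rn %in% c("LYS", "ARG")] <- +1
  q[rn == "HIS"] <- opts$q_his
  known <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  if (any(!rn %in% known))
    warning("unknown residue name(s) assigned zero charge: ",
            paste(unique(rn[!rn %in% known]), collapse = ", "))
  ref$beads$charge <- q
  if (nrow(ref$ligand)) {
    lq <- rep(0, nrow(ref$ligand))
    lq[ref$ligand$parent == "Mg"] <- +2
    lq[ref$ligand$parent == "ADP" &
         ref$ligand$atom %in% opts$adp_oxygens] <- -1
    lq[ref$ligand$parent == "Pi" &
         ref$ligand$atom %in% opts$pi_oxygens] <- opts$q_pi_o
    ref$ligand$charge <- lq
  }
  ref
}

#' Helical symmetry parameters of the actin filament
#'
#' The filament is generated by a screw operation of `rot_per_subunit` about z
#' followed by `rise_per_subunit` along z per subunit. With the default
#' parameters (166.4 degrees, 2.759 nm) the 13-subunit repeat has length
#' 35.867 nm and a net twist of 3.2 degrees.
#'
#' @param rot_per_subunit rotation per subunit, degrees.
#' @param rise_per_subunit rise per subunit, nm.
#' @param subunits_per_repeat number of subunits in the approximate repeat.
#' @return A list of class `helical_params` with derived `repeat_length_nm`
#'   and `net_twist_deg` (mapped into (-180, 180]).
#' @export
helical_params <- function(rot_per_subunit = 166.4, rise_per_subunit = 2.759,
                           subunits_per_repeat = 13L) {
  stopifnot(rise_per_subunit > 0, subunits_per_repeat >= 1)
  twist <- (subunits_per_repeat * rot_per_subunit) %% 360
  if (twist > 180) twist <- twist - 360
  structure(list(rot_per_subunit = rot_per_subunit,
                 rise_per_subunit = rise_per_subunit,
                 subunits_per_repeat = as.integer(subunits_per_repeat),
                 repeat_length_nm = subunits_per_repeat * rise_per_subunit,
                 net_twist_deg = twist),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(paste0("helical_params: %.4g deg / %.4g nm per subunit; ",
                     "%d-subunit repeat = %.3f nm, net twist %.2f deg\n"),
              x$rot_per_subunit, x$rise_per_subunit, x$subunits_per_repeat,
              x$repeat_length_nm, x$net_twist_deg))
  invisible(x)
}

# rotate coordinates about z by ang (rad) and translate along z by dz (Angstrom)
.screw <- function(xyz, ang, dz) {
  ca <- cos(ang); sa <- sin(ang)
  cbind(ca * xyz[, 1] - sa * xyz[, 2],
        sa * xyz[, 1] + ca * xyz[, 2],
        xyz[, 3] + dz)
}

#' Build a helical filament from one subunit
#'
#' Subunit `k` (0-based) is the reference subunit rotated by
#' `k * rot_per_subunit` about z and translated by `k * rise_per_subunit`
#' along z.
#'
#' @param subunit a [reference_structure()] for one filament subunit.
#' @param n number of subunits (>= 1; 26 in the full-size model).
#' @param helix a [helical_params()] object.
#' @return A list of class `filament_model` with the transformed beads and
#'   heavy atoms (each carrying a `subunit` index), the generating subunit and
#'   helix.
#' @export
build_filament <- function(subunit, n = 26L, helix = helical_params()) {
  stopifnot(inherits(subunit, "reference_structure"))
  if (n < 1) stop("n must be >= 1")
  rot <- helix$rot_per_subunit * pi / 180
  rise <- helix$rise_per_subunit * 10  # nm -> Angstrom
  beads <- do.call(rbind, lapply(seq_len(n) - 1L, function(k) {
    b <- subunit$beads
    b[, c("x", "y", "z")] <- .screw(as.matrix(b[, c("x", "y", "z")]),
                                    k * rot, k * rise)
    b$subunit <- k + 1L
    b
  }))
  heavy <- do.call(rbind, lapply(seq_len(n) - 1L, function(k) {
    h <- subunit$heavy
    h[, c("x", "y", "z")] <- .screw(as.matrix(h[, c("x", "y", "z")]),
                                    k * rot, k * rise)
    h$subunit <- k + 1L
    h
  }))
  rownames(beads) <- rownames(heavy) <- NULL
  structure(list(subunit = subunit, n_subunits = as.integer(n), helix = helix,
                 beads = beads, heavy = heavy),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("filament_model: %d subunits x %d beads; repeat %.3f nm, net twist %.2f deg\n",
              x$n_subunits, nrow(x$subunit$beads),
              x$helix$repeat_length_nm, x$helix$net_twist_deg))
  invisible(x)
}
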