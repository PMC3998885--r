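# Shared fixtures, built in code and cached across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .cache)) assign(name, fn(), envir = .cache)
  get(name, envir = .cache)
}

mini <- function() cached("mini", function() make_mini_system())

landscape_set <- function() cached("lset", function() make_landscape_set())

main_mc_run <- function() cached("main_mc", function() {
  run_trajectories(landscape_set(), kinetic_network("main"), mc_params(),
                   n_traj = 8000L, seed = 20240301L)
})

# write a small PDB file; residues is a data.frame with chain, resno, resid
# and one CA row each; het optionally appends HETATM records
write_toy_pdb <- function(path, residues, het = NULL) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    atoms <- r$atoms[[1]]
    for (a in seq_len(nrow(atoms))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, atoms$name[a], r$resid, r$chain, r$resno,
        atoms$x[a], atoms$y[a], atoms$z[a]))
    }
  }
  if (!is.null(het)) {
    for (a in seq_len(nrow(het))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, het$name[a], het$resid[a], het$chain[a], het$resno[a],
        het$x[a], het$y[a], het$z[a]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_residue <- function(chain, resno, resid, x, y, z, extra = NULL) {
  atoms <- data.frame(name = "CA", x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  if (!is.null(extra)) atoms <- rbind(atoms, extra)
  data.frame(chain = chain, resno = resno, resid = resid,
             atoms = I(list(atoms)), stringsAsFactors = FALSE)
}

# a bare single-chain cg system (no actin) built from explicit coordinates
chain_system <- function(xyz, resid = NULL, params = forcefield_params(),
                         flexible = NULL) {
  n <- nrow(xyz)
  if (is.null(resid)) resid <- rep("GLY", n)
  beads <- data.frame(chain = "A", resno = seq_len(n), resid = resid,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  ref <- reference_structure(beads)
  if (!is.null(flexible)) ref$beads$flexible[flexible] <- TRUE
  ref <- assign_charges(ref)
  topo <- build_topology(ref)
  assemble_system(myosin = topo, actin = NULL, params = params,
                  motor_idx = seq_len(n))
}
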