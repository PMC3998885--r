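# Model archives: JSON metadata plus tabular bead / heavy-atom / ligand
# files. Round trips are lossless for positions (to the printed precision),
# charges and flexibility flags.

#' Write / read a reference-structure archive
#'
#' The archive is a directory containing `beads.tsv`, `heavy.tsv`,
#' `ligand.tsv` and `meta.json`.
#'
#' @param ref a [reference_structure()].
#' @param dir archive directory (created if needed).
#' @return `write_model`: `dir`, invisibly; `read_model`: a
#'   [reference_structure()].
#' @export
write_model <- function(ref, dir) {
  stopifnot(inherits(ref, "reference_structure"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(ref$beads, "beads.tsv")
  wt(ref$heavy, "heavy.tsv")
  wt(ref$ligand, "ligand.tsv")
  jsonlite::write_json(list(label = ref$label, format = "motorscape-model",
                            version = 1L),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(f, cls = NULL) {
    d <- read.table(file.path(dir, f), header = TRUE, sep = "\t",
                    colClasses = cls, stringsAsFactors = FALSE)
    d
  }
  beads <- rd("beads.tsv", c(chain = "character"))
  heavy <- rd("heavy.tsv", c(chain = "character"))
  ligand <- rd("ligand.tsv", c(atom = "character", parent = "character"))
  reference_structure(beads, heavy = heavy,
                      ligand = if (nrow(ligand)) ligand else NULL,
                      label = meta$label)
}

#' Write a sampler output (trajectory TSV + JSON metadata sidecar)
#'
#' @param out a [run_window()] result.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sampler_output <- function(out, path) {
  stopifnot(inherits(out, "sampler_output"))
  write.table(out$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- out$metadata
  meta$window <- unclass(out$window)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
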