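#' Read a protein structure for in-silico spin labelling
#'
#' Parses a PDB file (via bio3d), keeps protein heavy atoms, resolves
#' alternate locations by highest occupancy and converts coordinates from
#' Angstrom to nm.  Waters and hetero records are excluded by default.
#'
#' @param path Path to a PDB file.
#' @param keep_hetero Keep HETATM records (waters are always dropped)?
#' @return An object of class `spin_structure`: data frame `atoms` with
#'   columns `chain`, `resno`, `resid`, `elety` (atom name), `x`, `y`,
#'   `z` (nm), `o` (occupancy), plus `source` (the file path).
#' @export
read_structure <- function(path, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  at <- at[!(toupper(trimws(elem)) %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no protein heavy atoms in ", path)
  # altloc policy: one position per atom, highest occupancy wins
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(-occ)
  keep <- sort(ord[!duplicated(key[ord])])
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety),
                      x = at$x / 10, y = at$y / 10, z = at$z / 10,
                      o = occ[keep], stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "spin_structure")
}

# Reject malformed coordinate records before handing the file to the
# parser, so the error can name the offending line.
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in rec) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords))
      stop(sprintf("malformed coordinate record at line %d of %s", i, path))
  }
  invisible(TRUE)
}

#' @export
print.spin_structure <- function(x, ...) {
  cat(sprintf("<spin_structure> %d heavy atoms, %d chains (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              basename(x$source %||% "in memory")))
  invisible(x)
}
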