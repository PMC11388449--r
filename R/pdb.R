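# Minimal fixed-column PDB I/O. No R PDB reader ships with the analysis
# stack this package targets, and the structures handled here (receptor
# snapshots, generated fixtures) only need ATOM records, so a small
# strict parser is used instead of an external dependency.

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, NA. = 22.990, CL = 35.45,
                   F = 18.998, BR = 79.904, FE = 55.845, ZN = 65.38,
                   MG = 24.305, K = 39.098, CA. = 40.078)

# guess the element from the PDB atom name when columns 77-78 are blank:
# strip leading digits, take the first letter (two-letter metals are not
# expected among protein heavy atoms handled here)
guess_element <- function(name) {
  nm <- sub("^[0-9]+", "", trimws(name))
  toupper(substr(nm, 1L, 1L))
}

atom_masses <- function(element) {
  key <- ifelse(element %in% c("NA", "CA"), paste0(element, "."), element)
  m <- .element_mass[key]
  if (anyNA(m))
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Structure frame
#'
#' One structural snapshot: a table of atoms with coordinates in Angstrom
#' and per-atom masses. Constructed from parsed PDB records or built
#' programmatically (see [generate_toy_structure()]).
#'
#' @param atoms data.frame with columns `atom_name`, `res_name`, `chain`,
#'   `res_num`, `x`, `y`, `z`, `element`; a `mass` column is derived from
#'   `element` when absent.
#' @param frame_id frame identifier.
#' @param time_ps time stamp in picoseconds (>= 0).
#' @return An object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, frame_id = "frame1", time_ps = 0) {
  need <- c("atom_name", "res_name", "chain", "res_num", "x", "y", "z",
            "element")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("structure_frame: atoms must have columns ",
         paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("structure_frame: non-finite coordinates")
  if (is.null(atoms$mass)) atoms$mass <- atom_masses(atoms$element)
  if (any(atoms$mass <= 0)) stop("structure_frame: masses must be > 0")
  if (time_ps < 0) stop("structure_frame: time_ps must be >= 0")
  structure(list(atoms = atoms, frame_id = frame_id, time_ps = time_ps),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %s (t=%g ps): %d atoms, %d residues\n",
              x$frame_id, x$time_ps, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "res_num")]))))
  invisible(x)
}

parse_pdb_lines <- function(lines, frame_id, time_ps = 0) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("read_pdb: no ATOM/HETATM records")
  atom_name <- trimws(substr(rec, 13L, 16L))
  res_name <- trimws(substr(rec, 18L, 20L))
  chain <- trimws(substr(rec, 22L, 22L))
  res_num <- as.integer(substr(rec, 23L, 26L))
  x <- as.numeric(substr(rec, 31L, 38L))
  y <- as.numeric(substr(rec, 39L, 46L))
  z <- as.numeric(substr(rec, 47L, 54L))
  element <- toupper(trimws(substr(rec, 77L, 78L)))
  element[element == ""] <- guess_element(atom_name[element == ""])
  if (anyNA(res_num) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("read_pdb: malformed coordinate record")
  structure_frame(data.frame(atom_name = atom_name, res_name = res_name,
                             chain = chain, res_num = res_num,
                             x = x, y = y, z = z, element = element,
                             stringsAsFactors = FALSE),
                  frame_id = frame_id, time_ps = time_ps)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records of a single-model PDB file into a
#' [structure_frame()].
#'
#' @param path PDB file.
#' @param frame_id,time_ps frame metadata (default: file name, t = 0).
#' @return A `structure_frame`.
#' @export
read_pdb <- function(path, frame_id = basename(path), time_ps = 0) {
  parse_pdb_lines(readLines(path), frame_id, time_ps)
}

#' Read a multi-model PDB trajectory
#'
#' Splits a PDB file on MODEL/ENDMDL records and returns one
#' [structure_frame()] per model. `dt_ps` sets the time stamp spacing
#' (frame k gets `t = (k-1) * dt_ps`).
#'
#' @param path multi-model PDB file.
#' @param dt_ps snapshot interval in ps (default 100, a common trajectory
#'   stride for pKa post-processing).
#' @return List of `structure_frame` objects.
#' @export
read_pdb_trajectory <- function(path, dt_ps = 100) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(read_pdb(path)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("read_pdb_trajectory: unbalanced MODEL/ENDMDL records")
  lapply(seq_along(starts), function(k)
    parse_pdb_lines(lines[(starts[k] + 1L):(ends[k] - 1L)],
                    frame_id = sprintf("model%d", k),
                    time_ps = (k - 1L) * dt_ps))
}

#' Write a structure frame as PDB
#'
#' @param frame a `structure_frame` (or list of frames, written as
#'   MODEL/ENDMDL blocks).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, path) {
  fmt1 <- function(fr) {
    a <- fr$atoms
    name4 <- ifelse(nchar(a$atom_name) < 4L,
                    sprintf(" %-3s", a$atom_name),
                    substr(a$atom_name, 1L, 4L))
    sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$res_name, a$chain, a$res_num,
      a$x, a$y, a$z, 1, 0, a$element)
  }
  if (inherits(frame, "structure_frame")) {
    writeLines(c(fmt1(frame), "END"), path)
  } else {
    out <- unlist(lapply(seq_along(frame), function(k)
      c(sprintf("MODEL %8d", k), fmt1(frame[[k]]), "ENDMDL")))
    writeLines(c(out, "END"), path)
  }
  invisible(path)
}
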