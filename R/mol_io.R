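# Readers and writers for the file formats the toolkit touches:
# fixed-column PDB, Wavefront OBJ, OpenDX scalar grids and the JSON
# field-line dialect.

#' Parsing policy for PDB files
#'
#' Bundles the switches that control which records [parse_pdb()] accepts.
#' The defaults keep the first MODEL of a multi-model file, the first
#' alternate location of each atom, HETATM records, hydrogens and waters.
#' Keeping the policy in one object lets atom counts be calibrated against
#' published per-entry sizes without touching the parser.
#'
#' @param first_model_only keep only records from the first MODEL/ENDMDL
#'   block (files without MODEL records are a single implicit model).
#' @param first_alt_loc for atoms with alternate locations, keep only the
#'   first record seen per (chain, residue, insertion, atom-name) key.
#' @param keep_hetero keep HETATM records.
#' @param keep_hydrogens keep atoms whose element is H or D.
#' @param keep_waters keep residues named HOH, WAT, DOD or H2O.
#' @return A list of class \code{"pdb_policy"}.
#' @export
pdb_policy <- function(first_model_only = TRUE, first_alt_loc = TRUE,
                       keep_hetero = TRUE, keep_hydrogens = TRUE,
                       keep_waters = TRUE) {
  structure(list(first_model_only = isTRUE(first_model_only),
                 first_alt_loc = isTRUE(first_alt_loc),
                 keep_hetero = isTRUE(keep_hetero),
                 keep_hydrogens = isTRUE(keep_hydrogens),
                 keep_waters = isTRUE(keep_waters)),
            class = "pdb_policy")
}

WATER_RES <- c("HOH", "WAT", "DOD", "H2O")

#' Molecular structure container
#'
#' An atom table plus a (possibly empty) bond list. Atoms are stored in
#' file order; bonds are 1-based index pairs with i < j, filled in by
#' [detect_bonds()].
#'
#' @param atoms data.frame with columns serial, name, element, alt_loc,
#'   res_name, chain, res_id, insertion, x, y, z, occupancy, is_hetero.
#' @param bonds integer matrix with two columns (i, j), 1-based, i < j.
#' @param source_id identifier of the source (file name, PDB id, ...).
#' @return Object of class \code{"mol_structure"}.
#' @export
mol_structure <- function(atoms, bonds = empty_bonds(), source_id = "") {
  stopifnot(is.data.frame(atoms))
  bonds <- as_bond_matrix(bonds, nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds, source_id = source_id),
            class = "mol_structure")
}

empty_bonds <- function() matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("i", "j")))

as_bond_matrix <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(bonds)) {
    if (any(bonds < 1L) || any(bonds > n_atoms))
      stop("bond indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    swap <- bonds[, 1] > bonds[, 2]
    bonds[swap, ] <- bonds[swap, 2:1]
    if (anyDuplicated(bonds)) stop("duplicate bond pairs")
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  bonds
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure '%s': %d atoms, %d bonds\n",
              x$source_id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param structure a \code{mol_structure}.
#' @return n x 3 numeric matrix of positions in Angstrom.
#' @export
atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# -- PDB ---------------------------------------------------------------------

pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Parse fixed-column PDB text
#'
#' Reads ATOM/HETATM records per the wwPDB v3.3 column layout. The element
#' is taken from columns 77-78 when present, otherwise derived from the
#' atom name (digits stripped; a two-letter symbol is accepted only when
#' the name starts in column 13, where two-letter elements are
#' left-justified). Bonds are not derived here; see [detect_bonds()].
#'
#' @param text PDB file content as a single string or character vector of
#'   lines.
#' @param policy a [pdb_policy()].
#' @param source_id identifier stored on the result.
#' @return A [mol_structure()] with an empty bond list.
#' @export
parse_pdb <- function(text, policy = pdb_policy(), source_id = "pdb") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) == 0L || all(!nzchar(trimws2(lines))))
    stop("empty PDB input")
  stopifnot(inherits(policy, "pdb_policy"))

  rec <- pdb_field(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  # model bookkeeping: records before the first MODEL belong to model 1
  model_no <- cumsum(substr(lines, 1, 5) == "MODEL")
  model_no[model_no == 0L] <- 1L
  keep <- is_atom
  if (policy$first_model_only) keep <- keep & model_no == min(model_no[is_atom])

  idx <- which(keep)
  al <- lines[idx]
  # pad short lines so fixed-column extraction is safe
  al <- formatC(al, width = 80, flag = "-")

  num_field <- function(from, to, what) {
    raw <- trimws2(pdb_field(al, from, to))
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(v) & nzchar(raw) | (!nzchar(raw) & what == "coordinate"))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, idx[bad[1]], trimws2(lines[idx[bad[1]]])))
    v
  }

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(trimws2(pdb_field(al, 7, 11)))),
    name = trimws2(pdb_field(al, 13, 16)),
    element = "",
    alt_loc = trimws2(pdb_field(al, 17, 17)),
    res_name = trimws2(pdb_field(al, 18, 20)),
    chain = trimws2(pdb_field(al, 22, 22)),
    res_id = suppressWarnings(as.integer(trimws2(pdb_field(al, 23, 26)))),
    insertion = trimws2(pdb_field(al, 27, 27)),
    x = num_field(31, 38, "coordinate"),
    y = num_field(39, 46, "coordinate"),
    z = num_field(47, 54, "coordinate"),
    occupancy = num_field(55, 60, "occupancy"),
    is_hetero = pdb_field(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1.0
  atoms$res_id[is.na(atoms$res_id)] <- 0L
  atoms$serial[is.na(atoms$serial)] <- seq_len(nrow(atoms))[is.na(atoms$serial)]

  atoms$element <- derive_elements(pdb_field(al, 77, 78), pdb_field(al, 13, 16))

  sel <- rep(TRUE, nrow(atoms))
  if (policy$first_alt_loc && any(nzchar(atoms$alt_loc))) {
    # keep only records carrying the first-seen alt_loc of their atom key
    key <- paste(atoms$chain, atoms$res_id, atoms$insertion, atoms$res_name,
                 atoms$name, sep = "\r")
    haskey <- nzchar(atoms$alt_loc)
    first_alt <- vapply(split(atoms$alt_loc[haskey], key[haskey]), `[[`, "", 1L)
    sel[haskey] <- atoms$alt_loc[haskey] == first_alt[key[haskey]]
  }
  if (!policy$keep_hetero) sel <- sel & !atoms$is_hetero
  if (!policy$keep_hydrogens) sel <- sel & !(atoms$element %in% c("H", "D"))
  if (!policy$keep_waters) sel <- sel & !(atoms$res_name %in% WATER_RES)

  atoms <- atoms[sel, , drop = FALSE]
  rownames(atoms) <- NULL
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates after parsing")
  mol_structure(atoms, source_id = source_id)
}

# Element from columns 77-78 with atom-name fallback.
derive_elements <- function(elem_field, name_field) {
  el <- toupper(trimws2(elem_field))
  el <- sub("[^A-Z].*$", "", el)         # strip charge suffixes like "1+"
  need <- !nzchar(el)
  if (any(need)) {
    nm <- toupper(name_field[need])
    first_col_used <- substr(nm, 1, 1) != " "   # name starts in column 13
    letters_only <- gsub("[^A-Z]", "", nm)
    two <- substr(letters_only, 1, 2)
    one <- substr(letters_only, 1, 1)
    guess <- ifelse(first_col_used & two %in% KNOWN_TWO_LETTER, two, one)
    guess[!nzchar(guess)] <- "X"
    el[need] <- guess
  }
  el
}

KNOWN_TWO_LETTER <- c("FE", "MG", "MN", "ZN", "CA", "NA", "CL", "BR", "CU",
                      "SE", "CO", "NI", "CD", "HG", "SI", "AL", "LI", "BE")

#' Fetch a PDB entry from the RCSB server
#'
#' Convenience download of the PDB-format file for a 4-character entry id.
#' Lower-case ids are normalized to upper case. Purely optional: everything
#' else in the package works from local text.
#'
#' @param pdb_id 4-character PDB id, e.g. "1KX2".
#' @param timeout seconds before the download is abandoned.
#' @return The entry's PDB text (single string).
#' @export
fetch_pdb <- function(pdb_id, timeout = 60) {
  if (!is.character(pdb_id) || length(pdb_id) != 1L || nchar(pdb_id) != 4L)
    stop("pdb_id must be a single 4-character string")
  id <- toupper(pdb_id)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
  txt <- tryCatch({
    con <- url(url)
    on.exit(close(con), add = TRUE)
    old <- options(timeout = timeout); on.exit(options(old), add = TRUE)
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }, error = function(e) stop(sprintf("failed to fetch PDB entry %s: %s",
                                      id, conditionMessage(e)), call. = FALSE))
  if (!nzchar(txt)) stop(sprintf("fetch of PDB entry %s returned no data", id))
  txt
}

# -- Wavefront OBJ -----------------------------------------------------------

#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix, Angstrom.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @return Object of class \code{"triangle_mesh"}.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (any(faces < 1L) || any(faces > nrow(vertices))))
    stop("face indices out of range")
  if (!is.null(normals)) {
    normals <- matrix(as.numeric(normals), ncol = 3)
    stopifnot(nrow(normals) == nrow(vertices))
    len <- row_norms(normals)
    if (any(abs(len - 1) > 1e-6)) stop("normals must have unit length")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' Read a Wavefront OBJ mesh
#'
#' Handles v, vn and f records; faces with more than three vertices are
#' fan-triangulated; f entries of the form v/vt/vn keep only the vertex
#' index; negative indices are resolved relative to the vertices read so
#' far, per the OBJ convention.
#'
#' @param text OBJ content as string or character vector of lines.
#' @return A [triangle_mesh()].
#' @export
read_obj <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  verts <- list(); norms <- list(); faces <- list()
  for (ln in lines) {
    ln <- trimws2(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\\s+")[[1]]
    tag <- parts[1]
    if (tag == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(parts[2:4])
    } else if (tag == "vn") {
      norms[[length(norms) + 1L]] <- as.numeric(parts[2:4])
    } else if (tag == "f") {
      vi <- as.integer(vapply(strsplit(parts[-1], "/", fixed = TRUE),
                              `[[`, "", 1L))
      nv <- length(verts)
      vi <- ifelse(vi < 0L, nv + vi + 1L, vi)
      if (any(vi < 1L | vi > nv))
        stop(sprintf("face references undefined vertex in line '%s'", ln))
      if (length(vi) < 3L) stop("face with fewer than 3 vertices")
      for (k in seq_len(length(vi) - 2L))
        faces[[length(faces) + 1L]] <- c(vi[1], vi[k + 1L], vi[k + 2L])
    }
  }
  v <- if (length(verts)) do.call(rbind, verts) else matrix(numeric(0), ncol = 3)
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), ncol = 3)
  n <- if (length(norms) == nrow(v) && nrow(v) > 0) do.call(rbind, norms) else NULL
  if (!is.null(n)) {
    len <- row_norms(n)
    len[len == 0] <- 1
    n <- n / len
  }
  triangle_mesh(v, f, n)
}

#' Serialize a mesh to Wavefront OBJ text
#'
#' Emits v lines, vn lines when normals are present, and f lines with
#' 1-based indices. Output is deterministic for a given mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @return OBJ text as a single string.
#' @export
write_obj <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  fmt <- function(m, tag) if (nrow(m) == 0) character(0) else
    sprintf("%s %.9g %.9g %.9g", tag, m[, 1], m[, 2], m[, 3])
  out <- c(fmt(mesh$vertices, "v"),
           if (!is.null(mesh$normals)) fmt(mesh$normals, "vn"),
           if (nrow(mesh$faces)) sprintf("f %d %d %d", mesh$faces[, 1],
                                         mesh$faces[, 2], mesh$faces[, 3]))
  paste0(paste(out, collapse = "\n"), if (length(out)) "\n" else "")
}

# -- OpenDX scalar grids -----------------------------------------------------

#' Read an OpenDX ASCII scalar grid
#'
#' Supports the gridpositions/gridconnections/array layout written by APBS
#' and friends. Only axis-aligned grids (diagonal delta vectors) are
#' accepted. Data are stored so that the grid's third (z) index varies
#' fastest in file order, the standard OpenDX layout.
#'
#' @param text OpenDX content as string or character vector of lines.
#' @return A [scalar_grid()].
#' @export
read_opendx <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[!startsWith(trimws2(lines), "#")]
  hdr_end <- grep("data follows", lines)
  if (length(hdr_end) == 0L) stop("no 'data follows' marker: not an OpenDX scalar file")
  hdr <- lines[seq_len(hdr_end[1])]

  counts_line <- grep("gridpositions", hdr, value = TRUE)
  if (length(counts_line) == 0L) stop("missing gridpositions header")
  counts <- as.integer(tail(strsplit(trimws2(counts_line[1]), "\\s+")[[1]], 3))

  origin_line <- grep("^\\s*origin", hdr, value = TRUE)
  if (length(origin_line) == 0L) stop("missing origin line")
  origin <- as.numeric(strsplit(trimws2(origin_line[1]), "\\s+")[[1]][2:4])

  delta_lines <- grep("^\\s*delta", hdr, value = TRUE)
  if (length(delta_lines) != 3L) stop("expected exactly 3 delta lines")
  deltas <- t(vapply(delta_lines, function(l)
    as.numeric(strsplit(trimws2(l), "\\s+")[[1]][2:4]), numeric(3)))
  offdiag <- deltas; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-12))
    stop("unsupported OpenDX grid: delta vectors are not axis-aligned")
  spacing <- diag(deltas)

  items_line <- grep("class array", hdr, value = TRUE)
  n_items <- if (length(items_line)) {
    toks <- strsplit(trimws2(items_line[1]), "\\s+")[[1]]
    as.integer(toks[which(toks == "items") + 1L])
  } else prod(counts)

  data_lines <- lines[-seq_len(hdr_end[1])]
  # stop at trailing object/attribute footer lines if present
  footer <- grep("^\\s*(object|attribute|component)", data_lines)
  if (length(footer)) data_lines <- data_lines[seq_len(footer[1] - 1L)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws2(data_lines), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != n_items)
    stop(sprintf("OpenDX item count mismatch: header declares %d, data has %d",
                 n_items, length(vals)))
  if (n_items != prod(counts))
    stop("OpenDX item count does not match grid dimensions")
  # file order: z fastest -> fill (z, y, x) then transpose to [x, y, z]
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  scalar_grid(counts, origin, spacing, arr)
}

#' Serialize a scalar grid to OpenDX ASCII
#'
#' @param grid a [scalar_grid()].
#' @param comment optional comment placed at the top of the file.
#' @return OpenDX text as a single string.
#' @export
write_opendx <- function(grid, comment = "written by hyperview") {
  stopifnot(inherits(grid, "scalar_grid"))
  n <- grid$counts
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  nfull <- (length(vals) %/% 3L) * 3L
  rows <- if (nfull > 0)
    apply(matrix(vals[seq_len(nfull)], ncol = 3, byrow = TRUE), 1,
          function(r) paste(sprintf("%.9e", r), collapse = " "))
  else character(0)
  if (nfull < length(vals))
    rows <- c(rows, paste(sprintf("%.9e", vals[(nfull + 1L):length(vals)]),
                          collapse = " "))
  paste0(paste(c(
    paste0("# ", comment),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.9e %.9e %.9e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.9e 0.0 0.0", grid$spacing[1]),
    sprintf("delta 0.0 %.9e 0.0", grid$spacing[2]),
    sprintf("delta 0.0 0.0 %.9e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n)),
    rows,
    "attribute \"dep\" string \"positions\""), collapse = "\n"), "\n")
}

# -- Field-line JSON ---------------------------------------------------------

#' Read field lines from the toolkit's JSON dialect
#'
#' The dialect is \code{{"lines": [{"points": [[x,y,z], ...]}, ...]}}.
#' Cumulative arclengths are computed on load.
#'
#' @param text JSON text.
#' @return A [field_line_set()].
#' @export
read_fieldlines_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$lines)) stop("field-line JSON must have a 'lines' array")
  lines <- lapply(obj$lines, function(l) {
    pts <- l$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    pts <- matrix(suppressWarnings(as.numeric(pts)), ncol = 3)
    if (any(!is.finite(pts))) stop("non-numeric coordinate in field line")
    if (nrow(pts) < 2L) stop("field line with fewer than 2 points")
    field_line(pts)
  })
  field_line_set(lines, source = "json")
}

#' Serialize a field-line set to the JSON dialect
#'
#' @param set a [field_line_set()].
#' @return JSON text.
#' @export
write_fieldlines_json <- function(set) {
  stopifnot(inherits(set, "field_line_set"))
  obj <- list(lines = lapply(set$lines, function(l)
    list(points = unname(l$points))))
  as.character(jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE))
}
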