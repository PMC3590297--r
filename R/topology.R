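# Bond perception from interatomic distances, and per-atom radius
# assignment. The distance rule is the classic viewer heuristic: atoms i
# and j are bonded when min_dist < d(i,j) <= rc_i + rc_j + tolerance,
# with rc the covalent radii.

#' Load the element constants table
#'
#' Reads the plain-text table shipped with the package (covalent and van
#' der Waals radii, masses and display colors per element; row X is the
#' fallback for unknown symbols), or a user-provided file of the same
#' layout.
#'
#' @param path optional path to an alternative table.
#' @return data.frame of class \code{"element_table"}, keyed by the
#'   \code{element} column (upper-case symbols).
#' @export
element_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "elements.tsv", package = "hyperview")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = character(0),  # "NA" is sodium
                           colClasses = c(element = "character"))
  need <- c("element", "covalent", "vdw", "mass", "r", "g", "b")
  if (!all(need %in% names(tab))) stop("element table missing columns")
  if (any(tab$covalent <= 0) || any(tab$vdw <= 0))
    stop("element radii must be positive")
  if (!"X" %in% tab$element) stop("element table must contain a default X row")
  rownames(tab) <- toupper(tab$element)
  class(tab) <- c("element_table", "data.frame")
  tab
}

# Look up a column for a vector of element symbols, falling back to the X
# row (with one warning) for unknown symbols.
element_lookup <- function(table, elements, column) {
  el <- toupper(elements)
  unknown <- !(el %in% rownames(table))
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default radii",
                    paste(unique(el[unknown]), collapse = ", ")))
    el[unknown] <- "X"
  }
  table[el, column]
}

#' Bond-detection parameters
#'
#' @param tolerance slack added to the covalent-radius sum, Angstrom.
#' @param min_dist pairs closer than this are never bonded (guards against
#'   duplicated/overlapping atoms), Angstrom.
#' @param max_dist_cap cutoff used when neither element is in the table,
#'   Angstrom.
#' @param neighbor_cell spatial-hash cell size, Angstrom; \code{NULL}
#'   derives it from the largest possible cutoff.
#' @param bond_waters_to_solute if \code{FALSE} (default), water residues
#'   only bond internally (O-H), never to non-water atoms.
#' @param h_single_bond if \code{TRUE} (default), a hydrogen is bonded to
#'   at most its single nearest eligible heavy atom.
#' @return list of class \code{"bond_params"}.
#' @export
bond_params <- function(tolerance = 0.4, min_dist = 0.4, max_dist_cap = 2.5,
                        neighbor_cell = NULL, bond_waters_to_solute = FALSE,
                        h_single_bond = TRUE) {
  stopifnot(min_dist > 0, tolerance >= 0, max_dist_cap > min_dist)
  structure(list(tolerance = tolerance, min_dist = min_dist,
                 max_dist_cap = max_dist_cap, neighbor_cell = neighbor_cell,
                 bond_waters_to_solute = isTRUE(bond_waters_to_solute),
                 h_single_bond = isTRUE(h_single_bond)),
            class = "bond_params")
}

#' Detect bonds from interatomic distances
#'
#' Creates bond (i, j) whenever \code{min_dist < d(i,j) <= rc_i + rc_j +
#' tolerance} with rc the covalent radii. Candidate pairs come from a
#' uniform spatial hash so the cost stays near-linear in atom count.
#' Hydrogens are restricted to their single nearest eligible heavy
#' neighbor, and waters do not bond to non-water atoms (both rules can be
#' switched off via [bond_params()]).
#'
#' @param structure a [mol_structure()].
#' @param table an [element_table()].
#' @param params a [bond_params()].
#' @return The structure with its \code{bonds} matrix filled; atoms
#'   untouched.
#' @export
detect_bonds <- function(structure, table = element_table(),
                         params = bond_params()) {
  stopifnot(inherits(structure, "mol_structure"),
            inherits(params, "bond_params"))
  n <- nrow(structure$atoms)
  if (n < 2L) {
    structure$bonds <- empty_bonds()
    return(structure)
  }
  xyz <- atom_coords(structure)
  el <- toupper(structure$atoms$element)
  known <- el %in% rownames(table)
  rc <- element_lookup(table, el, "covalent")

  cutmax <- 2 * max(rc) + params$tolerance
  cs <- params$neighbor_cell %||% max(cutmax, params$max_dist_cap)
  pairs <- neighbor_pairs(xyz, cs)
  if (nrow(pairs) == 0L) {
    structure$bonds <- empty_bonds()
    return(structure)
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  d <- row_norms(xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])
  cutoff <- ifelse(!known[i] & !known[j], params$max_dist_cap,
                   rc[i] + rc[j] + params$tolerance)
  ok <- d > params$min_dist & d <= cutoff

  is_w <- structure$atoms$res_name %in% WATER_RES
  if (!params$bond_waters_to_solute && any(is_w)) {
    res_key <- paste(structure$atoms$chain, structure$atoms$res_id,
                     structure$atoms$insertion, sep = "\r")
    same_res <- res_key[i] == res_key[j]
    ok <- ok & ((!is_w[i] & !is_w[j]) | (is_w[i] & is_w[j] & same_res))
  }

  is_h <- el %in% c("H", "D")
  if (params$h_single_bond && any(is_h)) {
    ok <- ok & !(is_h[i] & is_h[j])
    cand <- which(ok & (is_h[i] | is_h[j]))
    if (length(cand)) {
      h_of <- ifelse(is_h[i[cand]], i[cand], j[cand])
      keep_row <- unlist(lapply(split(cand, h_of), function(rows)
        rows[which.min(d[rows])]), use.names = FALSE)
      drop <- setdiff(cand, keep_row)
      ok[drop] <- FALSE
    }
  }

  structure$bonds <- as_bond_matrix(cbind(i[ok], j[ok]), n)
  structure
}

# Candidate close pairs (i < j) from a uniform-grid spatial hash with cell
# size cs: all pairs within one cell plus pairs across the 13 forward
# neighbor cells. Every pair closer than cs is guaranteed to be returned.
neighbor_pairs <- function(xyz, cs) {
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cs)
  key <- cell[, 1] + 1e4 * (cell[, 2] + 1e4 * cell[, 3])  # collision-free for < 1e4 cells/axis
  members <- split(seq_len(nrow(xyz)), key)
  keys <- as.numeric(names(members))
  koff <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  koff <- koff[order(koff[, 3], koff[, 2], koff[, 1]), , drop = FALSE]
  forward <- koff[, 1] + 1e4 * (koff[, 2] + 1e4 * koff[, 3])
  forward <- forward[forward > 0]
  out <- vector("list", length(members) * 2L)
  nout <- 0L
  for (ci in seq_along(members)) {
    a <- members[[ci]]
    if (length(a) > 1L) {
      nout <- nout + 1L
      out[[nout]] <- pairs_within(a)
    }
    bi <- match(keys[ci] + forward, keys)
    for (b in members[bi[!is.na(bi)]]) {
      nout <- nout + 1L
      out[[nout]] <- cbind(rep(a, each = length(b)), rep(b, length(a)))
    }
  }
  if (nout == 0L) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out[seq_len(nout)])
  swap <- m[, 1] > m[, 2]
  m[swap, ] <- m[swap, 2:1]
  m
}

pairs_within <- function(a) {
  n <- length(a)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(a[i], a[j])
}

#' Assign per-atom radii
#'
#' @param structure a [mol_structure()].
#' @param table an [element_table()].
#' @param scheme \code{"vdw"}, \code{"covalent"} or \code{"uniform"}.
#' @param r radius used by the uniform scheme, Angstrom.
#' @return numeric vector, one radius per atom.
#' @export
assign_radii <- function(structure, table = element_table(),
                         scheme = c("vdw", "covalent", "uniform"), r = 1.0) {
  scheme <- match.arg(scheme)
  n <- nrow(structure$atoms)
  if (scheme == "uniform") {
    stopifnot(r > 0)
    return(rep(as.numeric(r), n))
  }
  element_lookup(table, structure$atoms$element, scheme)
}

#' Per-atom display colors from the element table
#'
#' @param structure a [mol_structure()].
#' @param table an [element_table()].
#' @return n x 3 matrix of RGB colors in [0, 1].
#' @export
element_colors <- function(structure, table = element_table()) {
  el <- toupper(structure$atoms$element)
  el[!(el %in% rownames(table))] <- "X"
  as.matrix(table[el, c("r", "g", "b")])
}
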