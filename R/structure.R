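#' Molecular structure container
#'
#' A `cage_structure` is a light S3 list holding one frame of a molecular
#' system: element symbols, Cartesian coordinates in Angstrom, and (once
#' perceived) a bond set. Multi-frame files yield a `cage_trajectory`, a list
#' of `cage_structure` objects sharing the same atoms in the same order.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param bonds integer m x 2 matrix of bonded atom-index pairs (1-based,
#'   each row `i < j`), or `NULL` if not yet perceived.
#' @param title free-text title/comment line.
#' @param resid optional per-atom residue names (PDB input), used for
#'   selection/filtering.
#' @return A `cage_structure` object.
#' @export
cage_structure <- function(elements, coords, bonds = NULL, title = "",
                           resid = NULL) {
  elements <- normalize_element(as.character(elements))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != n)
    data_error("coords must be an N x 3 matrix matching the element count")
  if (!all(is.finite(coords)))
    data_error("coordinates must all be finite")
  if (!is.null(bonds)) bonds <- validate_bonds(bonds, n)
  if (!is.null(resid) && length(resid) != n)
    data_error("resid must have one entry per atom")
  structure(
    list(elements = elements, coords = coords, bonds = bonds,
         frame_count = 1L, title = as.character(title)[1], resid = resid),
    class = "cage_structure")
}

validate_bonds <- function(bonds, n_atoms) {
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (length(bonds) == 0L) return(matrix(integer(), ncol = 2L))
  if (ncol(bonds) != 2L) data_error("bonds must be an m x 2 index matrix")
  if (any(bonds < 1L) || any(bonds > n_atoms))
    data_error("bond indices out of range")
  if (any(bonds[, 1] == bonds[, 2])) data_error("self-bonds are not allowed")
  ij <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  dimnames(ij) <- NULL
  ij <- unique(ij)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' @export
print.cage_structure <- function(x, ...) {
  cat(sprintf("<cage_structure> %d atoms (%s)%s\n", n_atoms(x),
              paste(names(sort(-table(x$elements))), collapse = ","),
              if (is.null(x$bonds)) "" else sprintf(", %d bonds", nrow(x$bonds))))
  invisible(x)
}

#' @export
print.cage_trajectory <- function(x, ...) {
  cat(sprintf("<cage_trajectory> %d frames x %d atoms\n",
              length(x), n_atoms(x[[1]])))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a `cage_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) length(x$elements)

new_trajectory <- function(frames) {
  structure(frames, class = "cage_trajectory")
}

#' Read a molecular structure or trajectory
#'
#' Reads XYZ (single- or multi-frame; element symbol in the first column) or
#' PDB (`ATOM`/`HETATM` records via \pkg{bio3d}) files. Elements and
#' coordinates are preserved exactly as parsed from the text.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; default guesses from the file extension.
#' @return A `cage_structure` for single-frame input, a `cage_trajectory`
#'   (list of `cage_structure`) for multi-frame XYZ.
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pdb") "pdb" else "xyz"
  }
  switch(format, xyz = read_xyz(path), pdb = read_pdb_structure(path))
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) parse_error(sprintf("empty XYZ file: %s", path))
  frames <- list()
  pos <- 1L
  n_ref <- NA_integer_
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0L)
      parse_error(sprintf("%s: line %d: expected atom count, got '%s'",
                          path, pos, lines[pos]))
    if (!is.na(n_ref) && n != n_ref)
      data_error(sprintf(
        "%s: frame %d has %d atoms but frame 1 has %d (inconsistent frames)",
        path, length(frames) + 1L, n, n_ref))
    n_ref <- n
    if (pos + 1L + n > length(lines))
      parse_error(sprintf("%s: truncated frame starting at line %d", path, pos))
    title <- lines[pos + 1L]
    el <- character(n); xyz <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      ln <- pos + 1L + k
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(tok) < 4L)
        parse_error(sprintf("%s: line %d: malformed atom line '%s'",
                            path, ln, lines[ln]))
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v))
        parse_error(sprintf("%s: line %d: non-numeric coordinates", path, ln))
      el[k] <- tok[1]; xyz[k, ] <- v
    }
    frames[[length(frames) + 1L]] <- cage_structure(el, xyz, title = title)
    pos <- pos + 2L + n
  }
  if (length(frames) == 1L) frames[[1]] else new_trajectory(frames)
}

read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || any(is.na(el) | !nzchar(trimws(el)))) {
    # fall back to the first letter(s) of the atom name
    el <- sub("[0-9'\"]*$", "", trimws(at$elety))
    el <- sub("^[0-9]+", "", el)
    el <- ifelse(nchar(el) > 2, substr(el, 1, 2), el)
  }
  cage_structure(trimws(el), cbind(at$x, at$y, at$z),
                 title = basename(path), resid = trimws(at$resid))
}

#' Write structures to an XYZ file
#'
#' Writes a single structure or a trajectory as (multi-frame) XYZ.
#'
#' @param x a `cage_structure` or `cage_trajectory`.
#' @param path output path.
#' @param digits coordinate decimal places (default 8, round-trip safe for
#'   downstream connectivity perception).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, digits = 8) {
  frames <- if (inherits(x, "cage_trajectory")) x else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%-3s %%16.%df %%16.%df %%16.%df", digits, digits, digits)
  for (fr in frames) {
    writeLines(c(as.character(n_atoms(fr)), fr$title), con)
    writeLines(sprintf(fmt, fr$elements, fr$coords[, 1], fr$coords[, 2],
                       fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Select a subset of atoms
#'
#' Filters a structure to the cage of interest, e.g. dropping counterions
#' (PF6-, BF4-, NO3-) and solvent before topology detection. Selection is by
#' element allow-list and/or residue names (PDB input). Bond indices are
#' remapped; bonds crossing the selection boundary are dropped.
#'
#' @param x a `cage_structure` or `cage_trajectory`.
#' @param elements character vector of element symbols to keep (`NULL` = all).
#' @param resid character vector of residue names to keep (`NULL` = all;
#'   requires PDB-derived input when used).
#' @return Filtered object of the same class.
#' @export
select_atoms <- function(x, elements = NULL, resid = NULL) {
  if (inherits(x, "cage_trajectory"))
    return(new_trajectory(lapply(x, select_atoms, elements = elements,
                                 resid = resid)))
  keep <- rep(TRUE, n_atoms(x))
  if (!is.null(elements))
    keep <- keep & x$elements %in% normalize_element(elements)
  if (!is.null(resid)) {
    if (is.null(x$resid))
      data_error("residue-based selection requires PDB input with residue names")
    keep <- keep & x$resid %in% resid
  }
  if (!any(keep)) data_error("selection removed every atom")
  idx <- which(keep)
  bonds <- NULL
  if (!is.null(x$bonds) && nrow(x$bonds)) {
    b <- x$bonds[x$bonds[, 1] %in% idx & x$bonds[, 2] %in% idx, , drop = FALSE]
    remap <- match(seq_len(n_atoms(x)), idx)
    bonds <- cbind(remap[b[, 1]], remap[b[, 2]])
  }
  cage_structure(x$elements[idx], x$coords[idx, , drop = FALSE], bonds,
                 title = x$title, resid = x$resid[idx])
}
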