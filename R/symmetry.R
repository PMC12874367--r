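#' Partition a molecular graph into symmetry-equivalence classes
#'
#' Iterative neighbourhood colour refinement (Morgan / 1-dimensional
#' Weisfeiler-Lehman): atoms start coloured by element; each round appends
#' the sorted multiset of neighbour colours and colours are re-canonicalised,
#' until the partition is stable. Two atoms end in the same class only if no
#' such graph invariant distinguishes them. For the ligands handled here the
#' refinement classes coincide with the automorphism orbits of the molecular
#' graph. Class order and labels are canonical (derived from the refinement
#' signature), so the partition is invariant under input atom permutation.
#'
#' For charge-grouping of a full cage the convention is a single ligand,
#' hydrogens included, Pd excluded: all four ligands are equivalent, and this
#' is the convention under which the endo-C ligand yields 19 classes and the
#' endo-N ligand 18.
#'
#' @param structure a `cage_structure` with bonds (perceived if missing), or
#'   any object with `elements` and `bonds` fields.
#' @param require_connected error on disconnected graphs (default TRUE; the
#'   grouping convention operates on one connected molecule).
#' @return A `cage_partition`: `classes` (list of disjoint 1-based atom-index
#'   vectors covering all atoms), `class_labels` (element + signature hash),
#'   `membership` (per-atom class id).
#' @export
equivalence_classes <- function(structure, require_connected = TRUE) {
  if (inherits(structure, "cage_structure") && is.null(structure$bonds))
    structure <- perceive_bonds(structure)
  el <- structure$elements
  n <- length(el)
  b <- structure$bonds
  if (require_connected && n > 1L) {
    g <- bond_graph(structure)
    if (igraph::components(g)$no != 1L)
      data_error("molecular graph is disconnected; grouping requires one connected molecule")
  }
  # adjacency list
  adj <- vector("list", n)
  if (!is.null(b) && nrow(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1]; j <- b[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  # colours as integers; signature strings kept for canonical labels
  # radix sorts: byte order, locale-independent, so labels are reproducible
  sig <- el
  color <- match(sig, sort(unique(sig), method = "radix"))
  # each round's colour includes the previous one, so the partition can only
  # refine; stable once the class count stops growing
  repeat {
    new_sig <- vapply(seq_len(n), function(i) {
      nb <- sort(color[adj[[i]]])
      paste0(color[i], "|", paste(nb, collapse = ","))
    }, character(1))
    new_color <- match(new_sig, sort(unique(new_sig), method = "radix"))
    if (length(unique(new_color)) == length(unique(color))) break
    color <- new_color
    sig <- new_sig
  }
  # canonical label per class: element + full refinement signature; classes
  # ordered by label so the output is permutation-invariant
  labels <- vapply(split(seq_len(n), color), function(ix) {
    paste0(el[ix[1]], ":", substr(signature_hash(sig[ix[1]]), 1, 8))
  }, character(1))
  full_sig <- vapply(split(seq_len(n), color), function(ix) sig[ix[1]], character(1))
  ord <- order(vapply(split(seq_len(n), color), function(ix) el[ix[1]], character(1)),
               full_sig, method = "radix")
  classes <- unname(split(seq_len(n), color)[ord])
  labels <- unname(labels[ord])
  # disambiguate identical short labels deterministically
  labels <- make.unique(labels, sep = "_")
  membership <- integer(n)
  for (k in seq_along(classes)) membership[classes[[k]]] <- k
  structure(list(classes = classes, class_labels = labels,
                 membership = membership),
            class = "cage_partition")
}

# stable short hash of a signature string (sum of char codes in two bases);
# only used to shorten labels, uniqueness is restored via make.unique
signature_hash <- function(s) {
  v <- utf8ToInt(s)
  sprintf("%08x", (sum(v * seq_along(v)) %% 0xfffffd) * 65537L %% 0xffffffff)
}

#' @export
print.cage_partition <- function(x, ...) {
  cat(sprintf("<cage_partition> %d atoms in %d equivalence classes\n",
              length(x$membership), length(x$classes)))
  invisible(x)
}

#' Number of equivalence classes in a partition
#' @param partition a `cage_partition`.
#' @return integer class count.
#' @export
n_classes <- function(partition) length(partition$classes)

#' Average partial charges within symmetry classes
#'
#' Replaces every atom's charge by the arithmetic mean over its equivalence
#' class, as done when assigning a common force-field charge to symmetry
#' equivalent atoms. The total charge is conserved exactly (the mean is a
#' projection; sums agree to machine precision).
#'
#' @param charges a `charge_set` (see [charge_set()]) or bare numeric vector.
#' @param partition a `cage_partition` over the same atoms.
#' @return A `charge_set` with averaged charges and `averaged = TRUE`.
#' @export
average_charges <- function(charges, partition) {
  cs <- as_charge_set(charges)
  q <- cs$charges
  if (length(q) != length(partition$membership))
    data_error(sprintf("charge count (%d) does not match partition atom count (%d)",
                       length(q), length(partition$membership)))
  means <- tapply(q, partition$membership, mean)
  out <- as.numeric(means[as.character(partition$membership)])
  charge_set(out, model = cs$model, averaged = TRUE)
}

#' Partial-charge set
#'
#' @param charges numeric per-atom charges (elementary-charge units).
#' @param model charge-model label, e.g. `"ESP"`, `"RESP"`, `"MUL"`, `"NBO"`.
#' @param averaged has within-class averaging been applied?
#' @return A `charge_set` object.
#' @export
charge_set <- function(charges, model = "other", averaged = FALSE) {
  charges <- as.numeric(charges)
  if (!all(is.finite(charges))) data_error("charges must be finite")
  structure(list(charges = charges, model = as.character(model)[1],
                 averaged = isTRUE(averaged)),
            class = "charge_set")
}

as_charge_set <- function(x) {
  if (inherits(x, "charge_set")) x else charge_set(x)
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set> %s%s, %d atoms, total charge %+0.4f\n", x$model,
              if (x$averaged) " (averaged)" else "", length(x$charges),
              sum(x$charges)))
  invisible(x)
}

#' Compare several charge models over one partition
#'
#' For each equivalence class, reports the mean charge under every model and
#' the cross-model range; additionally reports each model's polarization
#' (min-max spread of its class means), the quantity under which Mulliken
#' charges typically stand out as most polarized.
#'
#' @param chargesets named list of `charge_set` objects (>= 2) over the same
#'   atoms; names default to the models' labels.
#' @param partition a `cage_partition`.
#' @return A list with `per_class` (data.frame: class, label, n_atoms, one
#'   mean column per model, cross_model_range) and `polarization` (named
#'   numeric spread per model).
#' @export
compare_charge_models <- function(chargesets, partition) {
  if (length(chargesets) < 2L)
    data_error("need at least two charge sets to compare")
  chargesets <- lapply(chargesets, as_charge_set)
  if (is.null(names(chargesets)) || any(!nzchar(names(chargesets))))
    names(chargesets) <- make.unique(vapply(chargesets, `[[`, character(1), "model"))
  n <- length(partition$membership)
  lens <- vapply(chargesets, function(cs) length(cs$charges), integer(1))
  if (any(lens != n))
    data_error("all charge sets must cover the same atoms as the partition")
  means <- vapply(chargesets, function(cs)
    as.numeric(tapply(cs$charges, partition$membership, mean)),
    numeric(n_classes(partition)))
  means <- matrix(means, nrow = n_classes(partition),
                  dimnames = list(NULL, names(chargesets)))
  per_class <- data.frame(
    class = seq_len(n_classes(partition)),
    label = partition$class_labels,
    n_atoms = lengths(partition$classes))
  per_class <- cbind(per_class, as.data.frame(means))
  per_class$cross_model_range <- apply(means, 1, function(v) max(v) - min(v))
  polarization <- apply(means, 2, function(v) max(v) - min(v))
  list(per_class = per_class, polarization = polarization)
}

#' Read a charge table from CSV
#'
#' Expected columns: `atom_index`, `element`, then one column per charge
#' model (e.g. `esp`, `resp`, `mul`, `nbo`).
#'
#' @param path CSV path.
#' @return Named list of `charge_set` objects, one per model column, ordered
#'   by `atom_index`.
#' @export
read_charge_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("atom_index", "element")
  if (!all(need %in% names(df)))
    parse_error("charge CSV must have atom_index and element columns")
  df <- df[order(df$atom_index), , drop = FALSE]
  models <- setdiff(names(df), need)
  if (!length(models)) parse_error("charge CSV contains no charge-model columns")
  out <- lapply(models, function(m) {
    q <- suppressWarnings(as.numeric(df[[m]]))
    if (anyNA(q)) parse_error(sprintf("non-numeric charges in column '%s'", m))
    charge_set(q, model = toupper(m))
  })
  names(out) <- toupper(models)
  attr(out, "elements") <- as.character(df$element)
  out
}

#' Write charge sets to CSV
#'
#' @param chargesets named list of `charge_set` objects over the same atoms.
#' @param elements per-atom element symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charge_csv <- function(chargesets, elements, path) {
  chargesets <- lapply(chargesets, as_charge_set)
  df <- data.frame(atom_index = seq_along(elements), element = elements)
  for (nm in names(chargesets)) df[[tolower(nm)]] <- chargesets[[nm]]$charges
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substitute charges into a mol2 template
#'
#' Replaces the charge column (9th field of `@<TRIPOS>ATOM` records) of a
#' mol2 file, leaving everything else bit-exact, as needed when feeding
#' symmetry-averaged charges back into a force-field topology.
#'
#' @param template_path input mol2 path.
#' @param charges numeric vector or `charge_set`, one value per ATOM record.
#' @param out_path output path.
#' @return `out_path`, invisibly.
#' @export
substitute_mol2_charges <- function(template_path, charges, out_path) {
  q <- as_charge_set(charges)$charges
  lines <- readLines(template_path, warn = FALSE)
  sec <- grep("^@<TRIPOS>", lines)
  a0 <- grep("^@<TRIPOS>ATOM", lines)
  if (length(a0) != 1L) parse_error("mol2 template must contain one @<TRIPOS>ATOM section")
  nxt <- sec[sec > a0]
  aend <- if (length(nxt)) min(nxt) - 1L else length(lines)
  rows <- (a0 + 1L):aend
  rows <- rows[nzchar(trimws(lines[rows]))]
  if (length(rows) != length(q))
    data_error(sprintf("mol2 has %d ATOM records but %d charges supplied",
                       length(rows), length(q)))
  for (k in seq_along(rows)) {
    ln <- lines[rows[k]]
    m <- gregexpr("[^[:space:]]+", ln)[[1]]
    if (length(m) < 9L) parse_error(sprintf("malformed mol2 ATOM line %d", rows[k]))
    start <- m[9]; stop_ <- m[9] + attr(m, "match.length")[9] - 1L
    lines[rows[k]] <- paste0(substr(ln, 1, start - 1L),
                             sprintf("%.6f", q[k]),
                             substr(ln, stop_ + 1L, nchar(ln)))
  }
  writeLines(lines, out_path)
  invisible(out_path)
}
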