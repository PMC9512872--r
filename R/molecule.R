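#' Construct a molecule
#'
#' The central container: element symbols, 3D coordinates, an explicit bond
#' table, and per-atom annotations (vdW radius, formal charge, water flag).
#' Atom indices are 1-based everywhere.
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param bonds Integer matrix with columns `i`, `j`, `order` (may have zero
#'   rows for a bond-less molecule such as a receptor point cloud).
#' @param name Molecule identifier.
#' @param formal_charge Integer vector (recycled).
#' @param is_water Logical vector (recycled).
#' @return An object of class `growlite_mol`.
#' @export
molecule <- function(elements, xyz, bonds = NULL, name = "mol",
                     formal_charge = 0L, is_water = FALSE) {
  elements <- as.character(elements)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- length(elements)
  stopifnot(nrow(xyz) == n)
  if (!all(is.finite(xyz))) stop("molecule '", name, "': non-finite coordinates")
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- matrix(integer(), ncol = 3)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3)
  }
  colnames(bonds) <- c("i", "j", "order")
  if (nrow(bonds)) {
    if (any(bonds[, 1:2] < 1 | bonds[, 1:2] > n))
      stop("molecule '", name, "': bond index out of range")
    if (any(bonds[, 1] == bonds[, 2]))
      stop("molecule '", name, "': self-bond")
  }
  structure(list(
    name = name,
    elements = elements,
    xyz = xyz,
    bonds = bonds,
    vdw = vdw_radius(elements),
    formal_charge = rep_len(as.integer(formal_charge), n),
    is_water = rep_len(as.logical(is_water), n)
  ), class = "growlite_mol")
}

#' @export
print.growlite_mol <- function(x, ...) {
  heavy <- sum(x$elements != "H")
  cat(sprintf("<molecule '%s': %d atoms (%d heavy), %d bonds>\n",
              x$name, length(x$elements), heavy, nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `growlite_mol`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) length(mol$elements)

heavy_idx <- function(mol) which(mol$elements != "H")

mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  if (!nrow(b)) return(integer())
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

bond_order_sum <- function(mol, i) {
  b <- mol$bonds
  if (!nrow(b)) return(0)
  sum(b[b[, 1] == i | b[, 2] == i, 3])
}

explicit_h <- function(mol, i) {
  nb <- mol_neighbors(mol, i)
  nb[mol$elements[nb] == "H"]
}

# implicit hydrogens from the default valence model
implicit_h <- function(mol, i) {
  max(0, std_valence(mol$elements[i]) + mol$formal_charge[i] -
        bond_order_sum(mol, i))
}

#' Number of hydrogens attached to an atom (explicit plus implicit)
#' @param mol A `growlite_mol`.
#' @param i Atom index.
#' @return Integer count.
#' @export
attached_hydrogens <- function(mol, i) {
  length(explicit_h(mol, i)) + implicit_h(mol, i)
}

# an atom has an open valence if a hydrogen (explicit or implicit) can be
# sacrificed for a new single bond
has_open_valence <- function(mol, i) {
  mol$elements[i] != "H" && attached_hydrogens(mol, i) >= 1
}

#' Extract an atom subset as a new molecule
#'
#' Bonds are remapped; bonds crossing the subset boundary are dropped.
#' @param mol A `growlite_mol`.
#' @param idx Atom indices to keep.
#' @param name Name for the new molecule.
#' @return A `growlite_mol`.
#' @export
subset_mol <- function(mol, idx, name = mol$name) {
  idx <- as.integer(idx)
  map <- integer(n_atoms(mol))
  map[idx] <- seq_along(idx)
  b <- mol$bonds
  if (nrow(b)) {
    keep <- b[, 1] %in% idx & b[, 2] %in% idx
    b <- b[keep, , drop = FALSE]
    if (nrow(b)) b[, 1:2] <- cbind(map[b[, 1]], map[b[, 2]])
  }
  molecule(mol$elements[idx], mol$xyz[idx, , drop = FALSE], b, name = name,
           formal_charge = mol$formal_charge[idx],
           is_water = mol$is_water[idx])
}

# heavy-atom igraph with element vertex attribute and order edge attribute
mol_graph <- function(mol, heavy_only = TRUE) {
  idx <- if (heavy_only) heavy_idx(mol) else seq_len(n_atoms(mol))
  m <- subset_mol(mol, idx)
  g <- igraph::make_empty_graph(n = n_atoms(m), directed = FALSE)
  if (nrow(m$bonds))
    g <- igraph::add_edges(g, t(m$bonds[, 1:2, drop = FALSE]),
                           order = m$bonds[, 3])
  igraph::set_vertex_attr(g, "element", value = m$elements)
}

n_components <- function(mol) {
  igraph::components(mol_graph(mol, heavy_only = FALSE))$no
}

#' Molecular weight including implicit hydrogens
#' @param mol A `growlite_mol`.
#' @return Weight in Dalton.
#' @export
molecular_weight <- function(mol) {
  w <- sum(atomic_mass(mol$elements))
  hv <- heavy_idx(mol)
  w + sum(vapply(hv, function(i) implicit_h(mol, i), numeric(1))) * 1.008
}

#' Binding site: receptor atoms plus crystallographic waters
#'
#' @param receptor A `growlite_mol` holding the receptor atoms (no waters).
#' @param waters A `growlite_mol` of water oxygen atoms (may be empty).
#' @param frame_id Identifier of the alignment frame this site lives in.
#' @return An object of class `binding_site`.
#' @export
binding_site <- function(receptor, waters = NULL, frame_id = "site") {
  if (is.null(waters))
    waters <- molecule(character(), matrix(numeric(), ncol = 3),
                       name = "waters")
  if (any(receptor$is_water))
    stop("receptor must not contain water-flagged atoms")
  if (n_atoms(waters) && !all(waters$is_water))
    stop("all water atoms must be flagged is_water")
  structure(list(receptor = receptor, waters = waters, frame_id = frame_id),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding site '%s': %d receptor atoms, %d waters>\n",
              x$frame_id, n_atoms(x$receptor), n_atoms(x$waters)))
  invisible(x)
}

#' Drop all waters from a binding site
#' @param site A `binding_site`.
#' @return The site with an empty water list.
#' @export
strip_waters <- function(site) {
  binding_site(site$receptor, NULL, site$frame_id)
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a zero vector")
  v / nv
}

# Rodrigues rotation matrix about unit axis by angle (radians)
rotation_matrix <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation carrying unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(ref - sum(ref * u) * u)
    return(rotation_matrix(ax, pi))
  }
  rotation_matrix(ax / s, atan2(s, c_))
}

transform_mol <- function(mol, R = diag(3), shift = c(0, 0, 0)) {
  mol$xyz <- sweep(mol$xyz %*% t(R), 2, -shift)
  mol
}
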