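#' Core anchor: a frozen core with one growth vector
#'
#' @param core The core `growlite_mol`, posed in the binding-site frame.
#' @param attachment_atom Index of the attachment atom in `core`.
#' @param growth_vector Unit direction of the open valence.
#' @param frozen Whether core coordinates are to be held during growing.
#' @return An object of class `core_anchor`.
#' @export
core_anchor <- function(core, attachment_atom, growth_vector, frozen = TRUE) {
  stopifnot(inherits(core, "growlite_mol"))
  attachment_atom <- as.integer(attachment_atom)
  if (attachment_atom < 1 || attachment_atom > n_atoms(core))
    stop("attachment_atom out of range")
  growth_vector <- unit(as.numeric(growth_vector))
  structure(list(core = core, attachment_atom = attachment_atom,
                 growth_vector = growth_vector, frozen = isTRUE(frozen)),
            class = "core_anchor")
}

#' @export
print.core_anchor <- function(x, ...) {
  cat(sprintf(
    "<core anchor: '%s' (%d atoms), attachment %d (%s), growth [%.2f %.2f %.2f]>\n",
    x$core$name, n_atoms(x$core), x$attachment_atom,
    x$core$elements[x$attachment_atom],
    x$growth_vector[1], x$growth_vector[2], x$growth_vector[3]))
  invisible(x)
}

#' Mark the growth point on a core ligand
#'
#' Turns an atom with an open valence into the attachment point. If the atom
#' carries explicit hydrogens, the lowest-index one is removed and the growth
#' vector points along the former bond; with implicit hydrogens only, an
#' idealized open-valence direction is used (opposite the mean of the existing
#' bond directions).
#'
#' @param mol The ligand `growlite_mol`.
#' @param attachment_atom Atom index at which to grow.
#' @return A [core_anchor()].
#' @export
mark_core <- function(mol, attachment_atom) {
  attachment_atom <- as.integer(attachment_atom)
  if (attachment_atom < 1 || attachment_atom > n_atoms(mol))
    stop("attachment_atom out of range")
  if (!has_open_valence(mol, attachment_atom))
    stop("atom ", attachment_atom, " (", mol$elements[attachment_atom],
         ") is saturated: no hydrogen or open valence to grow from")
  hs <- explicit_h(mol, attachment_atom)
  if (length(hs)) {
    h <- min(hs)
    g <- unit(mol$xyz[h, ] - mol$xyz[attachment_atom, ])
    keep <- setdiff(seq_len(n_atoms(mol)), h)
    core <- subset_mol(mol, keep)
    new_idx <- match(attachment_atom, keep)
    return(core_anchor(core, new_idx, g))
  }
  # idealized direction from the implicit open valence
  g <- open_valence_direction(mol, attachment_atom)
  core_anchor(mol, attachment_atom, g)
}

# direction of an idealized open valence. A terminal atom (one neighbor)
# gets a tetrahedral direction 109.47 deg off its bond, azimuth fixed by a
# deterministic perpendicular; otherwise the direction opposes the sum of
# the unit bond vectors. An unbonded atom grows along +x by convention.
open_valence_direction <- function(mol, i) {
  nb <- mol_neighbors(mol, i)
  if (!length(nb)) return(c(1, 0, 0))
  vs <- sweep(mol$xyz[nb, , drop = FALSE], 2, mol$xyz[i, ])
  vs <- vs / sqrt(rowSums(vs^2))
  if (length(nb) == 1) {
    u <- vs[1, ]
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- unit(ref - sum(ref * u) * u)
    th <- 109.47 * pi / 180
    return(unit(cos(th) * u + sin(th) * p))
  }
  s <- -colSums(vs)
  if (sqrt(sum(s^2)) < 1e-6) {
    # symmetric neighbor shell (e.g. trigonal planar): grow normal to it
    if (length(nb) >= 2) {
      nrm <- c(vs[1, 2] * vs[2, 3] - vs[1, 3] * vs[2, 2],
               vs[1, 3] * vs[2, 1] - vs[1, 1] * vs[2, 3],
               vs[1, 1] * vs[2, 2] - vs[1, 2] * vs[2, 1])
      if (sqrt(sum(nrm^2)) > 1e-6) return(unit(nrm))
    }
    return(c(1, 0, 0))
  }
  unit(s)
}
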