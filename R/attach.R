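#' Grown pose
#'
#' A core-plus-fragment ligand with provenance and (after scoring) the score
#' breakdown. Core atoms come first in the ligand and keep the input core
#' coordinates exactly until optimization.
#'
#' @param ligand Combined `growlite_mol`.
#' @param fragment_atom_indices Indices of the fragment atoms in `ligand`.
#' @param fragment_id Library identifier of the fragment.
#' @param frame_id Ensemble member the pose was generated in.
#' @param score Score breakdown list (`filled`, `contacts`, `clash`,
#'   `combined`) or `NULL` before scoring.
#' @return An object of class `growlite_pose`.
#' @export
pose <- function(ligand, fragment_atom_indices, fragment_id = ligand$name,
                 frame_id = NA_character_, score = NULL) {
  structure(list(ligand = ligand,
                 fragment_atom_indices = as.integer(fragment_atom_indices),
                 fragment_id = fragment_id, frame_id = frame_id,
                 score = score),
            class = "growlite_pose")
}

#' @export
print.growlite_pose <- function(x, ...) {
  sc <- if (is.null(x$score)) "unscored" else
    sprintf("combined %.2f (filled %.2f, contacts %d, clash %.2f)",
            x$score$combined, x$score$filled, x$score$contacts, x$score$clash)
  cat(sprintf("<pose: fragment '%s', %d ligand atoms, %s>\n",
              x$fragment_id, n_atoms(x$ligand), sc))
  invisible(x)
}

# fragment atoms of a pose as a molecule (bonds among fragment atoms kept)
pose_fragment <- function(p) {
  subset_mol(p$ligand, p$fragment_atom_indices, name = p$fragment_id)
}

# ring-membership flags for bonds via a fundamental cycle basis
ring_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(logical())
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  g <- igraph::add_edges(g, t(b[, 1:2, drop = FALSE]))
  vapply(seq_len(nrow(b)), function(k) {
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = b[k, 1], to = b[k, 2])
    is.finite(d[1, 1])
  }, logical(1))
}

# internal rotatable bonds: acyclic single bonds between heavy atoms, each
# endpoint bonded to something else as well
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(matrix(integer(), ncol = 2))
  rb <- ring_bonds(mol)
  keep <- b[, 3] == 1 & !rb &
    mol$elements[b[, 1]] != "H" & mol$elements[b[, 2]] != "H"
  deg <- vapply(seq_len(n_atoms(mol)), function(i)
    length(mol_neighbors(mol, i)), integer(1))
  keep <- keep & deg[b[, 1]] >= 2 & deg[b[, 2]] >= 2
  b[keep, 1:2, drop = FALSE]
}

# rotate the v-side of bond (u, v) about the u->v axis
rotate_about_bond <- function(mol, u, v, angle) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  k <- which((mol$bonds[, 1] == u & mol$bonds[, 2] == v) |
               (mol$bonds[, 1] == v & mol$bonds[, 2] == u))
  g2 <- igraph::delete_edges(g, k[1])
  side <- which(igraph::components(g2)$membership ==
                  igraph::components(g2)$membership[v])
  axis <- mol$xyz[v, ] - mol$xyz[u, ]
  R <- rotation_matrix(axis, angle)
  pivot <- mol$xyz[u, ]
  mol$xyz[side, ] <- sweep(sweep(mol$xyz[side, , drop = FALSE], 2, pivot) %*%
                             t(R), 2, -pivot)
  mol
}

#' Enumerate conformers of a library fragment
#'
#' Library-build-time torsion enumeration: every internal rotatable bond is
#' sampled at `config$internal_torsion_step`, capped at
#' `config$max_conformers` conformers.
#'
#' @param fragment A `growlite_mol`.
#' @param config A [growlite_config()].
#' @return A list of coordinate matrices (the first is the input geometry).
#' @export
fragment_conformers <- function(fragment, config = growlite_config()) {
  config <- as_config(config)
  rb <- rotatable_bonds(fragment)
  confs <- list(fragment$xyz)
  if (nrow(rb)) {
    angles <- seq(0, 359, by = config$internal_torsion_step)[-1] * pi / 180
    for (k in seq_len(nrow(rb))) {
      new_confs <- list()
      for (cf in confs) {
        m <- fragment; m$xyz <- cf
        for (a in angles)
          new_confs[[length(new_confs) + 1L]] <-
            rotate_about_bond(m, rb[k, 1], rb[k, 2], a)$xyz
      }
      confs <- c(confs, new_confs)
      if (length(confs) >= config$max_conformers) {
        confs <- confs[seq_len(config$max_conformers)]
        break
      }
    }
  }
  confs
}

# fragment attachment preparation: pick the attachment atom (lowest-index open
# valence unless configured), drop its lowest-index explicit H, and return the
# local open-valence direction
prepare_fragment <- function(fragment, config) {
  att <- config$fragment_attachment
  if (is.na(att)) {
    open <- which(vapply(seq_len(n_atoms(fragment)), function(i)
      has_open_valence(fragment, i), logical(1)))
    if (!length(open))
      stop("fragment '", fragment$name, "' has no open valence to attach")
    att <- open[1]
  } else if (!has_open_valence(fragment, att)) {
    stop("configured fragment attachment atom ", att, " has no open valence")
  }
  anc <- mark_core(fragment, att)
  list(frag = anc$core, attach = anc$attachment_atom, u = anc$growth_vector)
}

# rigidly place a prepared fragment on the anchor and spin it by `torsion`
# about the new bond
place_fragment <- function(anchor, prep, torsion) {
  core <- anchor$core
  g <- anchor$growth_vector
  a_pos <- core$xyz[anchor$attachment_atom, ]
  blen <- covalent_radius(core$elements[anchor$attachment_atom]) +
    covalent_radius(prep$frag$elements[prep$attach])
  bond_pos <- a_pos + blen * g
  R0 <- rotation_between(prep$u, -g)
  xyz <- sweep(prep$frag$xyz, 2, prep$frag$xyz[prep$attach, ]) %*% t(R0)
  Rt <- rotation_matrix(g, torsion)
  xyz <- xyz %*% t(Rt)
  sweep(xyz, 2, -bond_pos)
}

# combine core and placed fragment into one ligand molecule
assemble_ligand <- function(anchor, prep, frag_xyz, fragment_id) {
  core <- anchor$core
  nc <- n_atoms(core)
  nf <- n_atoms(prep$frag)
  bonds <- rbind(
    core$bonds,
    if (nrow(prep$frag$bonds))
      cbind(prep$frag$bonds[, 1] + nc, prep$frag$bonds[, 2] + nc,
            prep$frag$bonds[, 3]),
    c(anchor$attachment_atom, prep$attach + nc, 1L)
  )
  lig <- molecule(c(core$elements, prep$frag$elements),
                  rbind(core$xyz, frag_xyz), bonds,
                  name = paste0(core$name, "+", fragment_id),
                  formal_charge = c(core$formal_charge,
                                    prep$frag$formal_charge))
  pose(lig, nc + seq_len(nf), fragment_id = fragment_id)
}

# symmetry-aware RMSD between two conformations of the same atom set:
# greedy nearest matching within each element class
matched_rmsd <- function(el, xyz_a, xyz_b) {
  total <- 0
  n <- 0L
  for (e in unique(el)) {
    ia <- which(el == e)
    d2 <- outer(seq_along(ia), seq_along(ia), function(p, q)
      rowSums((xyz_a[ia[p], , drop = FALSE] - xyz_b[ia[q], , drop = FALSE])^2))
    d2 <- matrix(d2, length(ia), length(ia))
    while (length(ia) && any(is.finite(d2))) {
      k <- arrayInd(which.min(d2), dim(d2))
      total <- total + d2[k[1], k[2]]
      n <- n + 1L
      d2[k[1], ] <- Inf
      d2[, k[2]] <- Inf
      if (all(!is.finite(d2))) break
    }
  }
  sqrt(total / n)
}

#' Enumerate unscored attachment poses of a fragment on a core
#'
#' A new single bond (length from covalent radii) joins the anchor's
#' attachment atom to the fragment's lowest-index open valence; the torsion
#' about the new bond is sampled at `config$torsion_step`. Fragments carrying
#' a single conformer additionally get ring-free internal torsions sampled at
#' `config$internal_torsion_step`; multi-conformer fragments (a `conformers`
#' attribute holding coordinate matrices) are enumerated per conformer.
#' Near-duplicate poses (symmetry-aware fragment RMSD below
#' `config$dedup_rmsd`) are merged and the total is capped at
#' `config$max_poses`.
#'
#' @param anchor A [core_anchor()].
#' @param fragment A `growlite_mol`.
#' @param config A [growlite_config()].
#' @return List of unscored [pose()] objects.
#' @export
enumerate_attachments <- function(anchor, fragment,
                                  config = growlite_config()) {
  config <- as_config(config)
  confs <- attr(fragment, "conformers")
  internal <- is.null(confs)
  if (internal) confs <- list(fragment$xyz)
  torsions <- seq(0, 359, by = config$torsion_step) * pi / 180
  poses <- list()
  frag_geoms <- list()
  truncated <- FALSE
  for (cf in confs) {
    m <- fragment
    m$xyz <- cf
    variants <- if (internal) fragment_conformers(m, config) else list(cf)
    for (vxyz in variants) {
      mv <- fragment; mv$xyz <- vxyz
      prep <- prepare_fragment(mv, config)
      single_atom <- n_atoms(prep$frag) == 1
      tors <- if (single_atom) 0 else torsions
      for (th in tors) {
        fxyz <- place_fragment(anchor, prep, th)
        dup <- FALSE
        for (gk in frag_geoms) {
          if (matched_rmsd(prep$frag$elements, fxyz, gk) <
              config$dedup_rmsd) { dup <- TRUE; break }
        }
        if (dup) next
        frag_geoms[[length(frag_geoms) + 1L]] <- fxyz
        poses[[length(poses) + 1L]] <-
          assemble_ligand(anchor, prep, fxyz, fragment$name)
        if (length(poses) >= config$max_poses) { truncated <- TRUE; break }
      }
      if (truncated) break
    }
    if (truncated) break
  }
  if (truncated)
    warning("pose enumeration for '", fragment$name, "' truncated at ",
            config$max_poses, " poses")
  poses
}
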