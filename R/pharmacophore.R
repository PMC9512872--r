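#' Typed pharmacophore search point
#'
#' @param type `"donor"`, `"acceptor"` or `"hydrophobic"`.
#' @param position xyz in Angstrom.
#' @param tolerance Tolerance radius, Angstrom (> 0).
#' @param source Provenance: `"ligand"`, `"water"` or `"user"`.
#' @return An object of class `search_point`.
#' @export
search_point <- function(type, position, tolerance = 2.0, source = "user") {
  type <- match.arg(type, c("donor", "acceptor", "hydrophobic"))
  stopifnot(tolerance > 0, length(position) == 3, all(is.finite(position)))
  structure(list(type = type, position = as.numeric(position),
                 tolerance = tolerance, source = source),
            class = "search_point")
}

#' @export
print.search_point <- function(x, ...) {
  cat(sprintf("<%s point at [%.2f %.2f %.2f], tol %.1f A (%s)>\n",
              x$type, x$position[1], x$position[2], x$position[3],
              x$tolerance, x$source))
  invisible(x)
}

#' Read search points from JSON
#'
#' Format: an array of objects `{"type": ..., "x": ..., "y": ..., "z": ...,
#' "tolerance": ...}` (tolerance optional, default 2.0).
#'
#' @param path JSON file path.
#' @return List of [search_point()].
#' @export
read_search_points <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) search_point(
    r$type, c(r$x, r$y, r$z),
    tolerance = if (is.null(r$tolerance)) 2.0 else r$tolerance,
    source = if (is.null(r$source)) "user" else r$source))
}

#' Write search points to JSON
#' @param points List of [search_point()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_search_points <- function(points, path) {
  recs <- lapply(points, function(p) list(
    type = p$type, x = p$position[1], y = p$position[2], z = p$position[3],
    tolerance = p$tolerance, source = p$source))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ring atom sets from a fundamental cycle basis of the heavy-atom graph
mol_rings <- function(mol) {
  hv <- heavy_idx(mol)
  m <- subset_mol(mol, hv)
  b <- m$bonds
  if (!nrow(b)) return(list())
  g <- igraph::make_empty_graph(n = n_atoms(m), directed = FALSE)
  g <- igraph::add_edges(g, t(b[, 1:2, drop = FALSE]))
  rb <- which(ring_bonds(m))
  rings <- list()
  for (k in rb) {
    g2 <- igraph::delete_edges(
      g, which((b[, 1] == b[k, 1] & b[, 2] == b[k, 2]) |
                 (b[, 1] == b[k, 2] & b[, 2] == b[k, 1]))[1])
    p <- igraph::shortest_paths(g2, from = b[k, 1], to = b[k, 2])$vpath[[1]]
    ring <- sort(as.integer(p))
    if (length(ring) >= 3 &&
        !any(vapply(rings, function(r) identical(r, ring), logical(1))))
      rings[[length(rings) + 1L]] <- ring
  }
  lapply(rings, function(r) hv[r])
}

# feature perception on a ligand. Donors: N/O with >=1 hydrogen. Acceptors:
# O with free valence capacity, or N with no hydrogens and an available lone
# pair. Hydrophobic atoms: C/S with only C/S/H neighbors.
ligand_features <- function(mol) {
  hv <- heavy_idx(mol)
  el <- mol$elements
  donors <- integer(); acceptors <- integer(); hydrophobic <- integer()
  for (i in hv) {
    if (el[i] %in% c("N", "O")) {
      nh <- attached_hydrogens(mol, i)
      if (nh >= 1) donors <- c(donors, i)
      occ <- bond_order_sum(mol, i) + implicit_h(mol, i)
      if (el[i] == "O" && occ <= 2) acceptors <- c(acceptors, i)
      if (el[i] == "N" && nh == 0 && occ <= 3) acceptors <- c(acceptors, i)
    } else if (el[i] %in% c("C", "S")) {
      nb <- mol_neighbors(mol, i)
      if (!length(nb) || all(el[nb] %in% c("C", "S", "H")))
        hydrophobic <- c(hydrophobic, i)
    }
  }
  rings <- mol_rings(mol)
  hp_rings <- Filter(function(r) {
    if (!all(el[r] %in% c("C", "S"))) return(FALSE)
    subst <- setdiff(unique(unlist(lapply(r, mol_neighbors, mol = mol))), r)
    !any(el[subst] %in% c("N", "O"))
  }, rings)
  # terminal hydrophobic groups: hydrophobic atoms with <= 1 heavy neighbor
  terminal <- Filter(function(i) {
    nb <- mol_neighbors(mol, i)
    sum(el[nb] != "H") <= 1
  }, hydrophobic)
  list(donors = donors, acceptors = acceptors, hydrophobic = hydrophobic,
       hp_rings = hp_rings, terminal = as.integer(terminal))
}

angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cc <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(1, pmax(-1, cc))) * 180 / pi
}

#' Detect protein--ligand interactions as search points
#'
#' Donor points sit on ligand N/O atoms bearing hydrogens whose heavy-atom
#' distance to a receptor N/O lies in `config$hbond_range` with a D-H...A
#' angle of at least `config$hbond_angle_min` (the angle test applies when an
#' explicit hydrogen is present). Acceptor points mirror this against
#' receptor N/O donors. Hydrophobic points sit at centroids of fully
#' hydrophobic rings and at terminal hydrophobic atoms that have a receptor
#' C/S within `config$hydrophobic_range`; `hydrophobic_mode = "permissive"`
#' instead emits a point for every qualifying hydrophobic atom. All points
#' are placed on the ligand side of the interaction.
#'
#' @param site A [binding_site()].
#' @param ligand A `growlite_mol` posed in the site frame.
#' @param config A [growlite_config()].
#' @return List of [search_point()] with `source = "ligand"`.
#' @export
detect_interactions <- function(site, ligand, config = growlite_config()) {
  config <- as_config(config)
  rec <- site$receptor
  el_r <- rec$elements
  rec_no <- which(el_r %in% c("N", "O"))
  rec_cs <- which(el_r %in% c("C", "S"))
  feats <- ligand_features(ligand)
  pts <- list()
  lo <- config$hbond_range[1]; hi <- config$hbond_range[2]
  add <- function(type, pos) {
    pts[[length(pts) + 1L]] <<- search_point(type, pos, config$sp_tolerance,
                                             source = "ligand")
  }
  for (i in feats$donors) {
    if (!length(rec_no)) break
    d <- sqrt(colSums((t(rec$xyz[rec_no, , drop = FALSE]) -
                         ligand$xyz[i, ])^2))
    cand <- rec_no[d >= lo & d <= hi]
    hs <- explicit_h(ligand, i)
    ok <- FALSE
    for (a in cand) {
      if (!length(hs)) { ok <- TRUE; break }
      ang <- vapply(hs, function(h)
        angle_deg(ligand$xyz[i, ], ligand$xyz[h, ], rec$xyz[a, ]), numeric(1))
      if (any(ang >= config$hbond_angle_min)) { ok <- TRUE; break }
    }
    if (ok) add("donor", ligand$xyz[i, ])
  }
  for (i in feats$acceptors) {
    if (!length(rec_no)) break
    d <- sqrt(colSums((t(rec$xyz[rec_no, , drop = FALSE]) -
                         ligand$xyz[i, ])^2))
    if (any(d >= lo & d <= hi)) add("acceptor", ligand$xyz[i, ])
  }
  hlo <- config$hydrophobic_range[1]; hhi <- config$hydrophobic_range[2]
  near_cs <- function(pos) {
    if (!length(rec_cs)) return(FALSE)
    d <- sqrt(colSums((t(rec$xyz[rec_cs, , drop = FALSE]) - pos)^2))
    any(d >= hlo & d <= hhi)
  }
  if (config$hydrophobic_mode == "strict") {
    for (r in feats$hp_rings) {
      cen <- colMeans(ligand$xyz[r, , drop = FALSE])
      if (near_cs(cen)) add("hydrophobic", cen)
    }
    for (i in feats$terminal)
      if (near_cs(ligand$xyz[i, ])) add("hydrophobic", ligand$xyz[i, ])
  } else {
    for (i in feats$hydrophobic)
      if (near_cs(ligand$xyz[i, ])) add("hydrophobic", ligand$xyz[i, ])
  }
  pts
}

# greedy one-to-one same-type matching of points within `radius`; returns the
# index pairs (a, b) matched
match_point_sets <- function(points_a, points_b, radius = 2.0) {
  pairs <- list()
  if (!length(points_a) || !length(points_b))
    return(matrix(integer(), ncol = 2))
  cand <- do.call(rbind, lapply(seq_along(points_a), function(i) {
    do.call(rbind, lapply(seq_along(points_b), function(j) {
      if (points_a[[i]]$type != points_b[[j]]$type) return(NULL)
      d <- sqrt(sum((points_a[[i]]$position - points_b[[j]]$position)^2))
      if (d > radius) return(NULL)
      c(i, j, d)
    }))
  }))
  if (is.null(cand) || !nrow(cand)) return(matrix(integer(), ncol = 2))
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used_a <- logical(length(points_a)); used_b <- logical(length(points_b))
  out <- matrix(integer(), ncol = 2)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      out <- rbind(out, c(i, j))
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  out
}

#' Stable search points between two structures
#'
#' A point of `points_a` is stable if a same-type point of `points_b` lies
#' within `radius` (greedy nearest one-to-one matching).
#'
#' @param points_a,points_b Lists of [search_point()] in one frame.
#' @param radius Match radius, Angstrom.
#' @return The stable subset of `points_a`.
#' @export
stable_points <- function(points_a, points_b, radius = 2.0) {
  m <- match_point_sets(points_a, points_b, radius)
  points_a[m[, 1]]
}

#' Match a pose against search-point constraints
#'
#' Passes iff every point finds a compatible ligand feature (donor point ->
#' donor atom, acceptor -> acceptor atom, hydrophobic -> hydrophobic atom or
#' fully hydrophobic ring centroid) within its tolerance radius. A ligand
#' feature may satisfy several points.
#'
#' @param p A [pose()] or a bare `growlite_mol`.
#' @param points List of [search_point()].
#' @param config A [growlite_config()].
#' @return List with `pass` (logical) and `assignment` (data frame: point
#'   index, type, distance to the matched feature).
#' @export
match_pose <- function(p, points, config = growlite_config()) {
  config <- as_config(config)
  lig <- if (inherits(p, "growlite_pose")) p$ligand else p
  feats <- ligand_features(lig)
  pos_of <- function(type) {
    switch(type,
      donor = lig$xyz[feats$donors, , drop = FALSE],
      acceptor = lig$xyz[feats$acceptors, , drop = FALSE],
      hydrophobic = rbind(
        lig$xyz[feats$hydrophobic, , drop = FALSE],
        if (length(feats$hp_rings))
          do.call(rbind, lapply(feats$hp_rings, function(r)
            colMeans(lig$xyz[r, , drop = FALSE])))))
  }
  rows <- lapply(seq_along(points), function(k) {
    pt <- points[[k]]
    cand <- pos_of(pt$type)
    if (is.null(cand) || !nrow(cand))
      return(data.frame(point = k, type = pt$type, distance = NA_real_,
                        ok = FALSE))
    d <- sqrt(colSums((t(cand) - pt$position)^2))
    data.frame(point = k, type = pt$type, distance = min(d),
               ok = min(d) <= pt$tolerance)
  })
  assignment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(point = integer(), type = character(), distance = numeric(),
               ok = logical())
  list(pass = all(assignment$ok), assignment = assignment)
}

#' Search points from waters replaced by the ligand
#'
#' A water is replaced when its maximum vdW overlap with a ligand heavy atom
#' exceeds `config$overlap_threshold` percent. Each replaced water proposes a
#' donor, an acceptor and a dummy hydrophobic point at its oxygen; only
#' proposals confirmed within 2 A by a same-type point from
#' [detect_interactions()] on the ligand are kept. The indices of replaced
#' waters are attached as the `replaced` attribute so callers can strip them
#' from the site before growing.
#'
#' @param site A [binding_site()] that still holds its waters.
#' @param ligand_to_grow The ligand posed in the site frame.
#' @param config A [growlite_config()].
#' @return List of [search_point()] with `source = "water"`.
#' @export
water_replacement_query <- function(site, ligand_to_grow,
                                    config = growlite_config()) {
  config <- as_config(config)
  wat <- site$waters
  if (!n_atoms(wat)) {
    warning("binding site has no waters; empty water-replacement query")
    return(list())
  }
  lig <- ligand_to_grow
  li <- heavy_idx(lig)
  replaced <- integer()
  for (w in seq_len(n_atoms(wat))) {
    d <- sqrt(colSums((t(lig$xyz[li, , drop = FALSE]) - wat$xyz[w, ])^2))
    ov <- vdw_overlap(d, lig$vdw[li], wat$vdw[w],
                      metric = config$overlap_metric)
    if (max(ov) > config$overlap_threshold) replaced <- c(replaced, w)
  }
  if (!length(replaced)) return(structure(list(), replaced = integer()))
  proposals <- unlist(lapply(replaced, function(w) {
    lapply(c("donor", "acceptor", "hydrophobic"), function(tp)
      search_point(tp, wat$xyz[w, ], config$sp_tolerance, source = "water"))
  }), recursive = FALSE)
  lig_pts <- detect_interactions(site, lig, config)
  keep <- stable_points(proposals, lig_pts, radius = 2.0)
  structure(keep, replaced = replaced)
}
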