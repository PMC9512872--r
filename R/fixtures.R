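# Deterministic geometric fixture generator. Pockets are atom shells, not
# protein folds: their purpose is oracle-checkable geometry at desk scale.

#' Fixture specification
#'
#' @param seed Integer seed fixing every generated coordinate.
#' @param pocket_kind `"spherical"`, `"two-lobe"` or `"channel"`.
#' @param pocket_radius Main cavity radius, Angstrom.
#' @param spacing Approximate wall-atom spacing, Angstrom.
#' @param lobe_radius,lobe_dist Sub-pocket lobe radius and center distance
#'   (two-lobe pockets).
#' @param lobe_dir Unit direction of the lobe center.
#' @param planted_fragment Chain notation for the planted substituent: one
#'   letter per heavy atom, chained with idealized tetrahedral geometry;
#'   one level of parentheses branches, e.g. `"CC(C)C"`.
#' @param noise_sigma Gaussian coordinate noise (A) on the reference
#'   fragment.
#' @param polar Optional list of `list(element=, dir=)` wall substitutions
#'   hosting hydrogen-bond fixtures.
#' @param waters Optional matrix of water oxygen positions.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, pocket_kind = "two-lobe",
                         pocket_radius = 4.5, spacing = 1.2,
                         lobe_radius = 3.0, lobe_dist = 3.5,
                         lobe_dir = c(1, 0, 0),
                         planted_fragment = "CC", noise_sigma = 0,
                         polar = list(), waters = NULL) {
  pocket_kind <- match.arg(pocket_kind, c("spherical", "two-lobe", "channel"))
  stopifnot(noise_sigma >= 0)
  structure(list(seed = as.integer(seed), pocket_kind = pocket_kind,
                 pocket_radius = pocket_radius, spacing = spacing,
                 lobe_radius = lobe_radius, lobe_dist = lobe_dist,
                 lobe_dir = unit(lobe_dir),
                 planted_fragment = planted_fragment,
                 noise_sigma = noise_sigma, polar = polar, waters = waters),
            class = "fixture_spec")
}

# quasi-uniform atom shell of radius R around `center`
sphere_shell <- function(center, R, spacing, element = "C") {
  n <- max(12L, round(4 * pi * R^2 / spacing^2))
  pts <- fibonacci_sphere(n) * R
  sweep(pts, 2, -center)
}

#' Build a synthetic binding site
#'
#' Wall atoms (carbon unless substituted through `spec$polar`) on a
#' quasi-uniform shell forming the requested cavity; two-lobe pockets open
#' the main shell into a sub-pocket lobe; optional waters are added at the
#' stated positions.
#'
#' @param spec A [fixture_spec()].
#' @return A [binding_site()].
#' @export
make_pocket <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$pocket_radius < 2) stop("pocket radius below 2 A")
  R <- spec$pocket_radius
  pts <- switch(spec$pocket_kind,
    spherical = sphere_shell(c(0, 0, 0), R, spec$spacing),
    "two-lobe" = {
      cenB <- spec$lobe_dir * spec$lobe_dist
      a <- sphere_shell(c(0, 0, 0), R, spec$spacing)
      b <- sphere_shell(cenB, spec$lobe_radius, spec$spacing)
      # wall atoms of one shell strictly inside the other are removed; the
      # 0.3 A margin keeps atoms near the intersection seam so the two
      # shells join without a gap ring
      a <- a[sqrt(colSums((t(a) - cenB)^2)) >= spec$lobe_radius - 0.3, ,
             drop = FALSE]
      b <- b[sqrt(rowSums(b^2)) >= R - 0.3, , drop = FALSE]
      rbind(a, b)
    },
    channel = {
      xs <- seq(-R, R, by = spec$spacing)
      do.call(rbind, lapply(xs, function(x) {
        k <- max(6L, round(2 * pi * R / spec$spacing))
        th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
        cbind(x, R * cos(th), R * sin(th))
      }))
    })
  el <- rep("C", nrow(pts))
  for (p in spec$polar) {
    pos <- unit(p$dir) * R
    d <- sqrt(colSums((t(pts) - pos)^2))
    el[which.min(d)] <- p$element
    pts[which.min(d), ] <- pos
  }
  receptor <- molecule(el, pts, name = sprintf("pocket_seed%d", spec$seed))
  waters <- if (!is.null(spec$waters)) {
    w <- matrix(spec$waters, ncol = 3)
    molecule(rep("O", nrow(w)), w, name = "waters", is_water = TRUE)
  } else NULL
  binding_site(receptor, waters, frame_id = receptor$name)
}

#' Build a fragment from chain notation
#'
#' One letter per heavy atom, joined in a trans zigzag with tetrahedral
#' angles and covalent-radii bond lengths; a single level of parentheses
#' attaches a one-atom branch to the preceding chain atom. Hydrogens are
#' implicit.
#'
#' @param notation E.g. `"CCO"` or `"CC(C)C"`.
#' @param name Molecule name (defaults to the notation).
#' @return A `growlite_mol`.
#' @export
build_chain_fragment <- function(notation, name = notation) {
  toks <- strsplit(notation, "")[[1]]
  alpha <- 35.264 * pi / 180                 # half of (180 - 109.47)
  up <- c(cos(alpha), 0, sin(alpha))
  dn <- c(cos(alpha), 0, -sin(alpha))
  elements <- character(); xyz <- NULL; bonds <- NULL
  prev <- 0L       # last chain atom index
  pprev <- 0L      # chain atom before it
  in_branch <- FALSE
  k <- 1
  while (k <= length(toks)) {
    tok <- toks[k]
    if (tok == "(") { in_branch <- TRUE; k <- k + 1; next }
    if (tok == ")") { in_branch <- FALSE; k <- k + 1; next }
    if (!tok %in% names(.vdw_table) || tok == "H")
      stop("unsupported atom '", tok, "' in chain notation")
    if (prev == 0L) {
      elements <- tok; xyz <- matrix(c(0, 0, 0), 1)
      prev <- 1L
    } else {
      host <- prev
      blen <- covalent_radius(elements[host]) + covalent_radius(tok)
      if (in_branch) {
        # third tetrahedral direction at the host atom
        nb <- c(bonds[bonds[, 1] == host, 2], bonds[bonds[, 2] == host, 1])
        us <- sweep(xyz[nb, , drop = FALSE], 2, xyz[host, ])
        us <- us / sqrt(rowSums(us^2))
        if (nrow(us) >= 2) {
          bis <- -unit(colSums(us[1:2, ]))
          nrm <- unit(c(us[1, 2] * us[2, 3] - us[1, 3] * us[2, 2],
                        us[1, 3] * us[2, 1] - us[1, 1] * us[2, 3],
                        us[1, 1] * us[2, 2] - us[1, 2] * us[2, 1]))
          dir <- bis * cos(54.735 * pi / 180) + nrm * sin(54.735 * pi / 180)
        } else {
          dir <- c(0, 1, 0)
        }
        pos <- xyz[host, ] + blen * dir
      } else {
        dir <- if (length(elements) %% 2 == 1) up else dn
        pos <- xyz[prev, ] + blen * dir
      }
      elements <- c(elements, tok)
      xyz <- rbind(xyz, pos)
      bonds <- rbind(bonds, c(host, length(elements), 1L))
      if (!in_branch) { pprev <- prev; prev <- length(elements) }
    }
    k <- k + 1
  }
  molecule(elements, xyz, bonds, name = name)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
}

#' Plant a cross-growing case with a known answer
#'
#' Builds a two-lobe cavity whose sub-pocket lies along a randomly chosen
#' attachment torsion of the planted fragment, so the planted pose is the
#' shape-score optimum and is recoverable by pose enumeration. The reference
#' ligand (core plus fragment, optional Gaussian noise on the fragment) is
#' held out of the growing inputs; the whole scene is rotated by a seeded
#' random rotation so no fixture shares an orientation.
#'
#' @param spec A [fixture_spec()]; `seed` drives the torsion, rotation and
#'   noise draws.
#' @return A `cross_grow_case` with extra fields `planted_pose` (noise-free)
#'   and `spec`.
#' @export
plant_case <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  frag <- build_chain_fragment(spec$planted_fragment)
  n_heavy <- length(heavy_idx(frag))
  # zigzag chains advance ~1.25 A per bond along their axis
  extent <- (n_heavy - 1) * 1.3 + 1.7
  if (extent > spec$lobe_dist + spec$lobe_radius - 1.7)
    stop("fragment larger than cavity")
  core <- molecule(c("C", "C"), rbind(c(-1.54, 0, 0), c(0, 0, 0)),
                   matrix(c(1L, 2L, 1L), 1), name = "core")
  anchor <- core_anchor(core, 2L, c(1, 0, 0))
  cfg <- growlite_config()
  prep <- prepare_fragment(frag, cfg)
  torsions <- seq(0, 330, by = cfg$torsion_step) * pi / 180
  theta <- sample(torsions, 1)
  fxyz <- place_fragment(anchor, prep, theta)
  planted <- assemble_ligand(anchor, prep, fxyz, frag$name)
  # sub-pocket along the planted fragment's heavy centroid
  hv <- heavy_idx(prep$frag)
  cen <- colMeans(fxyz[hv, , drop = FALSE])
  lobe_dir <- if (sqrt(sum(cen^2)) > 0.5) unit(cen) else c(1, 0, 0)
  spec$lobe_dir <- lobe_dir
  site <- make_pocket(spec)
  # one seeded rotation for the whole scene
  Rr <- random_rotation()
  rot <- function(m) m %*% t(Rr)
  site$receptor$xyz <- rot(site$receptor$xyz)
  if (n_atoms(site$waters)) site$waters$xyz <- rot(site$waters$xyz)
  core_r <- core; core_r$xyz <- rot(core$xyz)
  anchor_r <- core_anchor(core_r, 2L, as.numeric(Rr %*% c(1, 0, 0)))
  planted$ligand$xyz <- rot(planted$ligand$xyz)
  reference <- planted$ligand
  target_fragment <- subset_mol(reference, planted$fragment_atom_indices,
                                name = frag$name)
  if (spec$noise_sigma > 0) {
    noise <- matrix(stats::rnorm(3 * n_atoms(target_fragment),
                                 sd = spec$noise_sigma), ncol = 3)
    target_fragment$xyz <- target_fragment$xyz + noise
    reference$xyz[planted$fragment_atom_indices, ] <-
      reference$xyz[planted$fragment_atom_indices, ] + noise
  }
  structure(list(
    growing_site = site,
    core = anchor_r,
    target_fragment = target_fragment,
    reference_ligand = reference,
    case_id = sprintf("planted_%s_seed%d", spec$planted_fragment, spec$seed),
    planted_pose = planted,
    spec = spec), class = "cross_grow_case")
}

#' Generate a labelled enrichment library
#'
#' Actives are short linear fragments shaped to fit a planted sub-pocket;
#' decoys are drawn from a pool of bulkier branched fragments by greedy
#' Rule-of-Three property matching ([match_decoys()]), so they resemble the
#' actives in properties but not in shape.
#'
#' @param seed Integer seed.
#' @param n_actives,n_decoys Library composition.
#' @return List with `library` (named list of `growlite_mol`) and `labels`
#'   (logical vector, `TRUE` = active).
#' @export
make_enrichment_set <- function(seed = 1L, n_actives = 5L, n_decoys = 50L) {
  if (n_actives < 1) stop("need at least one active")
  set.seed(seed)
  active_shapes <- c("C", "CC", "CCC", "CO", "CN", "CCO")
  actives <- lapply(seq_len(n_actives), function(i) {
    nt <- sample(active_shapes, 1)
    build_chain_fragment(nt, name = sprintf("active_%02d", i))
  })
  stems <- c("CC(C)C", "CC(C)CC", "CC(O)CC", "CC(C)CN", "CCC(C)C",
             "CC(N)CC", "CC(C)CO", "CCC(O)C")
  pool <- lapply(seq_len(max(3L * n_decoys, 60L)), function(i) {
    nt <- sample(stems, 1)
    build_chain_fragment(nt, name = sprintf("decoy_%03d", i))
  })
  a_props <- do.call(rbind, lapply(actives, ro3_properties))
  p_props <- do.call(rbind, lapply(pool, ro3_properties))
  picks <- match_decoys(a_props, p_props,
                        per_active = ceiling(n_decoys / n_actives))
  decoys <- pool[picks[seq_len(n_decoys)]]
  lib <- c(actives, decoys)
  names(lib) <- vapply(lib, function(m) m$name, character(1))
  list(library = lib,
       labels = c(rep(TRUE, n_actives), rep(FALSE, n_decoys)))
}
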