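# Element tables. vdW radii are a fixed Bondi-style set so that overlap and
# ray-casting results are deterministic and testable; unknown elements fall
# back to the carbon radius with a warning.
.vdw_table <- c(
  H = 1.09, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98
)
.cov_table <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39
)
.mass_table <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904
)
# default valences used for implicit-hydrogen / open-valence bookkeeping
.valence_table <- c(
  H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Van der Waals radius of an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom. Unknown symbols fall back to
#'   the carbon radius (1.70 A) with a warning.
#' @export
vdw_radius <- function(element) {
  r <- unname(.vdw_table[element])
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using fallback vdW radius 1.70 A")
    r[is.na(r)] <- 1.70
  }
  r
}

covalent_radius <- function(element) {
  r <- unname(.cov_table[element])
  r[is.na(r)] <- 0.76
  r
}

atomic_mass <- function(element) {
  m <- unname(.mass_table[element])
  m[is.na(m)] <- 12.011
  m
}

std_valence <- function(element) {
  v <- unname(.valence_table[element])
  v[is.na(v)] <- 4
  v
}

#' Workflow configuration
#'
#' Central bag of tunable parameters for descriptor casting, pose enumeration,
#' scoring and constraint matching. All distances are in Angstrom, angles in
#' degrees.
#'
#' @param ... Named overrides of the defaults below.
#'
#' @details Defaults:
#' \describe{
#'   \item{n_rays}{128 — rays in the Fibonacci-sphere direction set.}
#'   \item{max_range}{10 — ray cap; also the pocket-presence radius.}
#'   \item{clash_tol}{0.75 — per-ray clash tolerance in the shape score; a
#'     deliberately permissive value so that pose generation tolerates the
#'     sometimes uncomfortable fit of a transferred ligand.}
#'   \item{w_clash}{3.0 — weight of the clash term in the combined score.}
#'   \item{w_contact}{0.3 — weight of the close-contact count.}
#'   \item{contact_range}{c(3.2, 4.0) — heavy-atom distance window counted as
#'     a close contact.}
#'   \item{torsion_step}{30 — sampling increment about the new bond.}
#'   \item{internal_torsion_step}{120 — sampling of ring-free fragment
#'     torsions when the fragment carries a single conformer.}
#'   \item{dedup_rmsd}{0.1 — symmetry-aware RMSD below which two enumerated
#'     poses are considered duplicates.}
#'   \item{max_poses}{600 — cap on enumerated poses per fragment.}
#'   \item{max_conformers}{25 — cap used by the library conformer builder.}
#'   \item{top_k}{1 — poses kept per fragment in the hit list.}
#'   \item{overlap_threshold}{60 — percent vdW overlap above which a water
#'     counts as replaced and a pose as hard-clashed.}
#'   \item{prep_clash_overlap}{60 — overlap used when pruning site molecules
#'     that collide with the input core during preparation.}
#'   \item{overlap_metric}{"linear" — linear penetration fraction;
#'     "volume" switches to the intersection-volume fraction.}
#'   \item{hbond_range}{c(2.5, 3.5) — donor/acceptor heavy-atom distance.}
#'   \item{hbond_angle_min}{120 — minimum D-H...A angle.}
#'   \item{hydrophobic_range}{c(3.5, 4.5) — centroid-to-receptor-C/S window.}
#'   \item{sp_tolerance}{2.0 — default search-point tolerance radius.}
#'   \item{hydrophobic_mode}{"strict" — fully hydrophobic rings and terminal
#'     groups only; "permissive" emits a point per hydrophobic atom.}
#'   \item{keep_het}{character() — HETATM residue names to retain in the
#'     receptor when reading PDB files.}
#'   \item{fragment_attachment}{NA — force a specific fragment attachment atom
#'     index; by default the lowest-index open valence is used.}
#'   \item{opt_max_step}{0.1 — per-atom displacement cap per optimizer
#'     iteration (the limited step length).}
#'   \item{opt_max_iter}{500 — optimizer iteration budget.}
#'   \item{opt_tol}{1e-4 — energy-change convergence threshold.}
#'   \item{opt_max_halvings}{10 — step halvings allowed on an energy rise.}
#' }
#' @return A named list of class `growlite_config`.
#' @export
growlite_config <- function(...) {
  cfg <- list(
    n_rays = 128L,
    max_range = 10,
    clash_tol = 0.75,
    w_clash = 3.0,
    w_contact = 0.3,
    contact_range = c(3.2, 4.0),
    torsion_step = 30,
    internal_torsion_step = 120,
    dedup_rmsd = 0.1,
    max_poses = 600L,
    max_conformers = 25L,
    top_k = 1L,
    overlap_threshold = 60,
    prep_clash_overlap = 60,
    overlap_metric = "linear",
    hbond_range = c(2.5, 3.5),
    hbond_angle_min = 120,
    hydrophobic_range = c(3.5, 4.5),
    sp_tolerance = 2.0,
    hydrophobic_mode = "strict",
    keep_het = character(),
    fragment_attachment = NA_integer_,
    opt_max_step = 0.1,
    opt_max_iter = 500L,
    opt_tol = 1e-4,
    opt_max_halvings = 10L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all config overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config option(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "growlite_config")
}

as_config <- function(config) {
  if (is.null(config)) return(growlite_config())
  if (inherits(config, "growlite_config")) return(config)
  do.call(growlite_config, as.list(config))
}
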