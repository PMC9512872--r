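#' Deterministic Fibonacci-sphere direction set
#'
#' @param n Number of directions.
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

ray_descriptor <- function(origin, directions, lengths, max_range) {
  stopifnot(nrow(directions) == length(lengths))
  structure(list(origin = as.numeric(origin), directions = directions,
                 lengths = pmin(pmax(lengths, 0), max_range),
                 max_range = max_range),
            class = "ray_descriptor")
}

#' @export
print.ray_descriptor <- function(x, ...) {
  cat(sprintf("<ray descriptor: %d rays, lengths %.2f-%.2f A (cap %.1f)>\n",
              length(x$lengths), min(x$lengths), max(x$lengths), x$max_range))
  invisible(x)
}

# entry/exit parameters of rays against a set of spheres.
# Returns per-direction first positive surface hit (pocket mode) or the last
# exit (fragment mode).
ray_sphere_hits <- function(origin, dirs, centers, radii, mode, max_range) {
  D <- nrow(dirs)
  if (!nrow(centers)) {
    return(if (mode == "pocket") rep(max_range, D) else rep(0, D))
  }
  oc <- sweep(centers, 2, origin)           # n x 3
  b <- dirs %*% t(oc)                       # D x n
  c2 <- rowSums(oc^2) - radii^2             # n
  disc <- b^2 - matrix(c2, D, length(c2), byrow = TRUE)
  hit <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  t1 <- b - sq                              # entry
  t2 <- b + sq                              # exit
  eps <- 1e-9
  if (mode == "pocket") {
    # first positive root per (ray, atom): entry if ahead, else exit
    first <- ifelse(hit & t1 > eps, t1, ifelse(hit & t2 > eps, t2, Inf))
    out <- apply(first, 1, min)
    pmin(out, max_range)
  } else {
    t2[!hit | t2 <= eps] <- 0
    out <- apply(t2, 1, max)
    pmin(out, max_range)
  }
}

#' Cast the pocket-side ray descriptor
#'
#' Rays start at the anchor's attachment atom and run to the first vdW-surface
#' intersection with a receptor heavy atom (waters excluded), capped at
#' `config$max_range`.
#'
#' @param site A [binding_site()].
#' @param anchor A [core_anchor()]; its attachment atom is the ray origin.
#' @param config A [growlite_config()].
#' @return A `ray_descriptor`.
#' @export
cast_pocket <- function(site, anchor, config = growlite_config()) {
  config <- as_config(config)
  origin <- anchor$core$xyz[anchor$attachment_atom, ]
  rec <- site$receptor
  hv <- heavy_idx(rec)
  centers <- rec$xyz[hv, , drop = FALSE]
  radii <- rec$vdw[hv]
  dirs <- fibonacci_sphere(config$n_rays)
  in_range <- nrow(centers) &&
    any(rowSums(sweep(centers, 2, origin)^2) <= config$max_range^2)
  if (!in_range) {
    warning("open pocket: no receptor atom within ", config$max_range,
            " A of the attachment point")
    return(ray_descriptor(origin, dirs, rep(config$max_range, config$n_rays),
                          config$max_range))
  }
  lens <- ray_sphere_hits(origin, dirs, centers, radii, "pocket",
                          config$max_range)
  ray_descriptor(origin, dirs, lens, config$max_range)
}

#' Cast the fragment-side ray descriptor
#'
#' Symmetric counterpart of [cast_pocket()]: each ray length is the distance
#' to the last exit from the fragment's heavy-atom vdW volume (0 if the ray
#' never enters it).
#'
#' @param frag_pose A `growlite_mol` posed in the pocket frame.
#' @param origin Ray origin (the attachment point).
#' @param directions Direction matrix shared with the pocket descriptor.
#' @param config A [growlite_config()].
#' @return A `ray_descriptor`.
#' @export
cast_fragment <- function(frag_pose, origin, directions,
                          config = growlite_config()) {
  config <- as_config(config)
  if (any(sqrt(rowSums(directions^2)) < 1e-9))
    stop("zero-length ray direction")
  hv <- heavy_idx(frag_pose)
  centers <- frag_pose$xyz[hv, , drop = FALSE]
  radii <- frag_pose$vdw[hv]
  lens <- ray_sphere_hits(as.numeric(origin), directions, centers, radii,
                          "fragment", config$max_range)
  ray_descriptor(origin, directions, lens, config$max_range)
}

#' Shape complementarity score of a fragment descriptor against a pocket
#'
#' `filled` sums, ray by ray, the part of the fragment extent that stays
#' inside the pocket (a filled-volume proxy); `clash` sums the extent beyond
#' the pocket wall past the clash tolerance; `combined = filled -
#' w_clash * clash`. Higher is better.
#'
#' @param pocket,frag `ray_descriptor`s sharing one direction set.
#' @param config A [growlite_config()].
#' @return List with `filled`, `clash`, `combined` (Angstrom units).
#' @export
shape_score <- function(pocket, frag, config = growlite_config()) {
  config <- as_config(config)
  if (length(pocket$lengths) != length(frag$lengths) ||
      max(abs(pocket$directions - frag$directions)) > 1e-9)
    stop("descriptors do not share a direction set")
  filled <- sum(pmin(frag$lengths, pocket$lengths))
  clash <- sum(pmax(0, frag$lengths - pocket$lengths - config$clash_tol))
  list(filled = filled, clash = clash,
       combined = filled - config$w_clash * clash)
}
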