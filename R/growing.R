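#' Count close contacts between a pose's fragment and the receptor
#'
#' Fragment-heavy/receptor-heavy atom pairs whose distance falls inside
#' `config$contact_range` (default 3.2--4.0 A).
#'
#' @param p A [pose()].
#' @param site A [binding_site()].
#' @param config A [growlite_config()].
#' @return Integer count.
#' @export
close_contacts <- function(p, site, config = growlite_config()) {
  config <- as_config(config)
  frag <- pose_fragment(p)
  fi <- heavy_idx(frag)
  ri <- heavy_idx(site$receptor)
  if (!length(fi) || !length(ri)) return(0L)
  d <- pair_dist(frag$xyz[fi, , drop = FALSE],
                 site$receptor$xyz[ri, , drop = FALSE])
  sum(d >= config$contact_range[1] & d <= config$contact_range[2])
}

pair_dist <- function(a, b) {
  # dense distance matrix, rows of a x rows of b
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
}

#' Percent van der Waals overlap between two spheres
#'
#' The default "linear" metric is the penetration fraction
#' `max(0, (r1 + r2 - d) / (r1 + r2)) * 100`; `metric = "volume"` uses the
#' lens intersection volume as a fraction of the smaller sphere's volume.
#'
#' @param d Center distance(s), Angstrom.
#' @param r1,r2 Radii, Angstrom.
#' @param metric `"linear"` or `"volume"`.
#' @return Overlap percentage(s) in `[0, 100]`.
#' @export
vdw_overlap <- function(d, r1, r2, metric = "linear") {
  if (metric == "linear")
    return(pmax(0, (r1 + r2 - d) / (r1 + r2)) * 100)
  # sphere-sphere lens volume over the smaller sphere's volume
  rs <- pmin(r1, r2); rl <- pmax(r1, r2)
  full <- d <= rl - rs
  none <- d >= r1 + r2
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * pmax(d, 1e-12))
  frac <- lens / (4 / 3 * pi * rs^3)
  out <- ifelse(full, 1, ifelse(none, 0, pmin(pmax(frac, 0), 1)))
  out * 100
}

# TRUE if any fragment-heavy / receptor-heavy pair exceeds the hard-clash
# overlap threshold
hard_clash <- function(p, site, config) {
  frag <- pose_fragment(p)
  fi <- heavy_idx(frag)
  ri <- heavy_idx(site$receptor)
  if (!length(fi) || !length(ri)) return(FALSE)
  d <- pair_dist(frag$xyz[fi, , drop = FALSE],
                 site$receptor$xyz[ri, , drop = FALSE])
  ov <- vdw_overlap(d, matrix(frag$vdw[fi], length(fi), length(ri)),
                    matrix(site$receptor$vdw[ri], length(fi), length(ri),
                           byrow = TRUE),
                    metric = config$overlap_metric)
  any(ov > config$overlap_threshold)
}

score_pose <- function(p, pocket_desc, site, config) {
  frag <- pose_fragment(p)
  fd <- cast_fragment(frag, pocket_desc$origin, pocket_desc$directions, config)
  ss <- shape_score(pocket_desc, fd, config)
  ct <- close_contacts(p, site, config)
  p$score <- list(filled = ss$filled, contacts = as.integer(ct),
                  clash = ss$clash,
                  combined = ss$combined + config$w_contact * ct)
  p
}

new_hit_list <- function(poses, n_filtered = 0L, n_fragments = NA_integer_) {
  structure(list(poses = poses,
                 summary = list(n_fragments = n_fragments,
                                n_hits = length(poses),
                                n_filtered = n_filtered)),
            class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hit list: %d hits from %s fragments (%d filtered out)>\n",
              s$n_hits, s$n_fragments, s$n_filtered))
  df <- as.data.frame(x)
  if (nrow(df)) print(utils::head(df, 10))
  invisible(x)
}

#' @export
as.data.frame.hit_list <- function(x, ...) {
  if (!length(x$poses))
    return(data.frame(fragment_id = character(), frame_id = character(),
                      combined = numeric(), filled = numeric(),
                      contacts = integer(), clash = numeric()))
  do.call(rbind, lapply(x$poses, function(p) data.frame(
    fragment_id = p$fragment_id, frame_id = p$frame_id,
    combined = p$score$combined, filled = p$score$filled,
    contacts = p$score$contacts, clash = p$score$clash,
    stringsAsFactors = FALSE)))
}

#' @export
length.hit_list <- function(x) length(x$poses)

# descending combined score, ties by fragment id
sort_hits <- function(poses) {
  if (!length(poses)) return(poses)
  comb <- vapply(poses, function(p) p$score$combined, numeric(1))
  ids <- vapply(poses, function(p) p$fragment_id, character(1))
  poses[order(-comb, ids, method = "radix")]
}

#' Grow a fragment library from a core into a binding site
#'
#' For each library fragment: attachment poses are enumerated
#' ([enumerate_attachments()]), poses in hard steric clash with the receptor
#' (any heavy-atom pair above the vdW overlap threshold) are dropped, poses
#' failing any search point are dropped ([match_pose()]), survivors are
#' scored by shape complementarity plus weighted close contacts, and the best
#' `config$top_k` pose(s) per fragment enter the hit list, sorted by
#' descending combined score (ties by fragment id).
#'
#' @param anchor A [core_anchor()] posed in the site.
#' @param site A [binding_site()].
#' @param fragment_library List of `growlite_mol` (named or carrying names).
#' @param search_points Optional list of [search_point()]s; a surviving pose
#'   must satisfy all of them.
#' @param config A [growlite_config()].
#' @return A `hit_list`; its `summary` reports how many fragments were
#'   filtered out entirely.
#' @export
grow <- function(anchor, site, fragment_library, search_points = NULL,
                 config = growlite_config()) {
  config <- as_config(config)
  if (!length(fragment_library)) stop("empty fragment library")
  site_dry <- strip_waters(site)
  pocket_desc <- cast_pocket(site_dry, anchor, config)
  hits <- list()
  n_filtered <- 0L
  for (k in seq_along(fragment_library)) {
    frag <- fragment_library[[k]]
    if (is.null(frag$name) || frag$name == "mol")
      frag$name <- sprintf("frag_%03d", k)
    poses <- enumerate_attachments(anchor, frag, config)
    poses <- Filter(function(p) !hard_clash(p, site_dry, config), poses)
    if (!is.null(search_points) && length(search_points))
      poses <- Filter(function(p) match_pose(p, search_points, config)$pass,
                      poses)
    if (!length(poses)) { n_filtered <- n_filtered + 1L; next }
    poses <- lapply(poses, score_pose, pocket_desc = pocket_desc,
                    site = site_dry, config = config)
    poses <- lapply(poses, function(p) { p$frame_id <- site$frame_id; p })
    best <- sort_hits(poses)[seq_len(min(config$top_k, length(poses)))]
    hits <- c(hits, best)
  }
  if (!length(hits))
    warning("all ", length(fragment_library),
            " fragments were filtered out; empty hit list")
  new_hit_list(sort_hits(hits), n_filtered, length(fragment_library))
}

#' Write a hit list to SDF with score tags
#'
#' Each pose is written with SD tags `combined_score`, `filled`, `contacts`,
#' `clash`, `frame_id` and `fragment_id`.
#'
#' @param hits A `hit_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  mols <- lapply(hits$poses, function(p) p$ligand)
  tags <- lapply(hits$poses, function(p) list(
    combined_score = sprintf("%.4f", p$score$combined),
    filled = sprintf("%.4f", p$score$filled),
    contacts = p$score$contacts,
    clash = sprintf("%.4f", p$score$clash),
    frame_id = p$frame_id,
    fragment_id = p$fragment_id))
  write_sdf(mols, path, tags)
}
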