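#' Aligned binding-site ensemble
#'
#' Between 2 and `max_members` pre-aligned conformations of one binding site,
#' sharing a frame with the core anchor. No superposition is performed here;
#' members must already be aligned.
#'
#' @param members List of [binding_site()] with distinct `frame_id`s.
#' @param anchor A [core_anchor()] valid in every member.
#' @param max_members Cap on ensemble size (default 5).
#' @return An object of class `ensemble_site`.
#' @export
ensemble_site <- function(members, anchor, max_members = 5L) {
  if (length(members) < 2)
    stop("an ensemble needs at least two binding-site conformations")
  if (length(members) > max_members)
    stop("ensemble limited to ", max_members, " binding-site conformations")
  ids <- vapply(members, function(m) m$frame_id, character(1))
  if (anyDuplicated(ids)) stop("ensemble members must have distinct frame_ids")
  structure(list(members = members, anchor = anchor), class = "ensemble_site")
}

#' @export
print.ensemble_site <- function(x, ...) {
  cat(sprintf("<ensemble: %d members (%s)>\n", length(x$members),
              paste(vapply(x$members, function(m) m$frame_id, character(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Read an ensemble from a directory of aligned PDB files
#'
#' Each `*.pdb` file becomes one member; `frame_id` is the file name stem.
#'
#' @param dir Directory of aligned member PDBs.
#' @param anchor A [core_anchor()].
#' @param config A [growlite_config()].
#' @param max_members Cap on ensemble size.
#' @return An [ensemble_site()].
#' @export
read_ensemble <- function(dir, anchor, config = growlite_config(),
                          max_members = 5L) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  members <- lapply(files, read_pdb, config = config)
  ensemble_site(members, anchor, max_members)
}

#' Screen a fragment library against a binding-site ensemble
#'
#' Runs [grow()] in every member and keeps, per fragment, the single
#' best-scoring pose across members (ties broken by lexicographically
#' smallest `frame_id`). A fragment survives if it survives in at least one
#' member, so a conformation clashing in all but one member is scored from
#' the non-clashing one.
#'
#' @param ensemble An [ensemble_site()].
#' @param fragment_library List of `growlite_mol`.
#' @param search_points Optional list of [search_point()].
#' @param config A [growlite_config()].
#' @return A `hit_list` with `frame_id` identifying the winning member.
#' @export
grow_ensemble <- function(ensemble, fragment_library, search_points = NULL,
                          config = growlite_config()) {
  config <- as_config(config)
  per_member <- lapply(ensemble$members, function(site)
    suppressWarnings(grow(ensemble$anchor, site, fragment_library,
                          search_points, config)))
  best <- list()
  n_members_filtered <- integer()
  for (hl in per_member) {
    for (p in hl$poses) {
      cur <- best[[p$fragment_id]]
      if (is.null(cur) ||
          p$score$combined > cur$score$combined ||
          (p$score$combined == cur$score$combined &&
             p$frame_id < cur$frame_id)) {
        best[[p$fragment_id]] <- p
      }
    }
  }
  n_frag <- length(fragment_library)
  n_filtered <- n_frag - length(best)
  if (!length(best))
    warning("all fragments filtered out in every ensemble member")
  new_hit_list(sort_hits(unname(best)), n_filtered, n_frag)
}
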