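#' Read a binding site from a PDB file
#'
#' Waters (HOH/WAT residues) are separated from the receptor; only altloc A
#' (or blank) and the first model are kept; hydrogens are retained when
#' present. HETATM records are excluded from the receptor unless their residue
#' name appears in `config$keep_het`. Elements get vdW radii from the fixed
#' package table.
#'
#' @param path Path to a PDB file.
#' @param config A [growlite_config()].
#' @param frame_id Frame identifier; defaults to the file name stem.
#' @return A [binding_site()].
#' @export
read_pdb <- function(path, config = growlite_config(), frame_id = NULL) {
  config <- as_config(config)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(frame_id)) frame_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB format error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("PDB format error in ", path,
                                     ": no atom records")
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  element[missing_el] <- substr(trimws(at$elety[missing_el]), 1, 1)
  element <- normalize_element(trimws(element))
  is_wat <- at$resid %in% c("HOH", "WAT")
  is_het <- at$type == "HETATM" & !is_wat
  keep_rec <- !is_wat & (!is_het | at$resid %in% config$keep_het)
  xyz <- cbind(at$x, at$y, at$z)
  receptor <- molecule(element[keep_rec], xyz[keep_rec, , drop = FALSE],
                       name = frame_id)
  attr(receptor, "resid") <- at$resid[keep_rec]
  attr(receptor, "resno") <- at$resno[keep_rec]
  wat_keep <- is_wat & element == "O"
  waters <- molecule(element[wat_keep], xyz[wat_keep, , drop = FALSE],
                     name = "waters", is_water = TRUE)
  binding_site(receptor, waters, frame_id)
}

# PDB element columns are upper case ("CL"); bring them to symbol case
normalize_element <- function(el) {
  known <- names(.vdw_table)
  up <- toupper(el)
  match_up <- match(up, toupper(known))
  out <- el
  out[!is.na(match_up)] <- known[match_up[!is.na(match_up)]]
  out
}

#' Prepare a binding site for growing against a core
#'
#' Removes waters that sterically clash with the input core (vdW overlap
#' above `config$prep_clash_overlap` percent) and warns about receptor atoms
#' that do.
#'
#' @param site A [binding_site()].
#' @param anchor A [core_anchor()] posed in the site.
#' @param config A [growlite_config()].
#' @return The pruned [binding_site()].
#' @export
prepare_site <- function(site, anchor, config = growlite_config()) {
  config <- as_config(config)
  core <- anchor$core
  ci <- heavy_idx(core)
  max_overlap <- function(mol, idx) {
    vapply(idx, function(w) {
      d <- sqrt(colSums((t(core$xyz[ci, , drop = FALSE]) - mol$xyz[w, ])^2))
      max(vdw_overlap(d, core$vdw[ci], mol$vdw[w],
                      metric = config$overlap_metric))
    }, numeric(1))
  }
  if (n_atoms(site$waters)) {
    ov <- max_overlap(site$waters, seq_len(n_atoms(site$waters)))
    drop <- ov > config$prep_clash_overlap
    if (any(drop))
      site$waters <- subset_mol(site$waters, which(!drop), name = "waters")
  }
  ri <- heavy_idx(site$receptor)
  if (length(ri)) {
    ov <- max_overlap(site$receptor, ri)
    if (any(ov > config$prep_clash_overlap))
      warning(sum(ov > config$prep_clash_overlap),
              " receptor atom(s) clash with the input core")
  }
  site
}

#' Write a binding site to a PDB file
#'
#' Receptor atoms become ATOM records, waters HETATM/HOH records. Intended for
#' fixture export; occupancy and B-factor are zeroed.
#'
#' @param site A [binding_site()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_site <- function(site, path) {
  rec <- site$receptor
  wat <- site$waters
  n_r <- n_atoms(rec)
  n_w <- n_atoms(wat)
  xyz <- rbind(rec$xyz, wat$xyz)
  resid <- attr(rec, "resid")
  if (is.null(resid)) resid <- rep("UNK", n_r)
  resno <- attr(rec, "resno")
  if (is.null(resno)) resno <- seq_len(n_r)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = c(rep("ATOM", n_r), rep("HETATM", n_w)),
    resno = c(resno, max(c(resno, 0)) + seq_len(n_w)),
    resid = c(resid, rep("HOH", n_w)),
    eleno = seq_len(n_r + n_w),
    elety = c(rec$elements, wat$elements),
    chain = rep("A", n_r + n_w),
    elesy = c(rec$elements, wat$elements)
  )
  invisible(path)
}
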