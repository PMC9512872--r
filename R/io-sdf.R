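#' Read an SDF/MOL file into a list of molecules
#'
#' Records are split on `$$$$` and parsed individually so that a malformed
#' record is skipped with a warning instead of aborting the whole file.
#' Bond orders and 3D coordinates are preserved; SD data tags are attached as
#' the `tags` attribute of each molecule.
#'
#' @param path Path to an SDF or MOL file.
#' @return A list of `growlite_mol`.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("no readable SDF records in ", path)
  # a bare MOL file has no $$$$ terminator
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) {
    starts <- 1L
    ends <- length(lines)
  } else {
    starts <- c(1L, head(ends, -1L) + 1L)
  }
  out <- list()
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    m <- tryCatch(parse_sdf_record(rec), error = function(e) e)
    if (inherits(m, "error")) {
      warning("skipping unreadable SDF record ", k, ": ",
              conditionMessage(m))
    } else {
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out)) stop("no readable SDF records in ", path)
  out
}

# one record through ChemmineR, then into the growlite model
parse_sdf_record <- function(rec) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  if (!any(trimws(rec) == "$$$$")) rec <- c(rec, "$$$$")
  writeLines(rec, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  if (!length(sdfs)) stop("empty record")
  sdf <- sdfs[[1]]
  if (!ChemmineR::validSDF(sdfs)) stop("invalid SDF record")
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  bonds <- if (length(bb) && nrow(bb)) {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  } else NULL
  nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
  if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- "mol"
  m <- molecule(elements, xyz, bonds, name = nm)
  db <- ChemmineR::datablock(sdf)
  if (length(db)) attr(m, "tags") <- db
  m
}

format_molblock <- function(mol, tags = NULL) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  lines <- c(
    mol$name, "  growlite", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3], mol$elements)
  bond_lines <- if (nb) {
    sprintf("%3d%3d%3d  0", mol$bonds[, 1], mol$bonds[, 2], mol$bonds[, 3])
  } else character()
  lines <- c(lines, atom_lines, bond_lines, "M  END")
  if (length(tags)) {
    for (tn in names(tags))
      lines <- c(lines, sprintf("> <%s>", tn), as.character(tags[[tn]]), "")
  }
  c(lines, "$$$$")
}

#' Write molecules to an SDF file
#'
#' Emits V2000 connection tables; any `tags` attribute (or entries of the
#' `tags` argument) becomes SD data fields.
#'
#' @param mols A `growlite_mol` or list of them.
#' @param path Output path.
#' @param tags Optional list (parallel to `mols`) of named tag lists.
#' @return Invisibly, `path`.
#' @export
write_sdf <- function(mols, path, tags = NULL) {
  if (inherits(mols, "growlite_mol")) mols <- list(mols)
  out <- unlist(lapply(seq_along(mols), function(k) {
    tg <- if (!is.null(tags)) tags[[k]] else attr(mols[[k]], "tags")
    format_molblock(mols[[k]], tg)
  }))
  writeLines(out, path)
  invisible(path)
}
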