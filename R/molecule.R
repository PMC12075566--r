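#' Construct a small molecule with 3D coordinates
#'
#' `molecule3d()` is the basic ligand container used throughout the package:
#' a molecular graph (elements, bonds, formal charges) with one 3D conformer.
#' Structures are expected to arrive prepared (explicit hydrogens, assigned
#' formal charges, resolved protonation state); the package does not perform
#' ligand preparation.
#'
#' @param id Character scalar, compound identifier.
#' @param elements Character vector of element symbols (one per atom).
#' @param coords Numeric matrix, n x 3, Cartesian coordinates in Angstrom.
#' @param charges Integer vector of formal charges, one per atom. Defaults
#'   to all zero.
#' @param bonds Data frame (or matrix) with columns `from`, `to`, `order`
#'   giving 1-based atom indices and bond order (4 = aromatic).
#' @param conformer_id Integer conformer/protomer tag (default 1).
#'
#' @return An object of class `molecule3d`.
#' @export
molecule3d <- function(id, elements, coords, charges = NULL, bonds = NULL,
                       conformer_id = 1L) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_input("molecule id must be a non-empty string")
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(elements))
    abort_input("coords must be an n x 3 matrix matching elements")
  if (!all(is.finite(coords)))
    abort_input(sprintf("molecule '%s' has non-finite coordinates", id))
  if (is.null(charges)) charges <- integer(length(elements))
  if (length(charges) != length(elements))
    abort_input("charges must have one entry per atom")
  if (is.null(bonds)) {
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("from", "to", "order")
    if (nrow(bonds) && (any(bonds$from < 1) || any(bonds$to < 1) ||
                        any(bonds$from > length(elements)) ||
                        any(bonds$to > length(elements))))
      abort_input(sprintf("molecule '%s' has bond indices outside the atom list", id))
  }
  if (!any(elements != "H"))
    abort_input(sprintf("molecule '%s' has no heavy atom", id))
  structure(list(id = id, elements = as.character(elements), coords = coords,
                 charges = as.integer(charges), bonds = bonds,
                 conformer_id = as.integer(conformer_id)),
            class = "molecule3d")
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s (conformer %d): %d atoms (%d heavy), %d bonds\n",
              x$id, x$conformer_id, length(x$elements),
              sum(x$elements != "H"), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

heavy_idx <- function(mol) which(mol$elements != "H")

# Adjacency list of the molecular graph (list of integer vectors).
mol_adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$from[i]; b <- mol$bonds$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Apply a rigid transformation to a molecule
#'
#' Rotates (about the origin) and translates all atom coordinates. Used in
#' equivariance checks and by the synthetic-data generators.
#'
#' @param mol A [molecule3d()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric translation vector.
#' @return The transformed `molecule3d`.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mol, "molecule3d"))
  mol$coords <- mol$coords %*% t(rotation) +
    matrix(translation, nrow(mol$coords), 3, byrow = TRUE)
  mol
}

#' Read molecules from an SDF file
#'
#' Thin wrapper over [ChemmineR::read.SDFset()] that converts each valid
#' record into a [molecule3d()]. Formal charges are taken from the SDF
#' charge block (`M  CHG`); records failing validity checks are reported,
#' not fatal.
#'
#' @param path Path to an SDF (V2000) file.
#' @return A list with `molecules` (list of `molecule3d`) and `failures`
#'   (character vector of messages for rejected records).
#' @export
read_sdf_molecules <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("SDF file not found: %s", path))
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfs)
  failures <- character()
  if (any(!ok))
    failures <- sprintf("record %d: invalid SDF block", which(!ok))
  # ChemmineR drops "M  CHG" property lines; recover formal charges from the
  # raw records (one text block per molecule, split on the $$$$ delimiter).
  raw <- readLines(path, warn = FALSE)
  recs <- split(raw, cumsum(c(0L, head(raw == "$$$$", -1L))))
  mols <- list()
  ids <- ChemmineR::sdfid(sdfs)
  for (i in which(ok)) {
    chg <- parse_chg_lines(recs[[i]])
    m <- tryCatch(sdf_to_molecule(sdfs[[i]], id = ids[i], charges = chg),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) failures <- c(failures, sprintf("record %d: %s", i, m))
    else mols[[length(mols) + 1L]] <- m
  }
  list(molecules = mols, failures = failures)
}

# Parse "M  CHG n (atom charge)*n" lines of one raw SDF record.
parse_chg_lines <- function(lines) {
  out <- data.frame(atom = integer(), charge = integer())
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    v <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]])
    if (length(v) >= 2)
      out <- rbind(out, data.frame(atom = v[seq(1, length(v), 2)],
                                   charge = v[seq(2, length(v), 2)]))
  }
  out
}

# Convert one ChemmineR SDF object into a molecule3d.
sdf_to_molecule <- function(sdf, id = NULL, conformer_id = 1L, charges = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  chg <- integer(length(elements))
  if (!is.null(charges) && nrow(charges)) chg[charges$atom] <- charges$charge
  bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  if (is.null(id)) id <- ChemmineR::header(sdf)[["Molecule_Name"]]
  molecule3d(id = as.character(id), elements = elements, coords = coords,
             charges = chg, bonds = bonds, conformer_id = conformer_id)
}

#' Ingest pre-enumerated protomer/conformer records
#'
#' Protonation-state enumeration happens upstream; this function ingests a
#' table of pre-enumerated records (one row per protomer or charge state,
#' e.g. the 2+ and 3+ forms of an aminoglycoside arriving as two records)
#' and returns one molecule per record. Malformed records are collected in a
#' per-record failure report rather than aborting the batch; duplicate
#' (id, tag) keys are a hard input error.
#'
#' @param records Data frame with columns `id`, `tag` (protomer/conformer
#'   label) and `molecule` (a list-column of [molecule3d()] objects or SDF
#'   text blocks).
#' @return List with `molecules` and `failures` (data frame id/tag/message).
#' @export
enumerate_protomer_inputs <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    return(list(molecules = list(),
                failures = data.frame(id = character(), tag = character(),
                                      message = character())))
  if (!all(c("id", "tag", "molecule") %in% names(records)))
    abort_input("records need columns id, tag, molecule")
  key <- paste(records$id, records$tag, sep = "\r")
  if (anyDuplicated(key))
    abort_input(sprintf("duplicate (id, tag) record keys: %s",
                        paste(unique(records$id[duplicated(key)]), collapse = ", ")))
  mols <- list()
  fails <- list()
  for (i in seq_len(nrow(records))) {
    item <- records$molecule[[i]]
    m <- tryCatch({
      if (inherits(item, "molecule3d")) item
      else if (is.character(item)) {
        tmp <- tempfile(fileext = ".sdf")
        writeLines(item, tmp)
        on.exit(unlink(tmp), add = TRUE)
        got <- read_sdf_molecules(tmp)
        if (length(got$molecules) != 1L) abort_input("unparsable SDF block")
        got$molecules[[1]]
      } else abort_input("unsupported molecule payload")
    }, error = function(e) e)
    if (inherits(m, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        id = records$id[i], tag = records$tag[i], message = conditionMessage(m))
    } else {
      m$id <- as.character(records$id[i])
      m$conformer_id <- i
      attr(m, "tag") <- as.character(records$tag[i])
      mols[[length(mols) + 1L]] <- m
    }
  }
  list(molecules = mols,
       failures = if (length(fails)) do.call(rbind, fails)
       else data.frame(id = character(), tag = character(), message = character()))
}
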