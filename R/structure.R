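#' Atomic structure model
#'
#' A flat table of atom records: element, atom name, residue name, residue
#' number, chain, coordinates in Å and occupancy. This is the coordinate
#' currency of the measurement operations; [load_model()] builds it from
#' PDB/mmCIF files and the fixture generator builds it directly.
#'
#' @param atoms data.frame with columns `elem`, `atom`, `resid`, `resno`,
#'   `chain`, `x`, `y`, `z`, `occ`.
#' @return An object of class `mem_structure` (a data.frame subclass).
#' @export
structure_model <- function(atoms) {
  need <- c("elem", "atom", "resid", "resno", "chain", "x", "y", "z", "occ")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  atoms <- as.data.frame(atoms)[, need]
  class(atoms) <- c("mem_structure", "data.frame")
  atoms
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records (via bio3d), preserving chain and residue
#' indexing. The same model stored as PDB and as mmCIF yields identical
#' coordinates.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @return a [structure_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty model file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    suppressWarnings(switch(ext,
           cif = bio3d::read.cif(path),
           pdb = , ent = bio3d::read.pdb(path),
           stop("unsupported model format: .", ext, " (use PDB or mmCIF)"))),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no atom records in ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- toupper(substr(trimws(a$elety), 1, 1))
  structure_model(data.frame(
    elem = trimws(elem), atom = trimws(a$elety), resid = trimws(a$resid),
    resno = a$resno, chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    occ = if (is.null(a$o)) 1 else ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE))
}

#' Select atoms of a structure model
#'
#' Conjunctive selection by chain, residue name, residue number, atom name
#' and element, optionally restricted to atoms within a radius of a set of
#' reference atoms or of a point.
#'
#' @param model a [structure_model()].
#' @param chain,resid,resno,atom,elem optional vectors; an atom matches if
#'   its field is in the vector (all given filters must match).
#' @param within optional list `list(radius = Å, of = <mem_structure or
#'   length-3 point>)` keeping only atoms within `radius` of `of`.
#' @return a [structure_model()] subset (possibly 0 rows).
#' @export
select_atoms <- function(model, chain = NULL, resid = NULL, resno = NULL,
                         atom = NULL, elem = NULL, within = NULL) {
  stopifnot(inherits(model, "mem_structure"))
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resid)) keep <- keep & model$resid %in% resid
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(atom))  keep <- keep & model$atom %in% atom
  if (!is.null(elem))  keep <- keep & model$elem %in% elem
  sub <- model[keep, , drop = FALSE]
  if (!is.null(within)) {
    ref <- within$of
    pts <- if (inherits(ref, "mem_structure"))
      as.matrix(ref[, c("x", "y", "z")]) else matrix(ref, ncol = 3)
    if (nrow(sub) > 0) {
      d2min <- min_dist2_to_set(as.matrix(sub[, c("x", "y", "z")]), pts)
      sub <- sub[d2min <= within$radius^2, , drop = FALSE]
    }
  }
  class(sub) <- c("mem_structure", "data.frame")
  sub
}

# For each row of A (n x 3), squared distance to the nearest row of B.
min_dist2_to_set <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  pmax(apply(d2, 1, min), 0)
}

#' Geometric measurement result
#'
#' @param kind one of `"membrane_height"`, `"m_distance"`, `"e_distance"`,
#'   `"group_distance"`.
#' @param value measured value in Å (signed for `m_distance`).
#' @param n_atoms_used number of atoms entering the measurement.
#' @param frame free-text note of the coordinate frame / alignment applied.
#' @return An object of class `measurement_result`.
#' @export
measurement_result <- function(kind, value, n_atoms_used, frame = "input") {
  kind <- match.arg(kind, c("membrane_height", "m_distance", "e_distance",
                            "group_distance"))
  # heights are signed (below the reference plane is negative); Euclidean
  # distances are not
  if (kind %in% c("e_distance", "group_distance") && value < 0)
    stop("distance must be >= 0")
  structure(list(kind = kind, value = value,
                 n_atoms_used = as.integer(n_atoms_used), frame = frame),
            class = "measurement_result")
}

#' @export
print.measurement_result <- function(x, ...) {
  cat(sprintf("<%s: %.2f Å (n = %d atoms, frame: %s)>\n",
              x$kind, x$value, x$n_atoms_used, x$frame))
  invisible(x)
}

#' Local membrane-surface height from lipid headgroups
#'
#' Mean z of headgroup atoms within a lateral+vertical radius of a region
#' centre, in a frame where the membrane normal is the z axis (align the
#' model first, e.g. with the rotation from [fit_reference_plane()] on its
#' lipid atoms). This is the scalar membrane-surface reference used for
#' ligand-height (M-distance) measurements.
#'
#' @param model an aligned [structure_model()].
#' @param region_centre numeric length-3, Å.
#' @param radius inclusion radius around `region_centre`, Å.
#' @param headgroup a [structure_model()] of headgroup atoms, or `NULL` to
#'   use phosphorus atoms of `model`.
#' @param frame note recorded in the result.
#' @return a [measurement_result()] of kind `membrane_height`.
#' @export
membrane_height <- function(model, region_centre = c(0, 0, 0), radius = Inf,
                            headgroup = NULL, frame = "z-aligned") {
  if (is.null(headgroup)) headgroup <- select_atoms(model, elem = "P")
  sel <- if (is.finite(radius))
    select_atoms(headgroup, within = list(radius = radius, of = region_centre))
  else headgroup
  if (nrow(sel) == 0) stop("no headgroup atoms in region")
  measurement_result("membrane_height", mean(sel$z), nrow(sel), frame)
}

# The ligand reference atom: 1-carbonyl oxygen (atom name O1) if present,
# else the centroid of the selection (returned as a 1-row pseudo-atom).
ligand_reference <- function(ligand) {
  if (nrow(ligand) == 0) stop("ligand selection is empty")
  o1 <- ligand[ligand$atom == "O1", , drop = FALSE]
  if (nrow(o1) >= 1) return(list(xyz = unlist(o1[1, c("x", "y", "z")]),
                                 n = 1L, how = "O1"))
  list(xyz = colMeans(ligand[, c("x", "y", "z")]), n = nrow(ligand),
       how = "centroid")
}

#' Ligand height above the membrane surface (M-distance)
#'
#' Signed z of the ligand reference atom (the quinone 1-carbonyl oxygen
#' `O1`, falling back to the selection centroid) minus the membrane-surface
#' height. Positive values are above the surface (towards +z), negative
#' below.
#'
#' @param model an aligned [structure_model()] (same frame as the height).
#' @param ligand a [structure_model()] selecting the ligand atoms.
#' @param height a [measurement_result()] from [membrane_height()].
#' @return a [measurement_result()] of kind `m_distance` (signed).
#' @export
m_distance <- function(model, ligand, height) {
  stopifnot(inherits(height, "measurement_result"),
            height$kind == "membrane_height")
  ref <- ligand_reference(ligand)
  structure(list(kind = "m_distance", value = ref$xyz[[3]] - height$value,
                 n_atoms_used = ref$n + height$n_atoms_used,
                 frame = height$frame),
            class = "measurement_result")
}

#' Ligand distance from the channel entrance (E-distance)
#'
#' Euclidean distance from the ligand reference atom to a user-supplied
#' entrance landmark. The landmark has no operational definition in
#' structural databases and must be provided by the user.
#'
#' @param model a [structure_model()].
#' @param ligand a [structure_model()] selecting the ligand atoms.
#' @param entrance_point numeric length-3, Å.
#' @return a [measurement_result()] of kind `e_distance`.
#' @export
e_distance <- function(model, ligand, entrance_point) {
  stopifnot(length(entrance_point) == 3)
  ref <- ligand_reference(ligand)
  measurement_result("e_distance",
                     sqrt(sum((ref$xyz - entrance_point)^2)), ref$n)
}

#' Distance between two atom groups
#'
#' Minimum pairwise or centroid-centroid Euclidean distance between two
#' selections, in Å.
#'
#' @param model a [structure_model()] (carried for provenance; distances use
#'   the selections directly).
#' @param selection_a,selection_b [structure_model()] selections.
#' @param mode `"min"` (default) or `"centroid"`.
#' @return a [measurement_result()] of kind `group_distance`.
#' @export
group_distance <- function(model, selection_a, selection_b,
                           mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  if (nrow(selection_a) == 0 || nrow(selection_b) == 0)
    stop("empty selection in group_distance")
  A <- as.matrix(selection_a[, c("x", "y", "z")])
  B <- as.matrix(selection_b[, c("x", "y", "z")])
  d <- if (mode == "min") {
    # locate the closest pair with the fast quadratic form, then recompute
    # its distance with the direct formula so the result is bit-identical
    # to a naive pairwise evaluation
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    ij <- which(d2 == min(d2), arr.ind = TRUE)
    cand <- vapply(seq_len(nrow(ij)), function(k)
      sqrt(sum((A[ij[k, 1], ] - B[ij[k, 2], ])^2)), 0)
    min(cand)
  } else {
    sqrt(sum((colMeans(A) - colMeans(B))^2))
  }
  measurement_result("group_distance", d, nrow(A) + nrow(B))
}

#' Apply a rigid motion to a structure model
#'
#' @param model a [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3, Å.
#' @return the transformed [structure_model()].
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rotation)
  model$x <- xyz[, 1] + translation[1]
  model$y <- xyz[, 2] + translation[2]
  model$z <- xyz[, 3] + translation[3]
  model
}
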