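#' Export a fitted surface as a Wavefront OBJ mesh
#'
#' Triangulates the mid-surface grid (missing nodes are skipped) and writes
#' vertices in Å.
#'
#' @param model a `bilayer_surface`.
#' @param path output `.obj` path.
#' @param field which height field to export (default `"z_mid"`).
#' @return `path`, invisibly.
#' @export
write_surface_obj <- function(model, path, field = "z_mid") {
  z <- model[[field]]
  nx <- length(model$x); ny <- length(model$y)
  vid <- matrix(NA_integer_, nx, ny)
  verts <- character(0)
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!is.na(z[i, j])) {
      k <- k + 1L
      vid[i, j] <- k
      verts <- c(verts, sprintf("v %.3f %.3f %.3f",
                                model$x[i], model$y[j], z[i, j]))
    }
  }
  faces <- character(0)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    q <- c(vid[i, j], vid[i + 1, j], vid[i + 1, j + 1], vid[i, j + 1])
    if (!anyNA(q)) {
      faces <- c(faces, sprintf("f %d %d %d", q[1], q[2], q[3]),
                 sprintf("f %d %d %d", q[1], q[3], q[4]))
    }
  }
  writeLines(c("# cryomem surface mesh", verts, faces), path)
  invisible(path)
}

#' Export a surface with altitude and curvature as TSV
#'
#' One row per non-missing grid node: `x_A`, `y_A`, `z_mid_A`,
#' `altitude_A`, `H_per_nm`, `K_per_nm2`.
#'
#' @param model a `bilayer_surface`.
#' @param field a `curvature_field` from [surface_curvature()] on the same
#'   grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(model, field, path) {
  g <- expand.grid(ix = seq_along(model$x), iy = seq_along(model$y))
  df <- data.frame(x_A = model$x[g$ix], y_A = model$y[g$iy],
                   z_mid_A = model$z_mid[cbind(g$ix, g$iy)],
                   altitude_A = field$altitude[cbind(g$ix, g$iy)],
                   H_per_nm = field$H[cbind(g$ix, g$iy)],
                   K_per_nm2 = field$K[cbind(g$ix, g$iy)])
  df <- df[!is.na(df$z_mid_A), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a structure model as PDB
#'
#' @param model a [structure_model()].
#' @param path output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "mem_structure"))
  n <- nrow(model)
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", n),
                   resno = model$resno, resid = model$resid,
                   chain = substr(ifelse(model$chain == "", "A", model$chain),
                                  1, 1),
                   elety = model$atom, o = model$occ, b = rep(0, n),
                   elesy = model$elem)
  invisible(path)
}

#' Append measurement results to a TSV report
#'
#' @param results a [measurement_result()] or list of them.
#' @param path report path; created with a header if absent.
#' @param model_name free-text provenance column.
#' @return `path`, invisibly.
#' @export
write_measurements_tsv <- function(results, path, model_name = "") {
  if (inherits(results, "measurement_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(kind = r$kind, value_A = r$value, n_atoms = r$n_atoms_used,
               frame = r$frame, model = model_name)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' Read a measurement TSV report
#'
#' @param path report path.
#' @return data.frame with columns kind, value_A, n_atoms, frame, model.
#' @export
read_measurements_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
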