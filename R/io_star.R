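#' Write a metadata table as a STAR file
#'
#' RELION-style loop dialect: a `data_` block, a `loop_` header listing one
#' `_column #index` tag per column, then whitespace-separated rows. Column
#' names are written verbatim with a leading underscore.
#'
#' @param df data.frame.
#' @param path output path.
#' @param block data block name (default `"cryomem"`).
#' @return `path`, invisibly.
#' @export
write_star <- function(df, path, block = "cryomem") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  if (nrow(df) > 0) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }, character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df))
    writeLines(apply(cells, 1, paste, collapse = "  "), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read a metadata table from a STAR file
#'
#' Reads the first (or named) `data_` block's loop. Unknown columns are
#' preserved untouched; numeric-looking columns are converted.
#'
#' @param path path to a STAR file.
#' @param required optional character vector of column names that must be
#'   present.
#' @return data.frame.
#' @export
read_star <- function(path, required = NULL) {
  lines <- readLines(path, warn = FALSE)
  ln <- trimws(lines)
  li <- which(ln == "loop_")
  if (length(li) == 0) stop("no loop_ block in STAR file ", path)
  i <- li[1] + 1
  cols <- character(0)
  while (i <= length(ln) && startsWith(ln[i], "_")) {
    tag <- sub("^_", "", strsplit(ln[i], "[ \t#]+")[[1]][1])
    cols <- c(cols, tag)
    i <- i + 1
  }
  if (length(cols) == 0)
    stop(sprintf("malformed STAR loop at line %d: no column tags", li[1] + 1))
  rows <- list()
  while (i <= length(ln)) {
    if (ln[i] == "" || startsWith(ln[i], "data_")) break
    if (startsWith(ln[i], "#")) { i <- i + 1; next }
    fields <- strsplit(ln[i], "[ \t]+")[[1]]
    if (length(fields) != length(cols))
      stop(sprintf("malformed STAR loop at line %d: %d fields for %d columns",
                   i, length(fields), length(cols)))
    rows[[length(rows) + 1]] <- fields
    i <- i + 1
  }
  df <- if (length(rows) == 0) {
    stats::setNames(as.data.frame(matrix(character(0), 0, length(cols)),
                                  stringsAsFactors = FALSE), cols)
  } else {
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- cols
    out
  }
  for (j in seq_along(df)) {
    conv <- suppressWarnings(as.numeric(df[[j]]))
    if (nrow(df) > 0 && !anyNA(conv)) df[[j]] <- conv
  }
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop("STAR file ", path, " is missing required column(s): ",
           paste(miss, collapse = ", "))
  }
  df
}

#' Write ground-truth segments as a STAR table
#'
#' @param segments list of [arc_segment()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_star <- function(segments, path) {
  df <- data.frame(
    segment_id = seq_along(segments),
    centre_x_A = vapply(segments, function(s) s$centre[1], 0),
    centre_y_A = vapply(segments, function(s) s$centre[2], 0),
    theta_deg = vapply(segments, function(s) s$theta, 0),
    kappa_per_nm = vapply(segments, function(s) s$kappa, 0),
    length_A = vapply(segments, function(s) s$length, 0),
    thickness_A = vapply(segments, function(s) s$thickness, 0))
  write_star(df, path, block = "segments")
}

#' Read ground-truth segments written by [write_segments_star()]
#'
#' @param path STAR file path.
#' @return list of [arc_segment()]s.
#' @export
read_segments_star <- function(path) {
  df <- read_star(path, required = c("segment_id", "centre_x_A", "centre_y_A",
                                     "theta_deg", "kappa_per_nm", "length_A",
                                     "thickness_A"))
  lapply(seq_len(nrow(df)), function(i) {
    arc_segment(centre = c(df$centre_x_A[i], df$centre_y_A[i]),
                theta = df$theta_deg[i], kappa = df$kappa_per_nm[i],
                length = df$length_A[i], thickness = df$thickness_A[i])
  })
}
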