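# Plain-text interchange: centerlines as CSV, surfaces as ASCII STL,
# landmarks as JSON.

#' Write a centerline to CSV
#'
#' Columns `x`, `y`, `z` (cm) and `local_diameter_cm`.
#'
#' @param cl An `aorta_centerline`.
#' @param path Output file.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1], y = cl$points[, 2],
                   z = cl$points[, 3],
                   local_diameter_cm = cl$local_diameter)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline from CSV
#'
#' Expects columns `x`, `y`, `z` (cm); an optional `local_diameter_cm`
#' column (otherwise `default_diameter` is used throughout).
#'
#' @param path CSV file.
#' @param default_diameter Diameter (cm) when the file carries none.
#' @return An `aorta_centerline`.
#' @export
read_centerline_csv <- function(path, default_diameter = 2.0) {
  df <- utils::read.csv(path)
  stop_if(!all(c("x", "y", "z") %in% names(df)),
          "centerline CSV needs columns x, y, z")
  dia <- if ("local_diameter_cm" %in% names(df)) df$local_diameter_cm else
    default_diameter
  aorta_centerline(as.matrix(df[, c("x", "y", "z")]), dia)
}

#' Write a surface as ASCII STL
#'
#' @param surf An `aorta_surface`.
#' @param path Output file.
#' @export
write_stl <- function(surf, path) {
  geo <- triangle_geometry(surf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid neoaorta", con)
  v <- surf$vertices; tri <- surf$triangles
  for (i in seq_len(nrow(tri))) {
    n <- geo$normal[i, ]
    writeLines(c(
      sprintf("  facet normal %.6e %.6e %.6e", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.6e %.6e %.6e",
              v[tri[i, ], 1], v[tri[i, ], 2], v[tri[i, ], 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid neoaorta", con)
  invisible(path)
}

#' Write landmark annotations as JSON
#'
#' A flat map from landmark name to arclength (cm).
#'
#' @param landmarks Named numeric vector.
#' @param path Output file.
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(as.list(landmarks), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read landmark annotations from JSON
#'
#' @param path JSON file.
#' @return Named numeric vector of arclengths (cm).
#' @export
read_landmarks_json <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}
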