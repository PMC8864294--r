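#' Triangle mesh
#'
#' A surface mesh with \code{v x 3} vertex coordinates (mm) and 1-based
#' triangle indices. Optional per-vertex integer region labels travel with
#' the mesh (used for region-based pseudo-landmark filtering).
#'
#' @param vertices numeric \code{v x 3} matrix.
#' @param faces integer \code{f x 3} matrix of vertex indices (1-based).
#' @param regions optional per-vertex labels (character or factor,
#'   length \code{v}).
#' @return an object of class \code{cm_mesh}.
#' @export
cm_mesh <- function(vertices, faces, regions = NULL) {
  vertices <- as_landmarks(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop_cm("face indices out of range")
  if (!is.null(regions) && length(regions) != nrow(vertices))
    stop_cm("regions must have one label per vertex")
  structure(list(vertices = vertices, faces = faces,
                 regions = if (is.null(regions)) NULL else as.character(regions)),
            class = "cm_mesh")
}

#' @export
print.cm_mesh <- function(x, ...) {
  cat("Triangle mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces")
  if (!is.null(x$regions))
    cat(" | regions:", paste(names(table(x$regions)), collapse = ", "))
  cat("\n")
  invisible(x)
}

## Per-vertex unit normals by area-weighted averaging of face normals.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  out <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    out[, 1] <- out[, 1] + tabulate2(f[, j], fn[, 1], nrow(v))
    out[, 2] <- out[, 2] + tabulate2(f[, j], fn[, 2], nrow(v))
    out[, 3] <- out[, 3] + tabulate2(f[, j], fn[, 3], nrow(v))
  }
  nn <- row_norms(out)
  nn[nn < 1e-300] <- 1
  out / nn
}

tabulate2 <- function(idx, w, n) {
  as.numeric(rowsum(w, factor(idx, levels = seq_len(n)), reorder = TRUE))
}

## Bounding-box diagonal length.
bbox_diagonal <- function(points) {
  r <- apply(points, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

## Every edge of a closed (watertight) mesh is shared by exactly two faces.
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Read a PLY or OBJ mesh
#'
#' ASCII PLY (with an optional per-vertex integer \code{region} property)
#' and Wavefront OBJ are supported.
#'
#' @param path file path; format chosen by extension.
#' @return a [cm_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(read_ply(path))
  if (ext == "obj") return(read_obj(path))
  stop_cm("unsupported mesh format: ", ext)
}

#' Write a PLY or OBJ mesh
#'
#' @param mesh a [cm_mesh()].
#' @param path output path; \code{.ply} (ASCII, regions stored as an integer
#'   vertex property) or \code{.obj}.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "cm_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(write_ply(mesh, path))
  if (ext == "obj") return(write_obj(mesh, path))
  stop_cm("unsupported mesh format: ", ext)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ply")) stop_cm("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(lines))
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("format ascii", hdr))) stop_cm("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1", grep("element face", hdr, value = TRUE)[1]))
  vstart <- grep("element vertex", hdr)
  vend <- c(grep("element", hdr), hdr_end)
  vprops <- grep("^property ", trimws(hdr[(vstart + 1):hdr_end]), value = TRUE)
  vprops <- vprops[seq_len(which(!grepl("^property ", trimws(hdr[(vstart + 1):hdr_end])))[1] - 1)]
  pnames <- vapply(strsplit(vprops, "\\s+"), function(s) s[length(s)], "")
  body <- lines[(hdr_end + 1):length(lines)]
  vtab <- utils::read.table(text = body[seq_len(nv)], col.names = pnames,
                            colClasses = "numeric")
  verts <- as.matrix(vtab[, c("x", "y", "z")])
  regions <- NULL
  if ("region" %in% pnames) {
    regions <- as.character(vtab$region)
    lev_line <- grep("comment region_levels", hdr, value = TRUE)
    if (length(lev_line)) {
      lev <- strsplit(sub(".*region_levels ", "", lev_line[1]), " ")[[1]]
      regions <- lev[as.integer(vtab$region)]
    }
  }
  ftab <- utils::read.table(text = body[nv + seq_len(nf)])
  faces <- as.matrix(ftab[, 2:4]) + 1L
  cm_mesh(verts, faces, regions)
}

write_ply <- function(mesh, path) {
  has_reg <- !is.null(mesh$regions)
  reg_int <- if (has_reg) as.integer(factor(mesh$regions)) else NULL
  hdr <- c("ply", "format ascii 1.0",
           if (has_reg) paste0("comment region_levels ",
                               paste(levels(factor(mesh$regions)), collapse = " ")),
           paste("element vertex", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           if (has_reg) "property int region",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  vl <- if (has_reg)
    paste(format(mesh$vertices[, 1], digits = 17), format(mesh$vertices[, 2], digits = 17),
          format(mesh$vertices[, 3], digits = 17), reg_int)
  else
    paste(format(mesh$vertices[, 1], digits = 17), format(mesh$vertices[, 2], digits = 17),
          format(mesh$vertices[, 3], digits = 17))
  fl <- paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  atomic_write(c(hdr, vl, fl), path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(s) as.numeric(s[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(s)
    as.integer(sub("/.*", "", s[2:4]))))
  cm_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  vl <- paste("v", format(mesh$vertices[, 1], digits = 17),
              format(mesh$vertices[, 2], digits = 17),
              format(mesh$vertices[, 3], digits = 17))
  fl <- paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  atomic_write(c(vl, fl), path)
}

## Region levels comment round-trips factor codes back to label strings.
## (read_ply returns codes as characters when the comment is absent.)
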