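## Minimal NRRD reader/writer for label volumes and displacement fields.
## Supports ascii and raw (little-endian) encodings, axis-aligned geometry
## ("spacings" or diagonal "space directions", plus "space origin").

parse_nrrd_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
}

#' Read an NRRD volume
#'
#' Reads scalar volumes (label maps) and 3-component vector volumes
#' (displacement fields) with ascii or raw little-endian encoding and
#' axis-aligned geometry.
#'
#' @param path path to a \code{.nrrd} file.
#' @return a [label_volume()] for scalar data, or a [displacement_field()]
#'   when the file has a leading 3-component axis.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !nzchar(line)) break
    hdr <- c(hdr, line)
  }
  field <- function(name) {
    ln <- grep(paste0("^", name, ": ?"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", name, ": ?"), "", ln[1]))
  }
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  type <- field("type")
  encoding <- field("encoding")
  vector_data <- length(sizes) == 4
  grid_dim <- if (vector_data) sizes[2:4] else sizes
  spacing <- rep(1, 3); origin <- c(0, 0, 0)
  sd_line <- field("space directions")
  if (!is.null(sd_line)) {
    parts <- strsplit(sd_line, "\\s+")[[1]]
    parts <- parts[parts != "none"]
    dirs <- vapply(parts, parse_nrrd_vector, numeric(3))
    spacing <- vapply(1:3, function(j) dirs[j, j], 0)
  } else if (!is.null(field("spacings"))) {
    sp <- as.numeric(strsplit(field("spacings"), "\\s+")[[1]])
    spacing <- sp[!is.na(sp)][1:3]
  }
  if (!is.null(field("space origin"))) origin <- parse_nrrd_vector(field("space origin"))
  ntot <- prod(sizes)
  vals <- if (encoding == "ascii") {
    scan(con, what = double(), n = ntot, quiet = TRUE)
  } else if (encoding == "raw") {
    sz <- if (grepl("64|double", type)) 8L
          else if (grepl("32|^u?int$|^float$", type)) 4L
          else if (grepl("16|short", type)) 2L else 1L
    what <- if (grepl("float|double", type)) "double" else "integer"
    readBin(con, what, n = ntot, size = sz, endian = "little",
            signed = !(grepl("^u", type) && sz < 4))
  } else stop_cm("unsupported NRRD encoding: ", encoding)
  if (vector_data) {
    arr <- array(vals, dim = sizes)  # component fastest
    fld <- array(0, dim = c(grid_dim, 3))
    for (c3 in 1:3) fld[, , , c3] <- arr[c3, , , ]
    return(displacement_field(fld, spacing = spacing, origin = origin))
  }
  grid <- array(vals, dim = grid_dim)
  if (grepl("int|uchar|short|long", type)) storage.mode(grid) <- "integer"
  label_volume(grid, spacing = spacing, origin = origin)
}

#' Write an NRRD volume
#'
#' @param x a [label_volume()] or [displacement_field()].
#' @param path output path.
#' @param encoding \code{"ascii"} (text, default) or \code{"raw"}
#'   (little-endian binary).
#' @return the path, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  is_field <- inherits(x, "displacement_field")
  grid_dim <- dim(x$grid)[1:3]
  sp <- x$spacing
  dir_str <- paste(sprintf("(%.17g,%.17g,%.17g)",
                           c(sp[1], 0, 0), c(0, sp[2], 0), c(0, 0, sp[3])),
                   collapse = " ")
  hdr <- c("NRRD0004",
           paste0("type: ", if (is_field) "double" else "int"),
           paste0("dimension: ", if (is_field) 4L else 3L),
           "space: left-posterior-superior",
           paste0("sizes: ", paste(if (is_field) c(3L, grid_dim) else grid_dim,
                                   collapse = " ")),
           paste0("space directions: ", if (is_field) paste("none", dir_str) else dir_str),
           paste0("kinds: ", if (is_field) "vector domain domain domain"
                  else "domain domain domain"),
           "endian: little",
           paste0("encoding: ", encoding),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   x$origin[1], x$origin[2], x$origin[3]),
           "")
  vals <- if (is_field) {
    out <- array(0, dim = c(3, grid_dim))
    for (c3 in 1:3) out[c3, , , ] <- x$grid[, , , c3]
    as.numeric(out)
  } else as.numeric(x$grid)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "wb")
  writeLines(hdr, con)
  if (encoding == "ascii") {
    writeLines(paste(format(vals, digits = 17, trim = TRUE), collapse = " "), con)
  } else if (is_field) {
    writeBin(vals, con, size = 8L, endian = "little")
  } else {
    writeBin(as.integer(vals), con, size = 4L, endian = "little")
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}
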