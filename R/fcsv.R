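## FCSV (3D Slicer Markups fiducial) and plain-CSV landmark IO.
##
## Internal package coordinates are right-handed RAS millimetres. FCSV files
## declare their coordinate system in the header ("# CoordinateSystem = RAS"
## or "= LPS", or "= 0"/"= 1" in older files); LPS coordinates are converted
## by negating x and y on read and on write.

#' Read landmarks from an FCSV fiducial file
#'
#' Honors the \code{CoordinateSystem} header field (RAS or LPS; LPS
#' coordinates are converted to the package's RAS convention).
#'
#' @param path path to a \code{.fcsv} file.
#' @return a landmark configuration (\code{k x 3} matrix) with landmark
#'   labels as row names.
#' @export
read_fcsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cs_line <- grep("CoordinateSystem", hdr, value = TRUE)
  lps <- FALSE
  if (length(cs_line)) {
    cs <- trimws(sub(".*=", "", cs_line[1]))
    lps <- toupper(cs) %in% c("LPS", "0")
  }
  tab <- utils::read.csv(text = body, header = FALSE, stringsAsFactors = FALSE)
  pts <- as.matrix(tab[, 2:4])
  storage.mode(pts) <- "double"
  if (lps) pts[, 1:2] <- -pts[, 1:2]
  labels <- if (ncol(tab) >= 12) as.character(tab[[12]]) else NULL
  as_landmarks(pts, names = labels)
}

#' Write landmarks to an FCSV fiducial file
#'
#' @param config a landmark configuration.
#' @param path output path.
#' @param coordinate_system \code{"RAS"} (default) or \code{"LPS"}; the
#'   header records the choice and coordinates are converted accordingly.
#' @return the path, invisibly.
#' @export
write_fcsv <- function(config, path, coordinate_system = c("RAS", "LPS")) {
  config <- as_landmarks(config)
  coordinate_system <- match.arg(coordinate_system)
  pts <- config
  if (coordinate_system == "LPS") pts[, 1:2] <- -pts[, 1:2]
  labels <- rownames(config) %||% sprintf("LM_%d", seq_len(nrow(config)))
  hdr <- c("# Markups fiducial file version = 4.11",
           paste0("# CoordinateSystem = ", coordinate_system),
           "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  rows <- sprintf("vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,%s,,",
                  seq_len(nrow(pts)),
                  format(pts[, 1], digits = 17, trim = TRUE),
                  format(pts[, 2], digits = 17, trim = TRUE),
                  format(pts[, 3], digits = 17, trim = TRUE),
                  labels)
  atomic_write(c(hdr, rows), path)
}

#' Read a plain-CSV landmark table
#'
#' Long format with columns \code{specimen, landmark, x, y, z}; returns one
#' configuration per specimen.
#'
#' @param path path to the CSV file.
#' @return a named list of landmark configurations.
#' @export
read_landmark_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("specimen", "landmark", "x", "y", "z") %in% names(tab)))
  out <- lapply(split(tab, tab$specimen), function(d) {
    d <- d[order(d$landmark), ]
    as_landmarks(as.matrix(d[, c("x", "y", "z")]),
                 names = as.character(d$landmark))
  })
  out[unique(tab$specimen)]
}

#' Write configurations to a plain-CSV landmark table
#'
#' @param configs a named list of landmark configurations (or a single
#'   configuration).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_landmark_csv <- function(configs, path) {
  if (!is.list(configs)) configs <- list(specimen = configs)
  if (is.null(names(configs)))
    names(configs) <- sprintf("specimen_%d", seq_along(configs))
  rows <- lapply(names(configs), function(id) {
    m <- as_landmarks(configs[[id]])
    data.frame(specimen = id,
               landmark = rownames(m) %||% seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  lines <- c("specimen,landmark,x,y,z",
             sprintf("%s,%s,%s,%s,%s", tab$specimen, tab$landmark,
                     format(tab$x, digits = 17, trim = TRUE),
                     format(tab$y, digits = 17, trim = TRUE),
                     format(tab$z, digits = 17, trim = TRUE)))
  atomic_write(lines, path)
}
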