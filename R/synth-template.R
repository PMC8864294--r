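## Synthetic symmetric template: a skull-like closed surface built from a
## radially deformed ellipsoid with bilateral opercular lobes, a dorsal
## ridge (frontal/parietal analogs), an anterior-ventral jaw protrusion and
## a posterior-ventral pectoral-girdle bulge, labeled by region. The mesh is
## exactly symmetric across x = 0: vertices are computed for one side and
## mirrored bitwise onto the other.

template_features <- function() {
  norm3 <- function(v) v / sqrt(sum(v^2))
  list(
    operculum = list(dir = norm3(c(0.92, 0.15, -0.15)), amp = 0.30, sigma = 0.35,
                     bilateral = TRUE),
    frontal = list(dir = norm3(c(0, 0.45, 0.89)), amp = 0.18, sigma = 0.30,
                   bilateral = FALSE),
    parietal = list(dir = norm3(c(0, -0.45, 0.89)), amp = 0.12, sigma = 0.30,
                    bilateral = FALSE),
    jaws = list(dir = norm3(c(0, 0.85, -0.52)), amp = 0.25, sigma = 0.30,
                bilateral = FALSE),
    pectoral_girdle = list(dir = norm3(c(0, -0.85, -0.52)), amp = 0.20,
                           sigma = 0.30, bilateral = FALSE))
}

## Radial bump profile evaluated at unit directions (rows of d); uses |dx|
## so the value is exactly mirror-symmetric.
template_radius <- function(d, axes = c(1.5, 2.5, 1.2)) {
  base <- 1 / sqrt((d[, 1] / axes[1])^2 + (d[, 2] / axes[2])^2 + (d[, 3] / axes[3])^2)
  dm <- cbind(abs(d[, 1]), d[, 2], d[, 3])
  bump <- rep(0, nrow(d))
  for (ft in template_features()) {
    dist2 <- rowSums(sweep(dm, 2, ft$dir)^2)
    bump <- bump + ft$amp * exp(-dist2 / (2 * ft$sigma^2))
  }
  base * (1 + bump)
}

template_region_of <- function(d) {
  dm <- cbind(abs(d[, 1]), d[, 2], d[, 3])
  ft <- template_features()
  lab <- rep("cranium", nrow(d))
  near <- function(dir, r) rowSums(sweep(dm, 2, dir)^2) < r^2
  lab[near(ft$frontal$dir, 0.55)] <- "frontal"
  lab[near(ft$parietal$dir, 0.55)] <- "parietal"
  lab[near(ft$operculum$dir, 0.55)] <- "operculum"
  lab[near(ft$jaws$dir, 0.50)] <- "jaws"
  lab[near(ft$pectoral_girdle$dir, 0.48)] <- "pectoral_girdle"
  lab
}

#' Synthetic symmetric template mesh
#'
#' Builds the closed, watertight, skull-like template surface used by the
#' synthetic study: a radially deformed ellipsoid (semi-axes 1.5 x 2.5 x
#' 1.2 mm; +y anterior, +z dorsal, x lateral) with bilateral opercular
#' lobes, frontal and parietal dorsal ridges, a jaw protrusion and a
#' pectoral-girdle bulge, each vertex labeled by region. Exactly symmetric
#' across \code{x = 0} by construction: one half is computed and mirrored.
#'
#' @param n_theta number of latitude rows (excluding the poles).
#' @param n_phi number of longitude columns (even).
#' @return a [cm_mesh()] with \code{regions}, plus fields
#'   \code{mirror_index} (the vertex permutation realized by the mirror)
#'   and \code{plane} (the sagittal [symmetry_plane()]).
#' @export
make_template_mesh <- function(n_theta = 47L, n_phi = 96L) {
  stopifnot(n_phi %% 2 == 0)
  nv <- n_theta * n_phi + 2L
  verts <- matrix(0, nv, 3)
  dirs <- matrix(0, nv, 3)
  vid <- function(i, j) (i - 1L) * n_phi + (j %% n_phi) + 1L
  theta <- pi * seq_len(n_theta) / (n_theta + 1)
  for (i in seq_len(n_theta)) {
    for (j in 0:(n_phi %/% 2)) {
      phi <- 2 * pi * j / n_phi
      d <- c(sin(theta[i]) * sin(phi), sin(theta[i]) * cos(phi), cos(theta[i]))
      if (j == 0 || j == n_phi %/% 2) d[1] <- 0  # exact midline
      dirs[vid(i, j), ] <- d
    }
    for (j in (n_phi %/% 2 + 1):(n_phi - 1)) {
      d <- dirs[vid(i, n_phi - j), ]
      dirs[vid(i, j), ] <- c(-d[1], d[2], d[3])
    }
  }
  np <- n_theta * n_phi + 1L; sp <- np + 1L
  dirs[np, ] <- c(0, 0, 1); dirs[sp, ] <- c(0, 0, -1)
  r <- template_radius(dirs)
  verts <- dirs * r
  ## bitwise mirror symmetry: copy the x > 0 half onto the x < 0 half
  for (i in seq_len(n_theta)) {
    for (j in (n_phi %/% 2 + 1):(n_phi - 1)) {
      src <- vid(i, n_phi - j)
      verts[vid(i, j), ] <- c(-verts[src, 1], verts[src, 2], verts[src, 3])
    }
  }
  faces <- matrix(0L, 2L * n_phi * (n_theta - 1L) + 2L * n_phi, 3)
  fi <- 0L
  for (j in 0:(n_phi - 1L)) {
    fi <- fi + 1L
    faces[fi, ] <- c(np, vid(1L, j), vid(1L, j + 1L))
  }
  for (i in seq_len(n_theta - 1L)) {
    for (j in 0:(n_phi - 1L)) {
      a <- vid(i, j); b <- vid(i, j + 1L)
      c2 <- vid(i + 1L, j); d2 <- vid(i + 1L, j + 1L)
      faces[fi + 1L, ] <- c(a, c2, b)
      faces[fi + 2L, ] <- c(b, c2, d2)
      fi <- fi + 2L
    }
  }
  for (j in 0:(n_phi - 1L)) {
    fi <- fi + 1L
    faces[fi, ] <- c(sp, vid(n_theta, j + 1L), vid(n_theta, j))
  }
  mirror_index <- integer(nv)
  for (i in seq_len(n_theta)) for (j in 0:(n_phi - 1L))
    mirror_index[vid(i, j)] <- vid(i, (n_phi - j) %% n_phi)
  mirror_index[np] <- np; mirror_index[sp] <- sp
  mesh <- cm_mesh(verts, faces, regions = template_region_of(dirs))
  mesh$mirror_index <- mirror_index
  mesh$plane <- symmetry_plane(c(0, 0, 0), c(1, 0, 0))
  mesh
}

#' Deterministic manual-landmark sites on the template
#'
#' Chooses \code{k} well-spread template vertices (farthest-point sampling
#' from a fixed start) to serve as the synthetic analog of a manual
#' landmarking scheme.
#'
#' @param template a [make_template_mesh()] result.
#' @param k number of landmarks.
#' @return integer vector of vertex indices.
#' @export
template_landmark_sites <- function(template, k = 23L) {
  v <- template$vertices
  sel <- which.max(v[, 2])  # anterior-most vertex: a stable start
  mind <- sqrt(rowSums(sweep(v, 2, v[sel, ])^2))
  while (length(sel) < k) {
    i <- which.max(mind)
    sel <- c(sel, i)
    mind <- pmin(mind, sqrt(rowSums(sweep(v, 2, v[i, ])^2)))
  }
  sel
}
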