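#' Ellipsoid STN model
#'
#' Analytic stand-in for the subthalamic nucleus in right-hemisphere
#' MNI-like coordinates (x lateral+, y anterior+, z superior+), with a
#' planar tripartite partition (posterior motor, central associative,
#' anterior limbic) along the local anterior axis. Default center and
#' literature-scale semi-axes place the nucleus at the usual right-STN
#' location; this synthetic geometry ships for testing and does not
#' redistribute any atlas.
#'
#' @param center 3-vector, mm.
#' @param semi_axes 3-vector (a, b, c), mm.
#' @param rotation 3x3 rotation matrix mapping local to world axes.
#' @param partition_frac fractions of the anterior semi-axis at which the
#'   motor/associative and associative/limbic planes sit.
#' @return An object of class `stn_model` (ellipsoid variant).
#' @export
stn_ellipsoid <- function(center = c(12, -13, -7), semi_axes = c(3, 5, 3.5),
                          rotation = diag(3), partition_frac = c(0.15, 0.65)) {
  stopifnot(length(center) == 3, length(semi_axes) == 3, all(semi_axes > 0))
  structure(list(kind = "ellipsoid", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), rotation = rotation,
                 partition_frac = partition_frac),
            class = "stn_model")
}

#' Triangulated-mesh STN model
#'
#' @param meshes named list (motor, associative, limbic) of closed
#'   triangulated surfaces, each a list with `vertices` (n x 3, mm) and
#'   `faces` (m x 3, 1-based vertex indices).
#' @return An object of class `stn_model` (mesh variant).
#' @export
stn_mesh <- function(meshes) {
  stopifnot(is.list(meshes), length(meshes) >= 1, !is.null(names(meshes)))
  for (m in meshes) stopifnot(ncol(m$vertices) == 3, ncol(m$faces) == 3)
  structure(list(kind = "mesh", meshes = meshes), class = "stn_model")
}

## Local (ellipsoid-frame) coordinates of world points (n x 3 matrix).
.ellipsoid_local <- function(model, pts) {
  sweep(pts, 2, model$center) %*% model$rotation
}

## Even-odd ray-casting containment for a closed triangulated mesh.
## Ray direction is fixed; robust enough for the well-behaved closed
## surfaces this package handles.
.point_in_mesh <- function(mesh, pts) {
  v <- mesh$vertices; f <- mesh$faces
  dir <- c(0.57735027, 0.57735027, 0.57735027)
  p0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p0
  e2 <- v[f[, 3], , drop = FALSE] - p0
  ## Moeller-Trumbore, vectorized over faces per query point
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  apply(pts, 1, function(p) {
    s <- sweep(p0, 2, p, `-`) * -1
    u <- rowSums(s * h) / a
    q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
               s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
               s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
    tt <- rowSums(e2 * q) / a
    hit <- ok & u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9
    (sum(hit) %% 2L) == 1L
  })
}

#' Test points for STN containment and subregion membership
#'
#' For the ellipsoid model containment is analytic
#' ((x/a)^2 + (y/b)^2 + (z/c)^2 <= 1 in the local frame) and the
#' subregion is read off the planar partition of the local anterior
#' axis. For the mesh model containment uses ray-casting
#' (in-triangulation) against each subregion surface.
#'
#' @param model an `stn_model`.
#' @param pts n x 3 matrix of world coordinates, mm.
#' @return data.frame with columns `inside` (logical) and `subregion`
#'   (one of motor/associative/limbic/outside).
#' @export
stn_contains <- function(model, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (model$kind == "ellipsoid") {
    loc <- .ellipsoid_local(model, pts)
    r2 <- (loc[, 1] / model$semi_axes[1])^2 + (loc[, 2] / model$semi_axes[2])^2 +
      (loc[, 3] / model$semi_axes[3])^2
    inside <- r2 <= 1
    y <- loc[, 2]
    b <- model$semi_axes[2]
    sub <- ifelse(!inside, "outside",
                  ifelse(y <= model$partition_frac[1] * b, "motor",
                         ifelse(y <= model$partition_frac[2] * b, "associative", "limbic")))
  } else {
    sub <- rep("outside", nrow(pts))
    inside <- rep(FALSE, nrow(pts))
    for (nm in names(model$meshes)) {
      hit <- .point_in_mesh(model$meshes[[nm]], pts)
      take <- hit & !inside
      inside <- inside | hit
      sub[take] <- nm
    }
  }
  data.frame(inside = inside, subregion = sub, stringsAsFactors = FALSE)
}

#' Triangulate an ellipsoid into a closed mesh
#'
#' Convenience for exercising the mesh containment path against the
#' analytic ellipsoid oracle.
#'
#' @param model ellipsoid `stn_model`.
#' @param n_theta,n_phi angular resolution.
#' @return list with `vertices`, `faces`.
#' @export
ellipsoid_mesh <- function(model, n_theta = 24, n_phi = 48) {
  stopifnot(model$kind == "ellipsoid")
  th <- seq(0, pi, length.out = n_theta)[-c(1, n_theta)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(th = th, ph = ph)
  unit <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  verts <- rbind(c(0, 0, 1), unit, c(0, 0, -1))
  verts <- sweep(verts %*% diag(model$semi_axes) %*% t(model$rotation), 2,
                 model$center, `+`)
  nt <- n_theta - 2
  idx <- function(i, j) 1L + (j - 1L) * nt + i  # ring i (1..nt), azimuth j (1..n_phi)
  faces <- list()
  for (j in seq_len(n_phi)) {
    j2 <- if (j == n_phi) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(1L, idx(1, j), idx(1, j2))            # north cap
    faces[[length(faces) + 1L]] <- c(nrow(verts), idx(nt, j2), idx(nt, j)) # south cap
    for (i in seq_len(nt - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j2))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j2), idx(i, j2))
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Generate a directional-lead contact geometry through the STN
#'
#' Emulates an 8-contact directional DBS lead (Cartesia-style layout
#' approximated as point contacts): from the tip upward, one ring, two
#' levels of three 120-degree segments offset 0.66 mm radially, and a top
#' ring; 2 mm center-to-center level spacing along a jittered linear
#' trajectory aimed at the STN. Trajectories are re-drawn until at least
#' two contacts fall inside the STN, mirroring the cohort inclusion rule.
#'
#' @param stn_model an `stn_model`.
#' @param seed integer RNG seed (deterministic geometry).
#' @param target_jitter_mm SD of the tip-position jitter (default 1).
#' @param entry_jitter SD of the per-axis direction jitter (default 0.12).
#' @param max_retries bounded rejection sampling (default 100).
#' @return data.frame of 8 contact records: `contact_id` (0-7), `x`, `y`,
#'   `z` (mm), `is_ring`, `inside_stn`, `subregion`.
#' @export
make_lead_geometry <- function(stn_model, seed, target_jitter_mm = 1,
                               entry_jitter = 0.12, max_retries = 100) {
  with_seed(seed, {
    anchor <- if (stn_model$kind == "ellipsoid") stn_model$center else
      colMeans(stn_model$meshes[[1]]$vertices)
    for (try in seq_len(max_retries)) {
      u <- c(0.2, 0.3, 1) + rnorm(3, 0, entry_jitter)
      u <- u / sqrt(sum(u^2))                      # along-lead, pointing superior
      tip <- anchor - 3 * u + rnorm(3, 0, target_jitter_mm)
      ## orthonormal frame for segment offsets, random azimuth
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      az0 <- runif(1, 0, 2 * pi)
      seg_dir <- function(az) cos(az) * e1 + sin(az) * e2
      pos <- matrix(NA_real_, 8, 3)
      pos[1, ] <- tip                              # bottom ring
      k <- 2
      for (lev in 1:2) {
        base <- tip + 2 * lev * u
        for (s in 0:2) {
          pos[k, ] <- base + 0.66 * seg_dir(az0 + 2 * pi * s / 3)
          k <- k + 1
        }
      }
      pos[8, ] <- tip + 6 * u                      # top ring
      cls <- stn_contains(stn_model, pos)
      if (sum(cls$inside) >= 2) {
        return(data.frame(contact_id = 0:7,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          is_ring = c(TRUE, rep(FALSE, 6), TRUE),
                          inside_stn = cls$inside, subregion = cls$subregion,
                          stringsAsFactors = FALSE))
      }
    }
    stopf("make_lead_geometry: no trajectory with >= 2 inside-STN contacts after %d retries; geometry config inconsistent", max_retries)
  })
}
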