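# Pose state vector: rigid-body translation + unit-quaternion orientation +
# one dihedral per rotatable bond, applied to the molecule's torsion tree.

#' Construct a pose
#'
#' @param translation target position of the root rigid fragment's centroid
#'   (Angstrom, length-3).
#' @param orientation unit quaternion `c(w, x, y, z)` rotating the molecule
#'   about that centroid.
#' @param torsions dihedral offsets, degrees in `(-180, 180]`, one per branch
#'   of the torsion tree.
#' @return object of class `Pose`.
#' @export
new_pose <- function(translation = c(0, 0, 0), orientation = c(1, 0, 0, 0),
                     torsions = numeric(0)) {
  q <- orientation / sqrt(sum(orientation^2))
  tor <- ((torsions + 180) %% 360) - 180
  tor[tor == -180] <- 180
  p <- list(translation = as.numeric(translation), orientation = q,
            torsions = tor, score = NULL)
  class(p) <- "Pose"
  p
}

#' The identity pose: reproduces the molecule's stored coordinates exactly
#' @param mol a `Molecule` with a torsion tree.
#' @export
identity_pose <- function(mol) {
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  root <- mol$torsion_tree$root_atoms
  cen <- colMeans(coords(mol)[root, , drop = FALSE])
  new_pose(translation = cen, torsions = rep(0, length(mol$torsion_tree$branches)))
}

#' @export
print.Pose <- function(x, ...) {
  cat(sprintf("Pose: t = (%.2f, %.2f, %.2f), %d torsion(s)%s\n",
              x$translation[1], x$translation[2], x$translation[3],
              length(x$torsions),
              if (!is.null(x$score)) sprintf(", dG = %.3f", x$score$total) else ""))
  invisible(x)
}

# -- quaternion utilities ---------------------------------------------------

#' @noRd
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @noRd
quat_from_axis_angle <- function(axis, angle_deg) {
  ax <- unit3(axis)
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * ax)
}

#' @noRd
quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' @noRd
random_unit_quat <- function() {
  # uniform over SO(3) (Shoemake)
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))[c(2, 1, 3, 4)]
}

# rotate points (n x 3) about the origin
#' @noRd
rotate_points <- function(xyz, q) {
  xyz %*% t(quat_rotation_matrix(q))
}

# Rodrigues rotation of points about an axis through `origin`
#' @noRd
rotate_about_axis <- function(xyz, origin, axis, angle_deg) {
  u <- unit3(axis)
  th <- angle_deg * pi / 180
  p <- sweep(xyz, 2, origin)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(p %*% t(R), 2, origin, "+")
}

#' Realize Cartesian coordinates of a pose
#'
#' Branch torsion offsets are applied to the molecule's stored conformation
#' (branches closest to the root first), then the whole molecule is rotated
#' about the root-fragment centroid by the pose quaternion and translated so
#' that centroid lands on `pose$translation`.
#'
#' @param mol a `Molecule` with torsion tree built.
#' @param pose a `Pose`.
#' @return n x 3 coordinate matrix.
#' @export
realize_pose <- function(mol, pose) {
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  xyz <- coords(mol)
  br <- mol$torsion_tree$branches
  if (length(pose$torsions) != length(br)) {
    stop("pose has ", length(pose$torsions), " torsions; molecule has ",
         length(br), " rotatable bonds")
  }
  for (k in seq_along(br)) {
    ang <- pose$torsions[k]
    if (ang == 0) next
    b <- br[[k]]$bond
    xyz[br[[k]]$moved, ] <- rotate_about_axis(
      xyz[br[[k]]$moved, , drop = FALSE], xyz[b[1], ], xyz[b[2], ] - xyz[b[1], ], ang)
  }
  root <- mol$torsion_tree$root_atoms
  cen <- colMeans(xyz[root, , drop = FALSE])
  xyz <- rotate_points(sweep(xyz, 2, cen), pose$orientation)
  sweep(xyz, 2, pose$translation, "+")
}

#' Symmetry-aware heavy-atom RMSD between two poses of one molecule
#'
#' Coordinates are realized for both poses and compared over heavy atoms;
#' the minimum RMSD over graph automorphisms that preserve elements (e.g.
#' a benzene ring flip) is returned. Automorphism enumeration is capped for
#' highly symmetric graphs.
#'
#' @param mol a `Molecule`.
#' @param pose_a,pose_b `Pose`s (or n x 3 coordinate matrices).
#' @param max_maps automorphism cap.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(mol, pose_a, pose_b, max_maps = 500) {
  xa <- if (is.matrix(pose_a)) pose_a else realize_pose(mol, pose_a)
  xb <- if (is.matrix(pose_b)) pose_b else realize_pose(mol, pose_b)
  if (nrow(xa) != nrow(xb) || nrow(xa) != nrow(mol$atoms)) {
    stop("atom-count mismatch between poses and molecule")
  }
  heavy <- which(mol$atoms$element != "H")
  maps <- molecule_automorphisms(mol, max_maps)
  best <- Inf
  for (perm in maps) {
    d <- xa[heavy, , drop = FALSE] - xb[perm[heavy], , drop = FALSE]
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}

# element-preserving graph automorphisms (list of permutation vectors,
# identity always first)
#' @noRd
molecule_automorphisms <- function(mol, max_maps = 500) {
  n <- nrow(mol$atoms)
  ident <- list(seq_len(n))
  if (nrow(mol$bonds) == 0 || n > 200) return(ident)
  g <- mol_graph(mol)
  col <- as.integer(factor(mol$atoms$element))
  maps <- tryCatch(
    igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = col,
                                       vertex.color2 = col),
    error = function(e) NULL)
  if (is.null(maps) || length(maps) == 0) return(ident)
  if (length(maps) > max_maps) maps <- maps[seq_len(max_maps)]
  out <- lapply(maps, function(m) as.integer(m))
  # make sure identity is included
  if (!any(vapply(out, function(p) all(p == seq_len(n)), logical(1)))) {
    out <- c(ident, out)
  }
  out
}

# seed-scoped RNG: evaluate fn under a deterministic seed without touching
# the caller's RNG stream
#' @noRd
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}
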