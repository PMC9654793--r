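# shared fixtures built in code

PARAMS <- default_parameters()

mol_water <- function() {
  molecule(data.frame(element = c("O", "H", "H"),
                      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0),
           data.frame(i = c(1, 1), j = c(2, 3), order = 1), "water")
}

# heavy-atom benzene (kekulized)
mol_benzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  molecule(data.frame(element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0),
           data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
           "benzene")
}

mol_butane <- function() {
  molecule(data.frame(element = "C",
                      x = c(0, 1.53, 2.2, 3.7), y = c(0, 0, 1.35, 1.4), z = 0),
           data.frame(i = 1:3, j = 2:4, order = 1), "butane")
}

mol_ethylbenzene <- function() {
  b <- mol_benzene()
  atoms <- rbind(b$atoms[, c("element", "x", "y", "z")],
                 data.frame(element = "C", x = c(2.9, 3.6), y = c(0, 1.3), z = 0))
  bonds <- rbind(b$bonds, data.frame(i = c(1, 7), j = c(7, 8), order = 1))
  molecule(atoms, bonds, "ethylbenzene")
}

mol_methanol <- function() {
  molecule(data.frame(element = c("C", "O", "H", "H", "H", "H"),
                      x = c(0, 1.43, -0.5, -0.5, -0.5, 1.8),
                      y = c(0, 0, 0.9, -0.9, 0, 0.8),
                      z = c(0, 0, 0, 0, 1, 0)),
           data.frame(i = c(1, 2, 1, 1, 1), j = c(2, 6, 3, 4, 5), order = 1),
           "methanol")
}

# one-atom receptor for single-pair checks
single_atom_receptor <- function(params = PARAMS, element = "C") {
  rec <- hingedock:::new_receptor(data.frame(
    element = element, name = "P01", resname = "POC", resno = 1L, chain = "A",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  type_receptor(rec, params)
}

quat_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply one rigid transform (unit quaternion g + shift t) to receptor and pose
transform_complex <- function(rec, pose, g, t) {
  R <- quat_rotmat(g)
  xyz <- as.matrix(rec$atoms[, c("x", "y", "z")]) %*% t(R)
  rec$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, t, "+")
  rec$polar <- NULL  # recomputed on demand from the moved coordinates
  q2 <- hingedock:::quat_mul(g, pose$orientation)
  pose2 <- new_pose(translation = as.numeric(R %*% pose$translation) + t,
                    orientation = q2, torsions = pose$torsions)
  list(rec = rec, pose = pose2)
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "hingedock")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}
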