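# Rotation and direction-vector helpers shared by the generator and the
# preprocessing chain. World frame: right-handed, y up, +z from the player
# toward the front wall, x to the player's right.

#' Convert yaw/pitch angles to a unit direction vector
#'
#' Yaw is rotation about the vertical (y) axis, zero along +z, positive toward
#' +x. Pitch is the elevation above the horizontal plane, positive upward.
#'
#' @param yaw,pitch Angles in degrees.
#' @return A numeric matrix with columns x, y, z of unit vectors.
#' @export
angles_to_dir <- function(yaw, pitch) {
  y <- yaw * pi / 180
  p <- pitch * pi / 180
  cbind(x = cos(p) * sin(y), y = sin(p), z = cos(p) * cos(y))
}

#' Convert direction vectors to yaw/pitch angles
#'
#' @param v A length-3 vector or an n x 3 matrix of direction vectors
#'   (need not be unit length).
#' @return A data.frame with columns \code{yaw} and \code{pitch} in degrees.
#' @export
dir_to_angles <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  yaw <- atan2(v[, 1L], v[, 3L]) * 180 / pi
  pitch <- atan2(v[, 2L], sqrt(v[, 1L]^2 + v[, 3L]^2)) * 180 / pi
  data.frame(yaw = yaw, pitch = pitch)
}

# Rotation matrix about the y axis (yaw) and x axis.
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

# Rotation taking the head-frame forward axis (+z) to the direction given by
# (yaw, pitch): R = Ry(yaw) %*% Rx(-pitch).
look_rotation <- function(yaw, pitch) rot_y(yaw) %*% rot_x(-pitch)

#' Convert a rotation matrix to a unit quaternion (w, x, y, z)
#' @param R 3x3 rotation matrix.
#' @return Numeric length-4 quaternion.
#' @export
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L
    k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4L)
    q[1L] <- (R[k, j] - R[j, k]) / s
    q[i + 1L] <- 0.25 * s
    q[j + 1L] <- (R[j, i] + R[i, j]) / s
    q[k + 1L] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Convert a unit quaternion (w, x, y, z) to a rotation matrix
#' @param q Numeric length-4 quaternion.
#' @return 3x3 rotation matrix.
#' @export
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L)
}

#' Great-circle angle between direction vectors
#'
#' @param u,v Length-3 vectors or n x 3 matrices (rowwise pairs).
#' @return Angular separation in degrees.
#' @export
great_circle_deg <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3L)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  dot <- rowSums(u * v)
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  atan2(sqrt(rowSums(cr^2)), dot) * 180 / pi
}

# Spherical linear interpolation between unit vectors u and v at fractions f.
slerp <- function(u, v, f) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  ang <- atan2(sqrt(sum(crossprod_vec(u, v)^2)), sum(u * v))
  if (ang < 1e-9) return(matrix(u, nrow = length(f), ncol = 3L, byrow = TRUE))
  s <- sin(ang)
  a <- sin((1 - f) * ang) / s
  b <- sin(f * ang) / s
  cbind(a * u[1L] + b * v[1L], a * u[2L] + b * v[2L], a * u[3L] + b * v[3L])
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}
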