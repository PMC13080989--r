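# Rigid-body geometry utilities: rotations, superposition, sphere sampling.

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for angle theta (radians) about unit axis (Rodrigues).
rotation_about_axis <- function(axis, theta) {
  u <- unit_vec(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Orthonormal right-handed frame with x along `x_dir` and y toward `y_hint`.
build_frame <- function(x_dir, y_hint = NULL) {
  x <- unit_vec(x_dir)
  if (is.null(y_hint)) {
    y_hint <- if (abs(x[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  y <- y_hint - sum(y_hint * x) * x
  if (sqrt(sum(y^2)) < 1e-8) {
    y_hint <- if (abs(x[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    y <- y_hint - sum(y_hint * x) * x
  }
  y <- unit_vec(y)
  z <- cross3(x, y)
  cbind(x, y, z)
}

# Kabsch least-squares superposition: rotation R and translation t such
# that R %*% t(src) + t best matches ref (rows are points).
kabsch <- function(src, ref) {
  cs <- colMeans(src)
  cr <- colMeans(ref)
  A <- t(sweep(src, 2, cs)) %*% sweep(ref, 2, cr)
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cs)
  list(R = R, t = t_vec)
}

apply_rigid <- function(xyz, R, t_vec) {
  sweep(xyz %*% t(R), 2, t_vec, `+`)
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Uniform random rotation matrix (Arvo/Shoemake, driven by R's RNG).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Minimum pairwise vdW-scaled separation between two coordinate sets.
# Returns the most negative (distance - factor * vdw_sum); >= 0 means no
# clash. `exclude` is an optional 2-column matrix of (i, j) pairs to skip.
clash_score <- function(xyzA, elemA, xyzB, elemB,
                        factor = mf_clash_factor(), exclude = NULL) {
  if (nrow(xyzA) == 0L || nrow(xyzB) == 0L) return(Inf)
  rA <- vdw_radii(elemA)
  rB <- vdw_radii(elemB)
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) - 2 * xyzA %*% t(xyzB)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  lim <- factor * outer(rA, rB, `+`)
  marg <- dmat - lim
  if (!is.null(exclude) && nrow(exclude) > 0) {
    marg[exclude] <- Inf
  }
  min(marg)
}
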