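# shared fixtures and independent oracles for the test suite

# random proper rotation, independent of the package internals
test_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qd <- qr(m)
  q <- qr.Q(qd) %*% diag(sign(diag(qr.R(qd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion (or any affine map) to all atoms of a pose
transform_pose <- function(pose, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  pose$atoms$x <- xyz[, 1]
  pose$atoms$y <- xyz[, 2]
  pose$atoms$z <- xyz[, 3]
  pose
}

# mirror through the yz-plane (improper transformation: flips chirality)
mirror_pose <- function(pose) {
  pose$atoms$x <- -pose$atoms$x
  pose
}

# independent bisection oracle for the product ee solving the Chen-Sih
# relation at given conversion and E (200 halvings ~ 2^-200 bracket)
bisect_ee <- function(conversion, e) {
  lo <- 0
  hi <- min(1, 1 / conversion - 1) - 1e-9
  f <- function(ee) {
    log(1 - conversion * (1 + ee)) / log(1 - conversion * (1 - ee)) - e
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# docking records mirroring the bundled OxdRE reference scores
reference_docking <- function() {
  read_docking_table(oxdock_example("oxdre_docking_scores.tsv"))
}

reference_observations <- function() {
  read_resolution_table(oxdock_example("oxdre_wt_biotransformations.tsv"))
}
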