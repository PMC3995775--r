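# Shared fixtures: built in code, no stored data.

# uniform random rotation matrix (independent of the package's internals)
rand_rotation <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  rx <- rbind(
    c(1, 0, 0),
    c(0, cos(th[1]), -sin(th[1])),
    c(0, sin(th[1]), cos(th[1]))
  )
  ry <- rbind(
    c(cos(th[2]), 0, sin(th[2])),
    c(0, 1, 0),
    c(-sin(th[2]), 0, cos(th[2]))
  )
  rz <- rbind(
    c(cos(th[3]), -sin(th[3]), 0),
    c(sin(th[3]), cos(th[3]), 0),
    c(0, 0, 1)
  )
  rz %*% ry %*% rx
}

# apply a rigid motion to a long landmark table
transform_landmarks <- function(landmarks, rotation, translation = c(0, 0, 0)) {
  m <- as.matrix(landmarks[, c("x", "y", "z")]) %*% t(rotation)
  m <- sweep(m, 2, translation, "+")
  landmarks$x <- m[, 1]
  landmarks$y <- m[, 2]
  landmarks$z <- m[, 3]
  landmarks
}

# one complete synthetic shoulder as a landmark table
fixture_shoulder <- function(vault = 9.7, offset = 3.5, inclination = 12, ...) {
  build_shoulder(vault, offset, inclination_deg = inclination, ...)$landmarks
}

# named coordinate matrix for one shoulder
fixture_points <- function(...) {
  lm <- fixture_shoulder(...)
  m <- as.matrix(lm[, c("x", "y", "z")])
  rownames(m) <- lm$landmark
  m
}
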