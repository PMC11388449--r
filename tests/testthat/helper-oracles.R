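# Independent oracles, deliberately coded apart from the package's
# vectorized / log-sum-exp implementations: plain loops, direct weights.

# brute-force average protonation by explicit microstate loops
brute_force_titration <- function(model, ph_values) {
  n <- nrow(model$sites)
  states <- expand.grid(rep(list(0:1), n))
  prot <- matrix(0, length(ph_values), n)
  for (pi in seq_along(ph_values)) {
    G <- numeric(nrow(states))
    for (k in seq_len(nrow(states))) {
      s <- as.numeric(states[k, ])
      q <- ifelse(model$sites$polarity == "anionic", s - 1, s)
      e <- sum(s * (ph_values[pi] - model$sites$pkint))
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        e <- e + model$w[i, j] * q[i] * q[j]
      G[k] <- e
    }
    wgt <- 10^(-(G - min(G)))       # shift only, direct base-10 weights
    for (i in seq_len(n))
      prot[pi, i] <- sum(wgt * states[[i]]) / sum(wgt)
  }
  prot
}

# independent signed dihedral: angle between plane normals, sign from the
# triple product of (n1, n2, axis)
ref_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2]*v[3] - u[3]*v[2],
                            u[3]*v[1] - u[1]*v[3],
                            u[1]*v[2] - u[2]*v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# random interacting-site model; coupling scale ~ typical site-site
# charge-charge couplings (|w| <= 1 pK unit)
random_model <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, -1, 1)
  w <- w + t(w)
  titration_model(
    data.frame(id = paste0("s", seq_len(n)),
               pkint = stats::runif(n, 2, 12),
               polarity = sample(c("anionic", "cationic"), n, TRUE),
               stringsAsFactors = FALSE), w)
}

single_site_model <- function(pkint, id = "Asp2.50",
                              polarity = "anionic") {
  titration_model(data.frame(id = id, pkint = pkint, polarity = polarity,
                             stringsAsFactors = FALSE))
}

# random rigid transform of a structure_frame (rotation + translation)
rigid_transform <- function(frame, seed) {
  set.seed(seed)
  a <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  shift <- stats::runif(3, -20, 20)
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(R)
  frame$atoms$x <- xyz[, 1] + shift[1]
  frame$atoms$y <- xyz[, 2] + shift[2]
  frame$atoms$z <- xyz[, 3] + shift[3]
  frame
}
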