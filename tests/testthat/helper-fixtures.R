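# Shared test helpers: dimer construction and random rigid motions.

# Two copies of a solute separated along x; the far copy is an exact
# translate so surface tessellations of the monomers are congruent.
make_dimer <- function(s, shift = 50) {
  coords2 <- sweep(s$coords, 2, c(shift, 0, 0), "+")
  solute(c(s$elements, s$elements), rbind(s$coords, coords2),
         c(s$charges, s$charges), 2L * s$total_charge,
         name = paste0(s$name, "-dimer"))
}

# Zero out the partial charges of a solute (neutral, chargeless variant).
strip_charges <- function(s) {
  solute(s$elements, s$coords, rep(0, length(s$elements)), 0L,
         name = paste0(s$name, "-q0"))
}

# Uniformly random rotation matrix (QR of a Gaussian matrix).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid motion (rotation + translation) to a solute.
rigid_motion <- function(s, R = random_rotation(),
                         t = runif(3, -20, 20)) {
  solute(s$elements, sweep(s$coords %*% t(R), 2, t, "+"), s$charges,
         s$total_charge, name = s$name)
}
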