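# Independent brute-force torsion: project the outer bond vectors onto the
# plane normal to the central bond and take the signed angle between the
# projections. Shares no code with the package's triple-product formula.

oracle_torsion <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  bh <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * bh) * bh
  w <- (p4 - p3) - sum((p4 - p3) * bh) * bh
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  a <- atan2(sum(cr * bh), sum(u * w)) * 180 / pi
  if (a <= -180) a + 360 else a
}

random_quadruple <- function() {
  matrix(runif(12, -10, 10), nrow = 4)
}

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

descriptor_of <- function(generated, ...) {
  compute_descriptor(extract_joints(generated$trace, generated$annotation),
                     ...)
}
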