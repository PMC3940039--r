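# Independent oracle implementations and small fixture builders used across
# the test files.  These deliberately avoid the package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# rank-2 spherical-harmonic contraction oracle for the methyl-jump rate:
# (4*pi/5) * (1/9) * sum_m | sum_i Y_2m(Omega_i) / r_i^3 |^2
# equals (1/18) sum_ij [3 cos^2(theta_ij) - 1] / (r_i^3 r_j^3) by the
# addition theorem.
sh_rate_oracle <- function(protons, probe) {
  V <- sweep(protons, 2, probe)
  r <- sqrt(rowSums(V * V))
  U <- V / r
  th <- acos(pmin(1, pmax(-1, U[, 3])))
  ph <- atan2(U[, 2], U[, 1])
  y2m <- function(m) {
    switch(as.character(m),
      "0"  = sqrt(5 / (16 * pi)) * (3 * cos(th)^2 - 1),
      "1"  = -sqrt(15 / (8 * pi)) * sin(th) * cos(th) * exp(1i * ph),
      "-1" = sqrt(15 / (8 * pi)) * sin(th) * cos(th) * exp(-1i * ph),
      "2"  = sqrt(15 / (32 * pi)) * sin(th)^2 * exp(2i * ph),
      "-2" = sqrt(15 / (32 * pi)) * sin(th)^2 * exp(-2i * ph))
  }
  s <- 0
  for (m in -2:2) s <- s + Mod(sum(y2m(m) / r^3))^2
  (4 * pi / 5) * s / 9
}

# textbook two-pass Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# dihedral angle a-b-c-d in degrees, signed
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# fixed-column PDB ATOM line
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, alt = " ", bfac = 0) {
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, namef, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, bfac)
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# ideal tetrahedral substituent directions about a central atom
tetra_dirs <- function() {
  rbind(c(0, 0, 1),
        c(2 * sqrt(2) / 3, 0, -1 / 3),
        c(-sqrt(2) / 3, sqrt(2 / 3), -1 / 3),
        c(-sqrt(2) / 3, -sqrt(2 / 3), -1 / 3))
}

# hand-built valine-like fragment: CB at origin, CG1/CA/CG2 on ideal
# tetrahedral directions (bond 1.54 A), as a noemix structure
valine_fragment <- function() {
  d <- tetra_dirs() * 1.54
  new_structure(data.frame(
    chain = "A", resno = 30L, resid = "VAL",
    elety = c("CG1", "CA", "CG2", "CB"),
    x = c(d[1, 1], d[2, 1], d[3, 1], 0),
    y = c(d[1, 2], d[2, 2], d[3, 2], 0),
    z = c(d[1, 3], d[2, 3], d[3, 3], 0),
    stringsAsFactors = FALSE), label = "valfrag")
}

# random rigid-body transform applied to a structure's coordinates
apply_rigid <- function(struct, R, t) {
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")]) %*% t(R)
  struct$atoms$x <- xyz[, 1] + t[1]
  struct$atoms$y <- xyz[, 2] + t[2]
  struct$atoms$z <- xyz[, 3] + t[3]
  struct
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# independent forward evaluation of the extended spectral density from its
# algebraic definition (used as the second implementation in tests)
jext_oracle <- function(w, tc, s2, sf2, te) {
  tau_p <- tc * te / (tc + te)
  0.4 * (s2 * tc / (1 + (w * tc)^2) + (sf2 - s2) * tau_p / (1 + (w * tau_p)^2))
}
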