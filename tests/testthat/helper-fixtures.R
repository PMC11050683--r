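# Shared fixture builders. Everything is generated in code; no binary data.

# A minimal hand-written PDB with controllable residues/coordinates.
pdb_atom_line <- function(serial, resno, x, y, z, chain = "A", alt = "",
                          occ = 1.00, elety = "CA", resid = "ALA",
                          insert = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, paste0(" ", elety), alt, resid, chain, resno, insert,
          x, y, z, occ, 0)
}

tiny_pdb_text <- function() {
  c(pdb_atom_line(1, 1, 1.0, 2.0, 3.0),
    pdb_atom_line(2, 2, 4.0, 5.0, 6.0),
    pdb_atom_line(3, 3, 7.0, 8.0, 9.5),
    "END")
}

# random non-degenerate point cloud
random_points <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), ncol = 3)
}

random_proper_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent superposition oracle: Horn's quaternion characteristic-
# polynomial method (eigendecomposition of the 4x4 key matrix), entirely
# separate from the SVD route used by kabsch().
quaternion_lrmsd <- function(mobile, reference) {
  mc <- scale(mobile, scale = FALSE)
  rc <- scale(reference, scale = FALSE)
  m <- crossprod(mc, rc)  # 3x3 cross-covariance
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    nrow = 4, byrow = TRUE)
  lambda_max <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  ssq <- sum(mc^2) + sum(rc^2) - 2 * lambda_max
  sqrt(max(ssq, 0) / nrow(mobile))
}

# Floyd-Warshall all-pairs shortest paths, as an independent graph oracle.
floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$weight[r]
    d[i, j] <- min(d[i, j], w); d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Procrustes residual after optimal rigid motion + reflection, used to
# compare an embedding to ground-truth planar coordinates.
procrustes_residual <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(xc, yc))
  rot <- s$u %*% t(s$v)   # orthogonal, reflection allowed
  sqrt(sum((xc %*% rot - yc)^2) / nrow(x))
}
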