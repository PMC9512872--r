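# Shared in-code fixtures and independent oracles.

mk_benzene <- function(cx = 0, name = "benzene") {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  xyz <- cbind(1.39 * cos(th) + cx, 1.39 * sin(th), 0)
  bonds <- cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3))
  molecule(rep("C", 6), xyz, bonds, name = name)
}

mk_toluene <- function() {
  bz <- mk_benzene(name = "toluene")
  molecule(c(bz$elements, "C"), rbind(bz$xyz, c(2.9, 0, 0)),
           rbind(bz$bonds, c(1L, 7L, 1L)), name = "toluene")
}

# methane with explicit tetrahedral hydrogens
mk_methane <- function() {
  d <- 1.09 / sqrt(3)
  xyz <- rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d), c(-d, d, -d),
               c(-d, -d, d))
  molecule(c("C", "H", "H", "H", "H"), xyz,
           cbind(1L, 2:5, 1L), name = "methane")
}

# pyrrole-like N-H donor: N bonded to an explicit H and two ring carbons
mk_nh_ligand <- function() {
  molecule(c("N", "H", "C", "C"),
           rbind(c(0, 0, 0), c(0, 0, 1.01),
                 c(1.37, 0, -0.52), c(-1.37, 0, -0.52)),
           rbind(c(1L, 2L, 1L), c(1L, 3L, 1L), c(1L, 4L, 1L)),
           name = "nh_ligand")
}

# rigid rod fragment: cumulated double bonds leave no rotatable torsion, so
# unlike a flexible chain it cannot fold itself into a small cavity
mk_rigid_rod <- function(n = 6, name = "zzz_rigid_rod") {
  xyz <- cbind(1.31 * (seq_len(n) - 1), 0, 0)
  bonds <- if (n > 1) cbind(seq_len(n - 1), 2:n, 2L) else NULL
  molecule(rep("C", n), xyz, bonds, name = name)
}

# dense-marching ray oracle, step 0.01 A
march_ray <- function(origin, dir, centers, radii, mode, max_range = 10,
                      step = 0.01) {
  ts <- seq(0, max_range, by = step)
  inside <- vapply(ts, function(t) {
    p <- origin + t * dir
    any(sqrt(colSums((t(centers) - p)^2)) < radii)
  }, logical(1))
  if (mode == "pocket") {
    k <- which(inside & ts > 0)
    if (!length(k)) max_range else ts[k[1]]
  } else {
    k <- which(inside)
    if (!length(k)) 0 else min(ts[k[length(k)]] + step, max_range)
  }
}

# brute-force AUC: concordant pairs plus half ties over all active x decoy
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  a <- scores[labels]; d <- scores[!labels]
  tot <- 0
  for (x in a) for (y in d)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(a) * length(d))
}

# random rigid rotation matrix (uses current RNG state)
rand_rot <- function() {
  ax <- stats::rnorm(3)
  growlite:::rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
}

expect_same_molecule <- function(a, b, tol = 1e-3) {
  expect_identical(a$elements, b$elements)
  canon <- function(m) {
    if (!nrow(m$bonds)) return(m$bonds)
    b2 <- cbind(pmin(m$bonds[, 1], m$bonds[, 2]),
                pmax(m$bonds[, 1], m$bonds[, 2]), m$bonds[, 3])
    b2[order(b2[, 1], b2[, 2]), , drop = FALSE]
  }
  expect_equal(unname(canon(a)), unname(canon(b)))
  expect_lt(max(abs(a$xyz - b$xyz)), tol)
}
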