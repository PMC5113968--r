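# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# Horn's quaternion method: closed-form minimal RMSD of two paired point
# sets, computed from the largest eigenvalue of the 4x4 key matrix (no
# rotation matrix is ever constructed).
quaternion_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- t(Pc) %*% Qc
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,        -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# quaternion-based superposition returning residual distances of ALL points
# after fitting on a subset (independent of the package's SVD route)
quat_fit_distances <- function(mobile_xyz, fixed_xyz, subset) {
  P <- mobile_xyz[subset, , drop = FALSE]
  Q <- fixed_xyz[subset, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  S <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,        -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, which.max(ev$values)]
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2),
    3, 3, byrow = TRUE)
  moved <- sweep(sweep(mobile_xyz, 2, cp) %*% t(R), 2, cq, `+`)
  sqrt(rowSums((moved - fixed_xyz)^2))
}

# Brute-force seed enumeration for TM/GDT: every contiguous window (all
# lengths >= 3, all starts) seeds a superposition, each refined to
# convergence by the scores' defining distance-cut reassignment; best score
# over all residues is kept.
oracle_window_scores <- function(mobile_xyz, fixed_xyz) {
  L <- nrow(fixed_xyz)
  d0 <- if (L <= 15) 0.5 else max(0.5, 1.24 * (L - 15)^(1/3) - 1.8)
  thresholds <- c(0.5, 1, 2, 4)
  tm_cut <- max(d0, 1.5)
  best_tm <- -Inf
  best_frac <- rep(-Inf, 4)
  refine <- function(seed_subset, cut, score_fn) {
    best <- -Inf
    sel <- seed_subset
    prev <- integer(0)
    for (it in 1:20) {
      d <- tryCatch(quat_fit_distances(mobile_xyz, fixed_xyz, sel),
                    error = function(e) NULL)
      if (is.null(d)) break
      best <- max(best, score_fn(d))
      nxt <- which(d < cut)
      if (length(nxt) < 3) nxt <- order(d)[1:3]
      if (identical(nxt, prev) || identical(nxt, sel)) break
      prev <- sel
      sel <- nxt
    }
    best
  }
  for (len in 3:L) {
    for (s in 1:(L - len + 1)) {
      w <- s:(s + len - 1)
      best_tm <- max(best_tm,
                     refine(w, tm_cut,
                            function(d) sum(1 / (1 + (d / d0)^2)) / L))
      for (k in 1:4)
        best_frac[k] <- max(best_frac[k],
                            refine(w, thresholds[k],
                                   function(d) 100 * sum(d <= thresholds[k]) / L))
    }
  }
  list(tm = best_tm, gdt_ha = mean(best_frac))
}

# Direct O(n^2) restatement of the superposition-free local score on CA
# coordinate sets (one point per residue).
oracle_lddt_ca <- function(model_xyz, ref_xyz, radius = 15,
                           thresholds = c(0.5, 1, 2, 4)) {
  n <- nrow(ref_xyz)
  hits <- numeric(length(thresholds)); total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dr <- sqrt(sum((ref_xyz[i, ] - ref_xyz[j, ])^2))
    if (dr >= radius) next
    dm <- sqrt(sum((model_xyz[i, ] - model_xyz[j, ])^2))
    total <- total + 1
    for (k in seq_along(thresholds))
      if (abs(dm - dr) <= thresholds[k]) hits[k] <- hits[k] + 1
  }
  mean(hits / total)
}

# random rigid transformation (proper rotation + translation)
random_rigid <- function(xyz) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2),
    3, 3, byrow = TRUE)
  t_vec <- stats::rnorm(3, sd = 10)
  sweep(xyz %*% t(R), 2, t_vec, `+`)
}
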