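# Independent oracles used against the package's implementations. Each is
# deliberately brute-force / numerical and shares no code with the path it
# checks.

# Exhaustive enumeration of pae_interaction: walk every ordered interchain
# pair and average the two directed blocks.
oracle_pae_interaction <- function(pae, chain_map, binder_chain) {
  b <- which(chain_map == binder_chain)
  t <- which(chain_map != binder_chain)
  s_bt <- 0; s_tb <- 0
  for (i in b) for (j in t) s_bt <- s_bt + pae[i, j]
  for (i in t) for (j in b) s_tb <- s_tb + pae[i, j]
  (s_bt / (length(b) * length(t)) + s_tb / (length(t) * length(b))) / 2
}

# Numerical-optimization RMSD oracle: minimise over 3 Euler angles (the
# optimal translation is the centroid match) with multi-start BFGS.
oracle_min_rmsd <- function(moving, reference, n_starts = 12, seed = 1) {
  M <- sweep(moving, 2, colMeans(moving))
  R0 <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  f <- function(ang) sqrt(mean(rowSums((M %*% t(rotmat(ang)) - R0)^2)))
  best <- Inf
  starts <- withr::with_seed(seed,
    matrix(stats::runif(3 * n_starts, 0, 2 * pi), ncol = 3))
  for (k in seq_len(n_starts)) {
    fit <- stats::optim(starts[k, ], f, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 2000))
    fit <- stats::optim(fit$par, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Pair-counting AUC oracle: P(positive scored better than negative) plus
# half the tie probability.
oracle_auc <- function(score, label, direction) {
  good <- if (direction == "min") -score else score
  pos <- good[label]; neg <- good[!label]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# All-pairs domination oracle for the pareto front.
oracle_pareto <- function(records, objectives) {
  cols <- vapply(objectives, `[[`, character(1), 1)
  dirs <- vapply(objectives, function(o) if (length(o) > 1) o[[2]] else "min",
                 character(1))
  M <- as.matrix(records[, cols, drop = FALSE])
  for (j in seq_along(dirs)) if (dirs[j] == "max") M[, j] <- -M[, j]
  n <- nrow(M)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  records$design_id[keep]
}

# Random rigid transform (proper rotation + translation).
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(9), 3)
    qr_ <- qr(A)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = stats::rnorm(3, sd = 5))
  })
}

apply_rigid <- function(coords, rt) {
  sweep(coords %*% t(rt$R), 2, rt$t, "+")
}

random_score_table <- function(n, metrics, seed, with_label = FALSE) {
  withr::with_seed(seed, {
    df <- data.frame(design_id = sprintf("d%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
    for (m in metrics) df[[m]] <- round(stats::runif(n, 0, 20), 2)
    if (with_label) df$label <- stats::runif(n) < 0.4
    df
  })
}
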