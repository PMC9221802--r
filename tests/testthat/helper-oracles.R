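# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (exhaustive enumeration, brute-force loops, generic
# numeric optimization) so it shares no code path with the implementation.

# GLCM by explicit voxel-pair enumeration: triple loop over voxels and
# directions, features recomputed from first principles per direction.
oracle_glcm <- function(levels, mask, distance = 1L) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  L <- max(levels[mask == 1])
  feats <- NULL
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ] * distance
    counts <- matrix(0, L, L)
    npairs <- 0L
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
        if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
            z2 < 1 || z2 > dims[3]) next
        if (mask[x, y, z] == 1 && mask[x2, y2, z2] == 1) {
          a <- levels[x, y, z]; b <- levels[x2, y2, z2]
          counts[a, b] <- counts[a, b] + 1
          counts[b, a] <- counts[b, a] + 1
          npairs <- npairs + 1L
        }
      }
    if (npairs == 0L) next
    P <- counts / sum(counts)
    i <- matrix(seq_len(L), L, L); j <- t(i)
    mu <- sum(i * P)
    sigma2 <- sum((i - mu)^2 * P)
    pos <- P > 0
    psum <- sapply(2:(2 * L), function(k) sum(P[(i + j) == k]))
    pdif <- sapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]))
    ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
    f <- c(joint_energy = sum(P^2),
           contrast = sum((i - j)^2 * P),
           correlation = if (sigma2 > 0)
             sum((i - mu) * (j - mu) * P) / sigma2 else NA_real_,
           joint_entropy = -sum(P[pos] * log2(P[pos])),
           inverse_difference = sum(P / (1 + abs(i - j))),
           inverse_difference_moment = sum(P / (1 + (i - j)^2)),
           dissimilarity = sum(abs(i - j) * P),
           cluster_shade = sum((i + j - 2 * mu)^3 * P),
           cluster_prominence = sum((i + j - 2 * mu)^4 * P),
           autocorrelation = sum(i * j * P),
           sum_average = sum((i + j) * P),
           sum_entropy = ent(psum),
           difference_entropy = ent(pdif),
           sum_squares = sigma2)
    feats <- rbind(feats, f)
  }
  colMeans(feats)
}

# Fisher two-sided p by exhaustive enumeration of all tables with the
# observed margins (point-probability rule).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(k)
    stats::dhyper(k, c1, n - c1, r1), numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney two-sided p by full enumeration of group assignments.
oracle_mann_whitney <- function(x0, x1) {
  pooled <- c(x0, x1)
  n0 <- length(x0)
  u_stat <- function(g0) {
    g1 <- pooled[-g0]
    sum(outer(pooled[g0], g1, `<`)) + 0.5 * sum(outer(pooled[g0], g1, `==`))
  }
  obs <- u_stat(seq_len(n0))
  combos <- utils::combn(length(pooled), n0)
  us <- apply(combos, 2, u_stat)
  center <- n0 * (length(x1)) / 2
  mean(abs(us - center) >= abs(obs - center) - 1e-12)
}

# Negative penalized logistic objective at beta (glmnet parameterization):
# -(1/n) loglik + lambda * (alpha ||b||_1 + (1-alpha) ||b||_2^2 / 2)
penalized_objective <- function(par, X, y, alpha, lambda) {
  eta <- par[1] + X %*% par[-1]
  ll <- sum(y * eta - log(1 + exp(eta)))
  -ll / length(y) +
    lambda * (alpha * sum(abs(par[-1])) +
                (1 - alpha) * sum(par[-1]^2) / 2)
}

# Gaussian Bayes posterior with pooled covariance, computed from densities.
oracle_lda_posterior <- function(X_train, y_train, X_new, priors) {
  mu0 <- colMeans(X_train[y_train == 0, , drop = FALSE])
  mu1 <- colMeans(X_train[y_train == 1, , drop = FALSE])
  c0 <- sweep(X_train[y_train == 0, , drop = FALSE], 2, mu0)
  c1 <- sweep(X_train[y_train == 1, , drop = FALSE], 2, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (nrow(X_train) - 2)
  dens <- function(x, mu) {
    d <- length(mu)
    q <- drop(t(x - mu) %*% solve(S, x - mu))
    exp(-q / 2) / sqrt((2 * pi)^d * det(S))
  }
  apply(X_new, 1, function(x) {
    f1 <- priors[2] * dens(x, mu1)
    f0 <- priors[1] * dens(x, mu0)
    f1 / (f0 + f1)
  })
}

# AUC by explicit pairwise concordance count.
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# small planted-signal cohort shared by modelling tests
planted_cohort <- function(n = 300, p = 100, delta = 2, prevalence = 0.3,
                           index = 5, seed = 21) {
  generate_feature_table(cohort_config(
    n_patients = n, n_radiomics = p, prevalence = prevalence,
    planted = data.frame(index = index, delta = delta), seed = seed))
}
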