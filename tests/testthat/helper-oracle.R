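# Independent brute-force oracles, written directly from the model
# definitions in plain base R with explicit loops over the threshold grid.
# They never call into the package's implementation and are typically run
# at 4x the package's default grid resolution.

oracle_grid <- function(n = 801L, lo = -5, hi = 5) seq(lo, hi, length.out = n)

oracle_gauss_mass <- function(mean, sd, pts) {
  m <- stats::dnorm(pts, mean, sd)
  m / sum(m)
}

# Literal listener: loop over every threshold value (uniform over the grid),
# accumulate the truth-masked prior, normalize the joint, marginalize theta.
oracle_L0 <- function(polarity, prior_mass, pts) {
  n <- length(pts)
  acc <- numeric(n)
  for (ti in seq_len(n)) {
    tr <- switch(polarity,
                 positive = pts > pts[ti],
                 negative = pts < pts[ti],
                 silence = rep(TRUE, n))
    acc <- acc + prior_mass * tr / n
  }
  acc / sum(acc)
}

# Soft-max speaker over {positive, negative, silence} at every grid point.
oracle_speaker <- function(prior_mass, pts, alpha, costs) {
  L <- cbind(positive = oracle_L0("positive", prior_mass, pts),
             negative = oracle_L0("negative", prior_mass, pts),
             silence = oracle_L0("silence", prior_mass, pts))
  S <- matrix(0, length(pts), 3L,
              dimnames = list(NULL, colnames(L)))
  for (xi in seq_len(length(pts))) {
    w <- numeric(3L)
    for (ui in 1:3) {
      w[ui] <- if (L[xi, ui] <= 0 && alpha > 0) 0 else
        exp(alpha * (log(L[xi, ui]) - costs[ui]))
    }
    if (alpha == 0) w <- rep(1, 3L)
    if (sum(w) > 0) S[xi, ] <- w / sum(w)
  }
  S
}

# Pragmatic listener: joint over (x, class), class prior prior_sub.
oracle_pragmatic <- function(polarity, k_mass, sub_mass, sup_mass, prior_sub,
                             alpha, costs, pts) {
  ui <- match(polarity, c("positive", "negative", "silence"))
  s_sub <- oracle_speaker(sub_mass, pts, alpha, costs)[, ui]
  s_sup <- oracle_speaker(sup_mass, pts, alpha, costs)[, ui]
  w_sub <- prior_sub * s_sub * k_mass
  w_sup <- (1 - prior_sub) * s_sup * k_mass
  z <- sum(w_sub) + sum(w_sup)
  list(class_marginal = c(sub = sum(w_sub) / z, super = sum(w_sup) / z),
       degree_marginal = (w_sub + w_sup) / z)
}

# Rival literal class listener: joint over (x, theta, class).
oracle_literal_class <- function(polarity, sub_mass, sup_mass, prior_sub,
                                 pts) {
  n <- length(pts)
  p_true <- function(mass) {
    s <- 0
    for (ti in seq_len(n)) {
      tr <- switch(polarity,
                   positive = pts > pts[ti],
                   negative = pts < pts[ti],
                   silence = rep(TRUE, n))
      s <- s + sum(mass * tr) / n
    }
    s
  }
  w_sub <- prior_sub * p_true(sub_mass)
  w_sup <- (1 - prior_sub) * p_true(sup_mass)
  c(sub = w_sub, super = w_sup) / (w_sub + w_sup)
}

oracle_endorse <- function(polarity, k_mass, class_mass, alpha2, costs, pts) {
  ui <- match(polarity, c("positive", "negative", "silence"))
  sum(k_mass * oracle_speaker(class_mass, pts, alpha2, costs)[, ui])
}

# Cell-average a fine-grid mass (factor x refinement of an n-point grid)
# onto the coarse grid: fine points exactly between two coarse cells are
# split half-half, so mass is conserved and the comparison is symmetric.
bin_fine_to_coarse <- function(mass_fine, n_coarse, factor = 4L) {
  n_fine <- length(mass_fine)
  stopifnot(n_fine == factor * (n_coarse - 1L) + 1L)
  half <- factor / 2
  out <- numeric(n_coarse)
  for (i in seq_len(n_coarse)) {
    f0 <- factor * (i - 1L) + 1L
    idx <- (f0 - half):(f0 + half)
    w <- c(0.5, rep(1, factor - 1L), 0.5)
    keep <- idx >= 1L & idx <= n_fine
    out[i] <- sum(mass_fine[idx[keep]] * w[keep])
  }
  out
}

tv_dist <- function(a, b) 0.5 * sum(abs(a - b))
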