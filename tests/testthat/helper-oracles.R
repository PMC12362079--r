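# Brute-force oracles and small fixtures, coded independently of the
# package internals (plain loops, no shared helpers), used to validate the
# permutation machinery and the decoders.

# All 2^n sign vectors for n subjects.
all_sign_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

# Clusters of a statistic series: list of start/end/mass, plain loop.
brute_clusters <- function(s, threshold) {
  out <- list()
  t <- 1
  n <- length(s)
  while (t <= n) {
    if (s[t] > threshold) {
      start <- t
      mass <- 0
      while (t <= n && s[t] > threshold) {
        mass <- mass + s[t]
        t <- t + 1
      }
      out[[length(out) + 1]] <- list(start = start, end = t - 1, mass = mass)
    } else {
      t <- t + 1
    }
  }
  out
}

# Exhaustive-enumeration cluster mass p-values (add-one rule).
brute_cluster_mass <- function(A, threshold = 0.01, chance = 0.5) {
  D <- A - chance
  n <- nrow(D)
  S <- all_sign_vectors(n)
  obs <- colMeans(D)
  obs_cl <- brute_clusters(obs, threshold)
  null_max <- apply(S, 1, function(sg) {
    s <- colMeans(D * sg)
    cl <- brute_clusters(s, threshold)
    if (!length(cl)) 0 else max(vapply(cl, `[[`, 1.0, "mass"))
  })
  vapply(obs_cl, function(cl) {
    (1 + sum(null_max >= cl$mass - 1e-12)) / (1 + nrow(S))
  }, 1.0)
}

# Exhaustive-enumeration cluster depth p-values: head/tail depth-indexed
# null maxima, Troendle max-T step-down (quadratic, direct recomputation),
# head/tail combined by the maximum. Mirrors the algorithm definition, not
# the package code.
brute_cluster_depth <- function(A, threshold = 0.01, chance = 0.5) {
  D <- A - chance
  n <- nrow(D)
  n_times <- ncol(D)
  S <- all_sign_vectors(n)
  n_perm <- nrow(S)
  Dh <- matrix(0, n_perm, n_times)
  Dt <- matrix(0, n_perm, n_times)
  for (r in seq_len(n_perm)) {
    s <- colMeans(D * S[r, ])
    for (cl in brute_clusters(s, threshold)) {
      len <- cl$end - cl$start + 1
      for (j in seq_len(len)) {
        Dh[r, j] <- max(Dh[r, j], s[cl$start + j - 1])
        Dt[r, j] <- max(Dt[r, j], s[cl$end - j + 1])
      }
    }
  }
  obs <- colMeans(D)
  p <- rep(1, n_times)
  obs_cl <- brute_clusters(obs, threshold)
  if (!length(obs_cl)) return(p)
  idx <- unlist(lapply(obs_cl, function(cl) cl$start:cl$end))
  dh <- unlist(lapply(obs_cl, function(cl) seq_len(cl$end - cl$start + 1)))
  dt <- unlist(lapply(obs_cl, function(cl) rev(seq_len(cl$end - cl$start + 1))))
  stepdown <- function(stat_vals, depths, Dmat) {
    K <- length(stat_vals)
    ord <- order(stat_vals, decreasing = TRUE)
    pv <- numeric(K)
    for (i in seq_len(K)) {
      act <- unique(depths[ord[i:K]])
      nm <- rep(0, n_perm)
      for (d in act) nm <- pmax(nm, Dmat[, d])
      pv[ord[i]] <- (1 + sum(nm >= stat_vals[ord[i]] - 1e-12)) / (1 + n_perm)
    }
    run <- 0
    for (i in seq_len(K)) {
      pv[ord[i]] <- max(pv[ord[i]], run)
      run <- pv[ord[i]]
    }
    pv
  }
  ph <- stepdown(obs[idx], dh, Dh)
  pt <- stepdown(obs[idx], dt, Dt)
  p[idx] <- pmax(ph, pt)
  p
}

# Nearest-class-mean classifier accuracy with leave-one-out, an
# independent check that a dataset is linearly separable at a timepoint.
ncm_loo_accuracy <- function(X, y) {
  n <- nrow(X)
  correct <- 0
  for (i in seq_len(n)) {
    m0 <- colMeans(X[-i, , drop = FALSE][y[-i] == 0, , drop = FALSE])
    m1 <- colMeans(X[-i, , drop = FALSE][y[-i] == 1, , drop = FALSE])
    d0 <- sum((X[i, ] - m0)^2)
    d1 <- sum((X[i, ] - m1)^2)
    pred <- as.numeric(d1 < d0)
    correct <- correct + (pred == y[i])
  }
  correct / n
}

# Small, fast cohort configurations used across tests.
tiny_cfg <- function(...) {
  args <- list(n_subjects = 2, n_trials_per_stimulus = 10, n_sessions = 1,
               sfreq = 50, tmax = 0.8, effect_window = c(200, 600),
               subject_effect_sd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

make_binary_subject <- function(cfg, comp = "face_categorization",
                                subject = 1, seed = 1) {
  s <- generate_subject_epochs(cfg, subject)
  binarize(preprocess_subject(s$epochs, seed = seed), comparison(comp))
}
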