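#' Group-level sign-flip cluster mass test
#'
#' Tests where the group decoding accuracy exceeds chance while controlling
#' the family-wise error rate at the cluster level. The cluster-forming
#' statistic at timepoint t is the subject mean of `accuracy - chance`;
#' clusters are maximal contiguous runs where it exceeds `threshold`
#' (default 0.01, i.e. 1% above chance), and a cluster's mass is the sum of
#' the statistic over the run. The null is built by randomly flipping the
#' sign of each subject's whole `(accuracy - chance)` series (the canonical
#' one-sample exchangeability scheme); the permutation distribution is the
#' maximum cluster mass per permutation, and p-values use the add-one
#' Monte-Carlo rule, one-sided.
#'
#' For `n_subjects <= 20` with `exhaustive = TRUE`, all `2^n` sign
#' assignments are enumerated instead of sampled, making the test exact.
#'
#' @param acc Subject x timepoint accuracy matrix (values in `[0,1]`), or a
#'   `group_accuracy` object from [group_mean_sem()].
#' @param threshold Cluster-forming threshold on the mean-minus-chance
#'   scale.
#' @param n_perm Number of random sign-flip permutations.
#' @param seed Seed for the permutation draw.
#' @param chance Chance accuracy (0.5 for balanced binary decoding).
#' @param time_ms Optional time axis for reporting.
#' @param statistic `"mean"` (mean accuracy minus chance, the default) or
#'   `"t"` (one-sample t statistic against chance; with `"t"` the threshold
#'   is on the t scale).
#' @param exhaustive Enumerate all sign assignments (exact test).
#' @return A `cluster_result` with a `clusters` data frame
#'   (`start_idx`, `end_idx`, `start_ms`, `end_ms`, `mass`, `p_fwer`) and
#'   the permutation parameters.
#' @export
cluster_mass_test <- function(acc, threshold = 0.01, n_perm = 10000,
                              seed = 1L, chance = 0.5, time_ms = NULL,
                              statistic = c("mean", "t"),
                              exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  A <- as_accuracy_matrix(acc, chance)
  if (is.null(time_ms)) time_ms <- attr(A, "time_ms")
  stat <- group_statistic(A, statistic)
  cl <- find_clusters(stat, threshold)
  signs <- sign_matrix(nrow(A), n_perm, seed, exhaustive)
  null <- perm_null(A, signs, threshold, statistic, want_depth = FALSE)
  n_eff <- nrow(signs)
  p <- vapply(cl$mass, function(m) {
    (1 + sum(null$max_mass >= m - 1e-12)) / (1 + n_eff)
  }, 1.0)
  clusters <- data.frame(
    start_idx = cl$start, end_idx = cl$end,
    start_ms = if (!is.null(time_ms)) time_ms[cl$start] else
      rep(NA_real_, length(cl$start)),
    end_ms = if (!is.null(time_ms)) time_ms[cl$end] else
      rep(NA_real_, length(cl$end)),
    mass = cl$mass, p_fwer = p
  )
  structure(
    list(clusters = clusters, statistic_series = stat, time_ms = time_ms,
         threshold = threshold, n_permutations = n_eff, seed = seed,
         chance = chance, statistic = statistic, exhaustive = exhaustive),
    class = "cluster_result"
  )
}

#' Group-level sign-flip cluster depth test
#'
#' Refines the cluster mass test to timepoint-level FWER control. For each
#' permutation, clusters are formed as in [cluster_mass_test()]; every
#' in-cluster timepoint is indexed by its depth from the cluster head and
#' from the cluster tail, and for each depth the maximum statistic across
#' that permutation's clusters is recorded. Observed in-cluster timepoints
#' are then tested against the depth-indexed null distributions with a
#' Troendle-style max-T step-down (hypotheses ordered by observed
#' statistic; each compared against the null maximum over the depths of the
#' not-yet-rejected hypotheses; monotonicity enforced). Head- and
#' tail-based p-values are combined by their maximum (`side = "both"`) or
#' used alone (`side = "head"`). Timepoints outside observed clusters get
#' p = 1. One-sided.
#'
#' @inheritParams cluster_mass_test
#' @param side Combine head and tail depth nulls (`"both"`, default) or use
#'   the head only.
#' @return Numeric vector of FWER-corrected p-values, one per timepoint.
#' @export
cluster_depth_test <- function(acc, threshold = 0.01, n_perm = 10000,
                               seed = 1L, chance = 0.5,
                               statistic = c("mean", "t"),
                               side = c("both", "head"),
                               exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  side <- match.arg(side)
  A <- as_accuracy_matrix(acc, chance)
  stat <- group_statistic(A, statistic)
  cl <- find_clusters(stat, threshold)
  p_out <- rep(1, length(stat))
  if (!length(cl$start)) return(p_out)
  signs <- sign_matrix(nrow(A), n_perm, seed, exhaustive)
  null <- perm_null(A, signs, threshold, statistic, want_depth = TRUE)
  n_eff <- nrow(signs)

  idx <- unlist(mapply(seq, cl$start, cl$end, SIMPLIFY = FALSE))
  clus_of <- rep(seq_along(cl$start), cl$end - cl$start + 1L)
  depth_head <- unlist(lapply(seq_along(cl$start),
                              function(i) seq_len(cl$end[i] - cl$start[i] + 1L)))
  depth_tail <- unlist(lapply(seq_along(cl$start),
                              function(i) rev(seq_len(cl$end[i] - cl$start[i] + 1L))))
  obs <- stat[idx]

  p_head <- troendle_stepdown(obs, depth_head, null$depth_head, n_eff)
  if (side == "both") {
    p_tail <- troendle_stepdown(obs, depth_tail, null$depth_tail, n_eff)
    p_out[idx] <- pmax(p_head, p_tail)
  } else {
    p_out[idx] <- p_head
  }
  p_out
}

# Troendle max-T step-down against depth-indexed null distributions.
# obs: observed statistics; depth: depth index per hypothesis; D: n_perm x
# n_times null matrix whose column d is the depth-(d+1) maxima.
troendle_stepdown <- function(obs, depth, D, n_eff) {
  ord <- order(obs, decreasing = TRUE)
  K <- length(ord)
  p <- numeric(K)
  # Walk the step-down order backwards so the null maximum over the depths
  # of the not-yet-rejected hypotheses can be grown incrementally.
  null_max <- rep(0, nrow(D))
  included <- logical(ncol(D))
  for (i in K:1) {
    d <- depth[ord[i]]
    if (!included[d]) {
      null_max <- pmax(null_max, D[, d])
      included[d] <- TRUE
    }
    p[ord[i]] <- (1 + sum(null_max >= obs[ord[i]] - 1e-12)) / (1 + n_eff)
  }
  prev <- 0
  for (i in seq_len(K)) {        # enforce step-down monotonicity
    p[ord[i]] <- max(p[ord[i]], prev)
    prev <- p[ord[i]]
  }
  p
}

as_accuracy_matrix <- function(acc, chance) {
  if (inherits(acc, "group_accuracy")) {
    A <- acc$accuracy - chance
    attr(A, "time_ms") <- acc$time_ms
    return(A)
  }
  A <- as.matrix(acc) - chance
  if (nrow(A) < 2) stop("need at least 2 subjects")
  if (!all(is.finite(A))) stop("accuracy matrix contains non-finite values")
  A
}

group_statistic <- function(A, statistic) {
  if (statistic == "mean") {
    colMeans(A)
  } else {
    m <- colMeans(A)
    s <- apply(A, 2, stats::sd)
    s[s < 1e-12] <- 1e-12
    m / (s / sqrt(nrow(A)))
  }
}

find_clusters <- function(stat, threshold) {
  above <- stat > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  list(
    start = starts[keep],
    end = ends[keep],
    mass = vapply(keep, function(i) {
      sum(stat[starts[i]:ends[i]])
    }, 1.0)
  )
}

sign_matrix <- function(n_sub, n_perm, seed, exhaustive) {
  if (exhaustive) {
    if (n_sub > 20) stop("exhaustive enumeration limited to 20 subjects")
    g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
    dimnames(g) <- NULL
    g
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    with_seed(derive_seed(seed, "signflip"), {
      matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE), n_perm, n_sub)
    })
  }
}

perm_null <- function(A, signs, threshold, statistic, want_depth) {
  if (statistic == "mean") {
    .cluster_perm_null_core(unclass(A), signs, threshold, want_depth)
  } else {
    perm_null_t(A, signs, threshold, want_depth)
  }
}

# t-statistic variant of the sign-flip null (R implementation; the mean
# variant is the compiled default).
perm_null_t <- function(A, signs, threshold, want_depth) {
  n_perm <- nrow(signs)
  n_sub <- nrow(A)
  max_mass <- numeric(n_perm)
  Dh <- Dt <- if (want_depth) matrix(0, n_perm, ncol(A)) else NULL
  for (pm in seq_len(n_perm)) {
    Af <- A * signs[pm, ]
    s <- group_statistic(Af, "t")
    cl <- find_clusters(s, threshold)
    if (length(cl$mass)) {
      max_mass[pm] <- max(cl$mass)
      if (want_depth) {
        for (i in seq_along(cl$start)) {
          run <- s[cl$start[i]:cl$end[i]]
          len <- length(run)
          Dh[pm, seq_len(len)] <- pmax(Dh[pm, seq_len(len)], run)
          Dt[pm, seq_len(len)] <- pmax(Dt[pm, seq_len(len)], rev(run))
        }
      }
    }
  }
  list(max_mass = max_mass, depth_head = Dh, depth_tail = Dt)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$statistic, "statistic, threshold",
      x$threshold, ",", x$n_permutations,
      if (x$exhaustive) "exhaustive sign patterns\n" else "permutations\n")
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment across a family of p-values (as applied across
#' participants per comparison).
#'
#' @param p Vector of p-values in `[0,1]`.
#' @return Adjusted q-values in `[0,1]`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
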