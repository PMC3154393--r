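#' Replicate saturation analysis
#'
#' For R technical replicates of an experiment, enumerates every k-subset
#' of replicates (k = 1..R) and records the number of unique phosphosites
#' in the union of each subset, together with the per-k mean. A flat
#' profile (little gain from additional replicates) indicates the
#' experiment has saturated the sub-phosphoproteome it can reach.
#'
#' Exact subset enumeration, so the number of replicates is capped at 20.
#'
#' @param replicates A list of site sets (each a `site_dataset` or a data
#'   frame with columns `protein_id`, `position`, `residue`).
#' @return An object of class `replicate_curve`: a list with `k`,
#'   `unions` (list of per-subset union sizes, length `choose(R, k)` at
#'   each k), `mean` (per-k means), `n_replicates`, `n_unique`.
#' @examples
#' r <- list(data.frame(protein_id = "p", position = c(1, 2), residue = "S"),
#'           data.frame(protein_id = "p", position = c(2, 4), residue = "S"))
#' replicate_saturation(r)
#' @export
replicate_saturation <- function(replicates) {
  if (!is.list(replicates) || length(replicates) == 0) {
    stop_data("need at least one replicate")
  }
  R <- length(replicates)
  if (R > 20) stop_data("exhaustive enumeration supports at most 20 replicates")
  keysets <- lapply(replicates, function(r) {
    s <- as_sites(r)
    unique(site_key(s$protein_id, s$position, s$residue))
  })
  unions <- vector("list", R)
  for (k in seq_len(R)) {
    subsets <- combn(R, k, simplify = FALSE)
    unions[[k]] <- vapply(subsets, function(idx) {
      length(unique(unlist(keysets[idx], use.names = FALSE)))
    }, numeric(1))
  }
  structure(list(
    k = seq_len(R),
    unions = unions,
    mean = vapply(unions, mean, numeric(1)),
    n_replicates = R,
    n_unique = length(unique(unlist(keysets, use.names = FALSE)))
  ), class = "replicate_curve")
}

#' @export
print.replicate_curve <- function(x, ...) {
  cat("Replicate saturation over", x$n_replicates, "replicates (",
      x$n_unique, "unique sites )\n")
  for (k in x$k) {
    cat(sprintf("  k=%d: %d subset(s), mean union %.1f\n",
                k, length(x$unions[[k]]), x$mean[k]))
  }
  invisible(x)
}

#' Pooled-draw rarefaction (saturation) curve
#'
#' Builds the observation pool of a dataset (one pool entry per
#' observation of a site, so a site reported by m sources appears m
#' times), then repeatedly permutes the pool and draws it without
#' replacement, recording the number of unique sites discovered so far.
#' The averaged trajectory of (fraction of pool drawn, fraction of unique
#' sites discovered) is the saturation curve: a curve hugging the
#' diagonal means every draw is novel (no saturation), while early
#' flattening means the underlying site inventory is close to fully
#' sampled.
#'
#' Curves are evaluated at `ceiling(pool_size / grid)`-spaced draw counts
#' (at every draw when the pool is no larger than `grid`) and averaged
#' over `n_repeats` full permutations.
#'
#' @param dataset A `site_dataset` (or a bare integer vector of site
#'   multiplicities).
#' @param n_repeats Number of random permutations to average (default 100).
#' @param grid Approximate number of evaluation points (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `saturation_curve` with a `points` data
#'   frame (`draws`, `x`, `mean_unique`, `sd_unique`, `y`), plus
#'   `pool_size`, `n_unique`, `n_repeats`.
#' @export
pooled_rarefaction <- function(dataset, n_repeats = 100, grid = 100,
                               seed = NULL) {
  mult <- if (inherits(dataset, "site_dataset")) {
    dataset_multiplicities(dataset)
  } else {
    as.integer(dataset)
  }
  if (length(mult) == 0 || sum(mult) < 1) stop_data("empty observation pool")
  if (any(mult < 1)) stop_data("multiplicities must be >= 1")
  if (n_repeats < 1) stop_data("n_repeats must be >= 1")
  N <- sum(mult)
  U <- length(mult)
  pool <- rep.int(seq_len(U), mult)
  step <- max(1L, ceiling(N / grid))
  eval_at <- unique(c(seq(step, N, by = step), N))
  acc <- matrix(0, nrow = n_repeats, ncol = length(eval_at))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      perm <- pool[sample.int(N)]
      acc[r, ] <- cumsum(!duplicated(perm))[eval_at]
    }
  })
  mean_u <- colMeans(acc)
  sd_u <- if (n_repeats > 1) apply(acc, 2, sd) else rep(NA_real_, length(eval_at))
  points <- data.frame(
    draws = c(0L, eval_at),
    x = c(0, eval_at / N),
    mean_unique = c(0, mean_u),
    sd_unique = c(0, sd_u),
    y = c(0, mean_u / U)
  )
  structure(list(points = points, pool_size = N, n_unique = U,
                 n_repeats = n_repeats, seed = seed),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat("Saturation curve:", x$n_unique, "unique sites in a pool of",
      x$pool_size, "observations;", x$n_repeats, "repeats\n")
  mid <- x$points[which.min(abs(x$points$x - 0.5)), ]
  cat(sprintf("  y(0.5) = %.3f (diagonal would be 0.5)\n", mid$y))
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  plot(x$points$x, x$points$y, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "fraction of pool drawn", ylab = "fraction of unique sites",
       ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Novelty contributed by the tail of a saturation curve
#'
#' Quantifies how far a dataset is from saturation as the relative gain
#' in unique sites over the final fraction of draws: 100 * (U(1) -
#' U(1 - tail)) / U(1 - tail), where U(x) is the mean unique-site count
#' after a fraction x of the pool has been drawn. A fully saturated
#' dataset yields 0; a dataset with no repeated observations yields
#' 100 * tail / (1 - tail).
#'
#' @param x A `saturation_curve` or a `site_dataset` (a curve is computed
#'   with the supplied `...` arguments).
#' @param tail_fraction Final fraction of draws to assess (default 0.10).
#' @param ... Passed to [pooled_rarefaction()] when `x` is a dataset.
#' @return A list with `percent_increase`, `new_sites` (absolute mean
#'   gain), `u_tail_start`, `u_full`, `tail_fraction`.
#' @export
tail_novelty <- function(x, tail_fraction = 0.10, ...) {
  if (tail_fraction <= 0 || tail_fraction >= 1) {
    stop_data("tail_fraction must be in (0, 1)")
  }
  curve <- if (inherits(x, "saturation_curve")) x else pooled_rarefaction(x, ...)
  pts <- curve$points
  u_at <- function(frac) approx(pts$x, pts$mean_unique, xout = frac,
                                rule = 2)$y
  u1 <- u_at(1)
  u0 <- u_at(1 - tail_fraction)
  if (u0 <= 0) stop_data("no sites discovered before the tail window")
  list(percent_increase = 100 * (u1 - u0) / u0,
       new_sites = u1 - u0,
       u_tail_start = u0,
       u_full = u1,
       tail_fraction = tail_fraction)
}

#' Matched-draw comparison of saturation between two pools
#'
#' Draws the same number of observations from two observation pools and
#' compares the mean number of unique sites obtained. The focal pool
#' (`pool_a`, e.g. functionally annotated phosphosites) is called more
#' saturated than the comparison pool (`pool_b`) when the same number of
#' observations yields fewer unique sites. The p-value is the one-sided
#' add-one permutation estimate of the probability that a draw from
#' `pool_b` looks at least as saturated (unique count less than or equal
#' to `pool_a`'s mean).
#'
#' @param pool_a,pool_b `site_dataset` objects.
#' @param n_draws Number of observations to draw (must not exceed either
#'   pool).
#' @param n_trials Number of random draws per pool (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `matched_comparison`: list with
#'   `mean_unique_a`, `mean_unique_b`, `p_value`, `n_draws`, `n_trials`.
#' @export
matched_unique_comparison <- function(pool_a, pool_b, n_draws,
                                      n_trials = 1000, seed = NULL) {
  ma <- dataset_multiplicities(pool_a)
  mb <- dataset_multiplicities(pool_b)
  if (n_draws > sum(ma) || n_draws > sum(mb)) {
    stop_data("n_draws exceeds a pool size (", sum(ma), " / ", sum(mb), ")")
  }
  if (n_draws < 1 || n_trials < 1) stop_data("n_draws and n_trials must be >= 1")
  draw_unique <- function(mult) {
    pool <- rep.int(seq_along(mult), mult)
    vapply(seq_len(n_trials), function(i) {
      length(unique(pool[sample.int(length(pool), n_draws)]))
    }, numeric(1))
  }
  res <- with_seed(seed, {
    ua <- draw_unique(ma)
    ub <- draw_unique(mb)
    list(ua = ua, ub = ub)
  })
  mean_a <- mean(res$ua)
  mean_b <- mean(res$ub)
  p <- (1 + sum(res$ub <= mean_a)) / (1 + n_trials)
  structure(list(mean_unique_a = mean_a, mean_unique_b = mean_b,
                 p_value = p, n_draws = n_draws, n_trials = n_trials),
            class = "matched_comparison")
}

#' @export
print.matched_comparison <- function(x, ...) {
  cat(sprintf(
    "Matched draws of %d observations: pool A %.1f unique, pool B %.1f unique (p = %.4g)\n",
    x$n_draws, x$mean_unique_a, x$mean_unique_b, x$p_value))
  invisible(x)
}
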