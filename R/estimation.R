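#' Bootstrap sampling distribution of the mean difference
#'
#' Estimation-statistics effect size: `mean(b) - mean(a)` with a percentile
#' confidence interval from `n_boot` bootstrap resamples (resampling with
#' replacement within each group independently; 5000 resamples and a 95%
#' interval by default). Deterministic under a fixed seed.
#'
#' @param a,b numeric samples (>= 2 observations each).
#' @param n_boot number of bootstrap resamples.
#' @param ci_level confidence level in (0, 1).
#' @param seed integer RNG seed recorded in the output.
#' @return list of class `effect_size`: `mean_diff`, `ci_low`, `ci_high`,
#'   `n_boot`, `ci_level`, `seed`, `boot_diffs`.
#' @export
bootstrap_mean_diff <- function(a, b, n_boot = 5000L, ci_level = 0.95, seed = 1L) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 observations")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  na <- length(a); nb <- length(b)
  am <- matrix(a[sample.int(na, na * n_boot, replace = TRUE)], n_boot, na)
  bm <- matrix(b[sample.int(nb, nb * n_boot, replace = TRUE)], n_boot, nb)
  diffs <- rowMeans(bm) - rowMeans(am)
  alpha <- (1 - ci_level) / 2
  ci <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(mean_diff = mean(b) - mean(a),
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), boot_diffs = diffs),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("effect_size: mean difference %.4g, %g%% CI [%.4g, %.4g] (%d bootstrap samples)\n",
              x$mean_diff, 100 * x$ci_level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Two-sided permutation test for a difference in means
#'
#' `p = (1 + #(|permuted mean difference| >= |observed|)) / (n_perm + 1)`,
#' so p is never exactly zero. When the total number of distinct group
#' assignments is at most `n_perm` the test enumerates them exhaustively
#' (and p becomes `#(|perm| >= |obs|) / n_arrangements`). Degenerate input
#' (all values identical) gives p = 1.
#'
#' @param a,b numeric samples (combined size >= 4).
#' @param n_perm Monte-Carlo permutation count.
#' @param seed RNG seed (Monte-Carlo branch only).
#' @return list of class `perm_test`: `p`, `observed`, `n_perm`,
#'   `exhaustive`.
#' @export
permutation_pvalue <- function(a, b, n_perm = 5000L, seed = 1L) {
  na <- length(a); nb <- length(b)
  if (na + nb < 4L) stop("combined sample size must be >= 4")
  pool <- c(a, b)
  if (stats::sd(pool) == 0)
    return(structure(list(p = 1, observed = 0, n_perm = 0L, exhaustive = TRUE),
                     class = "perm_test"))
  obs <- mean(b) - mean(a)
  n <- na + nb
  total <- choose(n, na)
  if (total <= n_perm) {
    idx <- utils::combn(n, na)
    tot_sum <- sum(pool)
    a_sums <- colSums(matrix(pool[idx], nrow = na))
    diffs <- (tot_sum - a_sums) / nb - a_sums / na
    p <- sum(abs(diffs) >= abs(obs) - 1e-12) / total
    return(structure(list(p = p, observed = obs, n_perm = as.integer(total),
                          exhaustive = TRUE), class = "perm_test"))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  tot_sum <- sum(pool)
  cnt <- 0L
  block <- 1000L
  done <- 0L
  while (done < n_perm) {
    nbk <- min(block, n_perm - done)
    sel <- matrix(0, n, nbk)
    for (j in seq_len(nbk)) sel[sample.int(n, na), j] <- 1
    a_sums <- colSums(sel * pool)
    diffs <- (tot_sum - a_sums) / nb - a_sums / na
    cnt <- cnt + sum(abs(diffs) >= abs(obs) - 1e-12)
    done <- done + nbk
  }
  structure(list(p = (1 + cnt) / (n_perm + 1), observed = obs,
                 n_perm = as.integer(n_perm), exhaustive = FALSE),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("perm_test: p = %.4g (%s, %d arrangement(s)), observed diff %.4g\n",
              x$p, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_perm, x$observed))
  invisible(x)
}

#' Combined effect-size report
#'
#' Convenience wrapper pairing the bootstrap mean-difference interval with
#' the permutation p-value (and a rank-sum p-value via [stats::wilcox.test]
#' as conventional plumbing).
#'
#' @inheritParams bootstrap_mean_diff
#' @param n_perm permutations for [permutation_pvalue()].
#' @return list of class `estimation_report`.
#' @export
estimation_report <- function(a, b, n_boot = 5000L, ci_level = 0.95,
                              n_perm = 5000L, seed = 1L) {
  es <- bootstrap_mean_diff(a, b, n_boot, ci_level, seed)
  pt <- permutation_pvalue(a, b, n_perm, seed)
  wx <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  structure(list(effect = es, perm = pt, wilcoxon_p = wx), class = "estimation_report")
}

#' @export
print.estimation_report <- function(x, ...) {
  print(x$effect)
  print(x$perm)
  cat(sprintf("wilcoxon rank-sum p = %.4g\n", x$wilcoxon_p))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
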