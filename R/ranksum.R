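## Wilcoxon-Mann-Whitney two-sample rank test, and the chained-vs-single
## proximity analysis with label randomization.

#' Two-sample Wilcoxon-Mann-Whitney rank-sum test
#'
#' Tests the null that the two samples come from the same distribution.
#' For small samples (total n <= `exact_max`) the two-sided p-value is
#' computed by exhaustive enumeration over all `choose(n, n1)` assignments of
#' the (mid)ranks, with the doubling rule `p = min(1, 2 min(P(W <= w),
#' P(W >= w)))`. For larger samples a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples (neighbour counts, angles, ...).
#' @param exact_max Maximum total sample size for the exact enumeration path.
#' @return List with `statistic` (rank-sum W of `x`), `u` (Mann-Whitney U of
#'   `x`), `p_value`, `method` ("exact" or "normal"), `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, exact_max = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    return(list(statistic = NA_real_, u = NA_real_, p_value = NA_real_,
                method = "undefined", n1 = length(x), n2 = length(y)))
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))           # midranks under ties
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2

  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p_le <- mean(sums <= w + 1e-9)
    p_ge <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(statistic = w, u = u, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Compare neighbour counts of chained vs single MTs across search radii
#'
#' For each search radius, counts for every MT the neighbouring MTs within
#' that center-to-center radius, splits MTs into chained (chain size >= 2)
#' and single groups using the chain partition, and applies the two-sample
#' rank-sum test. MTs may be pooled across fibers by concatenating their
#' cross-section tables and partitions.
#'
#' @param points Data frame with `x_nm`, `y_nm` (one row per MT, aligned with
#'   `chained`), or a list of such data frames (one per fiber).
#' @param chained Logical vector (or list of vectors) marking chained MTs.
#' @param radii_nm Search radii; default 20-120 nm in 10 nm steps.
#' @return Tibble with one row per radius: `radius_nm`, `n_chained`,
#'   `n_single`, `median_chained`, `median_single`, `statistic`, `p_value`,
#'   `method`. Radii where either group is empty have `NA` p-values.
#' @export
chained_vs_single_test <- function(points, chained, radii_nm = seq(20, 120, by = 10)) {
  if (is.data.frame(points)) {
    points <- list(points); chained <- list(chained)
  }
  stopifnot(length(points) == length(chained))
  rows <- lapply(radii_nm, function(r) {
    counts_c <- numeric(0); counts_s <- numeric(0)
    for (i in seq_along(points)) {
      cnt <- neighbor_counts(points[[i]], radius_nm = r)$count
      ch <- chained[[i]]
      counts_c <- c(counts_c, cnt[ch])
      counts_s <- c(counts_s, cnt[!ch])
    }
    ts <- rank_sum_test(counts_c, counts_s)
    tibble::tibble(
      radius_nm = r,
      n_chained = length(counts_c), n_single = length(counts_s),
      median_chained = if (length(counts_c)) stats::median(counts_c) else NA_real_,
      median_single = if (length(counts_s)) stats::median(counts_s) else NA_real_,
      statistic = ts$statistic, p_value = ts$p_value, method = ts$method
    )
  })
  do.call(rbind, rows)
}

#' Randomize chain membership and repeat the proximity analysis
#'
#' Permutes the chained/single labels uniformly at random (within each fiber,
#' preserving each fiber's group sizes) and re-runs
#' [chained_vs_single_test()] per permutation. The randomized analysis is the
#' negative control: any chained-vs-single difference should vanish when
#' membership is shuffled.
#'
#' @param points,chained,radii_nm As in [chained_vs_single_test()].
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed (mandatory).
#' @return List with `p_matrix` (`n_permutations` x radii matrix of
#'   p-values), `median_p` (per-radius median randomized p) and `radii_nm`.
#' @export
randomize_membership <- function(points, chained, radii_nm = seq(20, 120, by = 10),
                                 n_permutations = 1000, seed) {
  if (missing(seed)) stop_kf("`seed` is required for membership randomization")
  if (n_permutations < 1) stop_kf("`n_permutations` must be >= 1")
  if (is.data.frame(points)) {
    points <- list(points); chained <- list(chained)
  }
  p_mat <- with_seed(derive_seed(seed, "randomize_membership"), {
    out <- matrix(NA_real_, nrow = n_permutations, ncol = length(radii_nm))
    for (b in seq_len(n_permutations)) {
      perm <- lapply(chained, function(ch) sample(ch))
      res <- chained_vs_single_test(points, perm, radii_nm)
      out[b, ] <- res$p_value
    }
    out
  })
  colnames(p_mat) <- as.character(radii_nm)
  list(p_matrix = p_mat,
       median_p = apply(p_mat, 2, stats::median, na.rm = TRUE),
       radii_nm = radii_nm)
}
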