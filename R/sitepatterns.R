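# Population-level site-pattern tests computed from group allele
# frequencies: the ABBA-BABA D statistic with a block-jackknife Z, and a
# linear site-pattern invariant test for hybrid origin with an
# admixture-proportion (gamma) estimate.

# delete-one block jackknife of a ratio-of-sums statistic.
# num/den: per-marker numerator and denominator contributions.
.jackknife_ratio <- function(num, den, block) {
  n_b <- length(unique(block))
  bn <- rowsum(num, block)
  bd <- rowsum(den, block)
  est <- sum(num) / sum(den)
  loo <- (sum(num) - bn) / (sum(den) - bd)
  se <- sqrt((n_b - 1) / n_b * sum((loo - mean(loo))^2))
  list(est = est, se = se, loo = as.vector(loo), n_blocks = n_b)
}

# delete-one block jackknife of a plain sum
.jackknife_sum <- function(x, block) {
  n_b <- length(unique(block))
  bs <- rowsum(x, block)
  loo <- sum(x) - bs
  sqrt((n_b - 1) / n_b * sum((loo - mean(loo))^2))
}

.block_index <- function(n, block_size) {
  if (block_size < 1) stop("block_size must be >= 1")
  idx <- ceiling(seq_len(n) / block_size)
  # the delete-one jackknife weights blocks equally, so a short trailing
  # block is folded into its neighbour
  n_b <- max(idx)
  if (n_b > 1L && sum(idx == n_b) < block_size / 2)
    idx[idx == n_b] <- n_b - 1L
  idx
}

#' Population-level ABBA-BABA D statistic
#'
#' Computes Patterson's D from group allele frequencies: for each marker
#' with frequencies `(p1, p2, p3, p4)` in the four groups of `order`,
#' `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3 (1-p4)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`.  Positive D indicates excess
#' allele sharing between P2 and P3.  The standard error comes from a
#' delete-one block jackknife over contiguous blocks of `block_size`
#' markers; `Z = D / SE` with a two-tailed p from the t distribution with
#' `B - 1` degrees of freedom (`B` blocks; at modest block counts the t
#' reference calibrates the test, and with hundreds of blocks it is
#' indistinguishable from the normal).  Markers lacking a
#' frequency in any of the four groups (insufficient call rate) are
#' dropped; no outgroup polarization is required.
#'
#' @param summary a [summarize_groups()] result.
#' @param order the four group labels in `(P1, P2, P3, Outgroup)` order;
#'   default `c("C", "D", "O", "A")`.
#' @param block_size markers per jackknife block (default 500).
#' @return A `d_result` with fields `d`, `se`, `z`, `p_value`,
#'   `n_markers`, `n_blocks`, `block_size` and the per-block D values.
#' @export
dstat <- function(summary, order = c("C", "D", "O", "A"),
                  block_size = 500) {
  stopifnot(inherits(summary, "group_allele_summary"))
  if (length(order) != 4L || !all(order %in% colnames(summary$freq)))
    stop("order must name four groups present in the summary")
  keep <- rowSums(summary$state[, order, drop = FALSE] ==
                    "insufficient") == 0L
  f <- summary$freq[keep, order, drop = FALSE]
  n <- nrow(f)
  if (n == 0L) stop("no markers with frequencies in all four groups")
  abba <- (1 - f[, 1]) * f[, 2] * f[, 3] * (1 - f[, 4])
  baba <- f[, 1] * (1 - f[, 2]) * f[, 3] * (1 - f[, 4])
  block <- .block_index(n, block_size)
  if (length(unique(block)) < 2L)
    stop("need at least two jackknife blocks; lower block_size")
  den_total <- sum(abba + baba)
  if (den_total == 0)
    return(structure(list(d = NA_real_, se = NA_real_, z = NA_real_,
                          p_value = NA_real_, n_markers = n,
                          n_blocks = length(unique(block)),
                          block_size = block_size, block_d = NULL,
                          note = "undefined: sum(ABBA + BABA) = 0"),
                     class = "d_result"))
  jk <- .jackknife_ratio(abba - baba, abba + baba, block)
  z <- jk$est / jk$se
  block_d <- as.vector(rowsum(abba - baba, block) /
                         rowsum(abba + baba, block))
  structure(list(d = jk$est, se = jk$se, z = z,
                 p_value = 2 * pt(-abs(z), df = jk$n_blocks - 1L),
                 n_markers = n, n_blocks = jk$n_blocks,
                 block_size = block_size, block_d = block_d,
                 order = order),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf(
    "ABBA-BABA: D = %.4f, Z = %.2f, two-tailed p = %.3g (%d markers, %d blocks)\n",
    x$d, x$z, x$p_value, x$n_markers, x$n_blocks))
  invisible(x)
}

#' Site-pattern invariant test for hybrid origin with gamma estimate
#'
#' For the quartet `(Outgroup, P1, Hybrid, P2)` and outgroup-polarized
#' derived-allele frequencies, accumulates the frequency-weighted
#' site-pattern sums `f_ABBA` (P1 and the hybrid share the derived
#' allele), `f_AABB` (hybrid and P2 share it) and `f_ABAB` (P1 and P2
#' share it - the ILS baseline, equal in expectation to whichever of the
#' other two carries no admixture signal).  The admixture proportion of
#' the hybrid from the P2 side is estimated by the linear invariant
#' `gamma = (f_AABB - f_ABAB) / ((f_ABBA - f_ABAB) + (f_AABB - f_ABAB))`,
#' and `H0: f_AABB - f_ABAB = 0` is tested one-sided (>0) with a block
#' jackknife Z (p from the upper tail of t with `B - 1` degrees of
#' freedom, as in [dstat()]).  Markers unpolarizable by the outgroup are
#' excluded.
#'
#' @param summary a [summarize_groups()] result.
#' @param quartet group labels in `(Outgroup, P1, Hybrid, P2)` order;
#'   default `c("A", "C", "D", "O")` so gamma is the contribution from the
#'   O side.
#' @param block_size markers per jackknife block.
#' @return A `hyde_result` with `gamma` (clamped to `[0, 1]`),
#'   `gamma_raw`, `z`, `p_value` (upper tail), and the three pattern sums.
#' @export
hybrid_invariant_test <- function(summary, quartet = c("A", "C", "D", "O"),
                                  block_size = 500) {
  stopifnot(inherits(summary, "group_allele_summary"))
  if (length(quartet) != 4L || !all(quartet %in% colnames(summary$freq)))
    stop("quartet must name four groups present in the summary")
  p1g <- quartet[2]; hg <- quartet[3]; p2g <- quartet[4]
  keep <- summary$polarizable &
    rowSums(summary$state[, c(p1g, hg, p2g), drop = FALSE] ==
              "insufficient") == 0L
  d <- summary$derived[keep, , drop = FALSE]
  n <- nrow(d)
  if (n == 0L) stop("no polarizable markers with complete frequencies")
  p1 <- d[, p1g]; ph <- d[, hg]; p2 <- d[, p2g]
  abba <- p1 * ph * (1 - p2)        # P1 + hybrid derived
  aabb <- (1 - p1) * ph * p2        # hybrid + P2 derived
  abab <- p1 * (1 - ph) * p2        # P1 + P2 derived (ILS baseline)
  block <- .block_index(n, block_size)
  if (length(unique(block)) < 2L)
    stop("need at least two jackknife blocks; lower block_size")
  num2 <- sum(aabb) - sum(abab)     # signal toward P2
  num1 <- sum(abba) - sum(abab)     # signal toward P1
  denom <- num1 + num2
  gamma_raw <- if (denom == 0) NA_real_ else num2 / denom
  se <- .jackknife_sum(aabb - abab, block)
  z <- if (se > 0) num2 / se else NA_real_
  n_b <- length(unique(block))
  structure(list(gamma = if (is.na(gamma_raw)) NA_real_
                         else min(1, max(0, gamma_raw)),
                 gamma_raw = gamma_raw,
                 z = z,
                 p_value = pt(z, df = n_b - 1L, lower.tail = FALSE),
                 f_abba = sum(abba), f_aabb = sum(aabb),
                 f_abab = sum(abab),
                 n_markers = n, n_blocks = length(unique(block)),
                 block_size = block_size, quartet = quartet),
            class = "hyde_result")
}

#' @export
print.hyde_result <- function(x, ...) {
  cat(sprintf(
    "Hybrid invariant test (quartet %s): gamma = %s, Z = %.2f, one-tailed p = %.3g\n",
    paste(x$quartet, collapse = ","),
    if (is.na(x$gamma)) "undefined" else sprintf("%.3f", x$gamma),
    x$z, x$p_value))
  cat(sprintf("  f_ABBA = %.1f, f_AABB = %.1f, f_ABAB = %.1f (%d markers)\n",
              x$f_abba, x$f_aabb, x$f_abab, x$n_markers))
  invisible(x)
}

#' Upper-tail standard normal probability
#'
#' The one-tailed p value attached to a Z statistic.
#'
#' @param z a finite Z score.
#' @return `P(N(0,1) > z)`.
#' @examples
#' z_to_one_tailed_p(0)     # 0.5
#' z_to_one_tailed_p(4.00)  # ~3.17e-05
#' @export
z_to_one_tailed_p <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) stop("z must be finite")
  pnorm(z, lower.tail = FALSE)
}
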