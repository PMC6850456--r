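#' @importFrom dplyr .data
#' @importFrom grDevices chull
NULL

.summarise_draws <- function(parameter, draws) {
  ci <- unname(quantile(draws, c(0.025, 0.975)))
  s <- tibble::tibble(parameter = parameter,
                      mean_difference = mean(draws),
                      ci_low = ci[1], ci_high = ci[2])
  s$significant <- is_significant(s)
  s
}

# Dirichlet draws via independent gammas, one row per draw.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Posterior for the difference of two multinomial proportion vectors
#'
#' Conjugate model: each count vector gets an independent Dirichlet
#' posterior (prior pseudo-count `alpha` per component), and the
#' per-component difference in proportions (second minus first) is
#' summarised from Monte-Carlo draws by its mean and central 95% credible
#' interval. A component is significant when 0 lies outside its interval.
#'
#' @param counts_a,counts_b Non-negative integer vectors of equal length.
#' @param alpha Prior pseudo-count per component (default 1, the uniform
#'   Dirichlet).
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed for reproducibility.
#' @param labels Component labels; defaults to names of `counts_a` or
#'   positional labels.
#' @return Tibble with one row per component: `parameter`,
#'   `mean_difference`, `ci_low`, `ci_high`, `significant`.
#' @export
multinomial_diff_posterior <- function(counts_a, counts_b, alpha = 1,
                                       n_draws = 10000, seed = NULL,
                                       labels = NULL) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors must have equal length", call. = FALSE)
  if (any(counts_a < 0) || any(counts_b < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be at least 1", call. = FALSE)
  if (is.null(labels))
    labels <- if (!is.null(names(counts_a))) names(counts_a) else
      paste0("component_", seq_along(counts_a))
  if (!is.null(seed)) set.seed(seed)
  pa <- .rdirichlet(n_draws, counts_a + alpha)
  pb <- .rdirichlet(n_draws, counts_b + alpha)
  diff <- pb - pa
  dplyr::bind_rows(lapply(seq_along(labels), function(i)
    .summarise_draws(labels[i], diff[, i])))
}

#' Posterior for the difference of two binomial proportions
#'
#' Conjugate Beta model: `p_a ~ Beta(k_a + prior[1], n_a - k_a + prior[2])`
#' and likewise for `p_b`; the difference `p_b - p_a` is summarised from
#' Monte-Carlo draws by its mean and central 95% credible interval.
#'
#' @param k_a,n_a,k_b,n_b Successes and trials for the two samples.
#' @param prior Beta prior shape pair; default `c(1, 1)` (uniform).
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed.
#' @param label Parameter label for the output row.
#' @return One-row tibble as in [multinomial_diff_posterior()].
#' @export
binomial_diff_posterior <- function(k_a, n_a, k_b, n_b, prior = c(1, 1),
                                    n_draws = 10000, seed = NULL,
                                    label = "proportion") {
  if (k_a > n_a || k_b > n_b || k_a < 0 || k_b < 0)
    stop("need 0 <= k <= n for both samples", call. = FALSE)
  if (any(prior <= 0)) stop("prior shapes must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pa <- rbeta(n_draws, k_a + prior[1], n_a - k_a + prior[2])
  pb <- rbeta(n_draws, k_b + prior[1], n_b - k_b + prior[2])
  .summarise_draws(label, pb - pa)
}

#' Is a posterior difference significant?
#'
#' A difference is significant when 0 falls outside the 95% credible
#' interval. Zero exactly on an interval bound is not significant (closed
#' interval), a probability-zero event under continuous posteriors.
#'
#' @param summary Data frame with `ci_low` and `ci_high` columns.
#' @return Logical vector.
#' @export
is_significant <- function(summary) {
  summary$ci_low > 0 | summary$ci_high < 0
}
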