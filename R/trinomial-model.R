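#' Model configuration
#'
#' Houses the prior on the internal branch length \eqn{\lambda} (coalescent
#' time units) of the species tree underlying a between-species triple:
#' \eqn{\pi(\lambda) = 1/L} on \eqn{[0, L]}. The default `L = 5` spans
#' dominant-triplet frequencies from 1/3 (panmixia) up to
#' \eqn{1 - (2/3)e^{-5} \approx 0.996}. The six candidate species-tree models
#' per triple carry the fixed prior \eqn{\pi(\tau) = 1/6}.
#'
#' @param L Upper bound of the uniform prior on lambda; must be positive.
#' @param quadrature_tol Relative tolerance of the adaptive quadrature used
#'   for the zero-minority-count branch of the marginal likelihood (and by
#'   test oracles); in `(0, 1e-6]`.
#' @return A `model_config` list.
#' @export
model_config <- function(L = 5, quadrature_tol = 1e-9) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            quadrature_tol > 0, quadrature_tol <= 1e-6)
  structure(list(L = L, quadrature_tol = quadrature_tol),
            class = "model_config")
}

as_counts_matrix <- function(counts) {
  if (inherits(counts, "triplet_table")) counts <- counts$counts
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == 3L, all(counts >= 0))
  counts
}

#' Within-species (uniform trinomial) log likelihood
#'
#' Probability of triplet counts when the three samples belong to one
#' panmictic species: every topology is equally likely, so
#' \eqn{P_W(n_1,n_2,n_3) = \frac{N!}{n_1!n_2!n_3!} (1/3)^N} with
#' \eqn{N = n_1+n_2+n_3}. Computed in log space via log-gamma.
#'
#' @param counts Length-3 vector `(n1, n2, n3)`, a `T x 3` matrix, or a
#'   `triplet_table` (its `counts` are used). Vectorized over rows.
#' @return Log probability (one value per row).
#' @examples
#' exp(log_pw(c(2, 1, 0)))  # 1/9
#' @export
log_pw <- function(counts) {
  m <- as_counts_matrix(counts)
  N <- rowSums(m)
  lgamma(N + 1) - rowSums(lgamma(m + 1)) - N * log(3)
}

#' Between-species (skewed trinomial) log likelihood
#'
#' When the three samples span two or three species separated by an internal
#' branch of length `lam` coalescent units, the topology congruent with the
#' species tree (the dominant topology, slot `dominant`) has probability
#' \eqn{1 - (2/3)e^{-\lambda}} and each incongruent topology has probability
#' \eqn{(1/3)e^{-\lambda}}.
#'
#' @inheritParams log_pw
#' @param lam Internal branch length in coalescent units, `>= 0`.
#' @param dominant Index in `1:3` of the dominant-topology slot.
#' @return Log probability (one value per row).
#' @export
log_pb <- function(counts, lam, dominant) {
  m <- as_counts_matrix(counts)
  stopifnot(length(lam) == 1L, lam >= 0, dominant %in% 1:3)
  N <- rowSums(m)
  nv <- m[, dominant]
  lcoef <- lgamma(N + 1) - rowSums(lgamma(m + 1))
  # log(1 - (2/3)e^-lam) computed stably near lam = 0
  lp_dom <- log1p(-(2 / 3) * exp(-lam))
  lcoef + nv * lp_dom + (N - nv) * (log(1 / 3) - lam)
}

#' Marginal likelihood of the one-species models
#'
#' Under a within-species model the likelihood does not involve
#' \eqn{\lambda}, so integrating over the uniform prior is trivial:
#' \eqn{\int_0^L P_W(X)\, d\lambda = L \cdot P_W(X)}.
#'
#' @inheritParams log_pw
#' @param cfg A [model_config()].
#' @return `log(L) + log_pw(counts)` per row.
#' @export
log_marginal_w <- function(counts, cfg = model_config()) {
  log(cfg$L) + log_pw(counts)
}

#' Marginal likelihood of one between-species model
#'
#' Integrates the skewed trinomial likelihood over the uniform prior on
#' \eqn{\lambda}. With the substitution \eqn{x = (2/3)e^{-\lambda}} the
#' integral has the closed form
#' \deqn{\left(\tfrac12\right)^{a} C \left\{\beta(2/3;\, a,\, n_\nu + 1) -
#'   \beta(\tfrac23 e^{-L};\, a,\, n_\nu + 1)\right\},}
#' where \eqn{a = N - n_\nu} is the total minority count, \eqn{C} the
#' multinomial coefficient and \eqn{\beta(x; a, b)} the non-regularized
#' incomplete beta integral. When \eqn{a = 0} the incomplete beta is not
#' defined; the integrand \eqn{(1-x)^{n_\nu} x^{-1}} is then integrated
#' directly over \eqn{[(2/3)e^{-L},\, 2/3]} by adaptive quadrature (finite
#' because the lower limit is strictly positive), cached by \eqn{N}.
#'
#' @inheritParams log_pb
#' @param cfg A [model_config()].
#' @return Log of \eqn{\int_0^L P_B(X \mid \lambda, \nu)\, d\lambda} per row.
#' @export
log_marginal_b <- function(counts, dominant, cfg = model_config()) {
  m <- as_counts_matrix(counts)
  stopifnot(dominant %in% 1:3)
  N <- rowSums(m)
  nv <- m[, dominant]
  a <- N - nv            # minority total
  b <- nv + 1
  lcoef <- lgamma(N + 1) - rowSums(lgamma(m + 1))
  x_hi <- 2 / 3
  x_lo <- (2 / 3) * exp(-cfg$L)
  out <- numeric(nrow(m))

  pos <- which(a > 0)
  if (length(pos)) {
    li_hi <- pbeta(x_hi, a[pos], b[pos], log.p = TRUE) + lbeta(a[pos], b[pos])
    li_lo <- pbeta(x_lo, a[pos], b[pos], log.p = TRUE) + lbeta(a[pos], b[pos])
    out[pos] <- lcoef[pos] - a[pos] * log(2) + li_hi +
      log1p(-exp(li_lo - li_hi))
  }
  zer <- which(a == 0)
  if (length(zer)) {
    # marginal depends only on N here (counts are (N,0,0) up to permutation)
    for (Nu in unique(N[zer])) {
      q <- stats::integrate(function(x) (1 - x)^Nu / x, x_lo, x_hi,
                            rel.tol = cfg$quadrature_tol)
      out[zer[N[zer] == Nu]] <- log(q$value)
    }
  }
  out
}

#' Per-triplet posterior of one species vs several
#'
#' Bayesian comparison of six equally weighted candidate models per triple:
#' three within-species models (uniform trinomial, jointly the delimitation
#' `W`) and three between-species models (skewed trinomial, one per candidate
#' dominant topology, jointly `B`). Summing over all three candidate dominant
#' topologies rather than conditioning on the observed majority topology
#' corrects for the unknown species tree; conditioning on the majority is
#' biased toward splitting and inflates false positives.
#'
#' \deqn{P(B \mid X) = \frac{\sum_{\nu} \int_0^L P_B(X \mid \lambda, \nu)
#'   d\lambda}{\sum_{\nu} \int_0^L P_B(X \mid \lambda, \nu) d\lambda +
#'   3 L P_W(X)}, \qquad P(W \mid X) = 1 - P(B \mid X).}
#'
#' @inheritParams log_pw
#' @param cfg A [model_config()].
#' @return A list with numeric vectors `log_post_W` and `log_post_B` (one
#'   entry per row of `counts`).
#' @examples
#' p <- triplet_posterior(c(20, 1, 0))
#' exp(p$log_post_B)  # close to 1: strongly skewed counts
#' @export
triplet_posterior <- function(counts, cfg = model_config()) {
  m <- as_counts_matrix(counts)
  lb <- vapply(1:3, function(v) log_marginal_b(m, v, cfg), numeric(nrow(m)))
  if (is.null(dim(lb))) lb <- matrix(lb, nrow = 1L)
  log_evid_b <- row_logsumexp(lb)
  log_evid_w <- log(3) + log_marginal_w(m, cfg)
  log_z <- log_add(log_evid_b, log_evid_w)
  list(log_post_W = log_evid_w - log_z, log_post_B = log_evid_b - log_z)
}

#' Posterior score of a delimitation
#'
#' Additive log-posterior score of a partition of the samples into putative
#' species: each triple contributes its `log P(W | X)` when its three samples
#' share a species and its `log P(B | X)` otherwise. The score is a composite
#' objective (triples overlap, so it is not a true posterior probability of
#' the delimitation); the delimitation maximizing it is reported.
#'
#' @param table A `triplet_table` from [count_triplets()].
#' @param partition Assignment of samples to species: a named vector
#'   (names = samples, values = species identifiers) or a list of disjoint
#'   character vectors covering the samples.
#' @param cfg A [model_config()].
#' @param post Optional precomputed `triplet_posterior(table, cfg)`, to avoid
#'   recomputation when scoring many partitions of one table.
#' @return The log score (a single number).
#' @export
partition_score <- function(table, partition, cfg = model_config(),
                            post = NULL) {
  stopifnot(inherits(table, "triplet_table"))
  partition <- as_partition(partition, table$samples)
  if (is.null(post)) post <- triplet_posterior(table$counts, cfg)
  sp <- match(partition[table$samples], unique(partition))
  same <- sp[table$triples[, 1]] == sp[table$triples[, 2]] &
    sp[table$triples[, 2]] == sp[table$triples[, 3]]
  sum(post$log_post_W[same]) + sum(post$log_post_B[!same])
}

# normalize a partition to a named vector over exactly `samples`
as_partition <- function(partition, samples) {
  if (is.list(partition)) {
    blocks <- partition
    partition <- rep(seq_along(blocks), lengths(blocks))
    names(partition) <- unlist(blocks)
  }
  if (is.null(names(partition))) {
    stop("partition must be named by sample", call. = FALSE)
  }
  missing <- setdiff(samples, names(partition))
  if (length(missing)) {
    stop("samples missing from partition: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(partition))) {
    stop("sample assigned more than once in partition", call. = FALSE)
  }
  partition[samples]
}
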