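test_that("uniform trinomial log likelihood matches exact arithmetic", {
  expect_equal(log_pw(c(0, 0, 0)), 0)
  expect_equal(log_pw(c(2, 1, 0)), log(1 / 9))
  # 15!/(5!5!5!) = 756756; 3^15 = 14348907 (exact rational oracle)
  expect_equal(log_pw(c(5, 5, 5)), log(756756 / 14348907))
  # symmetric in the three slots
  expect_equal(log_pw(c(4, 2, 7)), log_pw(c(7, 4, 2)))
})

test_that("skewed trinomial likelihood: endpoints and direct evaluation", {
  expect_equal(log_pb(c(1, 0, 0), log(2), 1), log(2 / 3))
  # lambda = 0 collapses to the uniform model
  for (cnts in list(c(3, 2, 1), c(10, 0, 0), c(0, 0, 0))) {
    expect_equal(log_pb(cnts, 0, 1), log_pw(cnts))
  }
  # extended-precision style direct evaluation, written out independently
  cnts <- c(8, 1, 1)
  direct <- lgamma(11) - lgamma(9) - lgamma(2) - lgamma(2) +
    8 * log(1 - (2 / 3) * exp(-1)) + 2 * log((1 / 3) * exp(-1))
  expect_equal(log_pb(cnts, 1, 1), direct, tolerance = 1e-12)
  expect_error(log_pb(c(1, 0, 0), -0.5, 1), "lam")
})

test_that("within-species marginal is L times the likelihood", {
  cfg <- model_config(L = 5)
  expect_equal(log_marginal_w(c(0, 0, 0), cfg), log(5))
  expect_equal(log_marginal_w(c(2, 1, 0), cfg), log(5 / 9))
  expect_equal(log_marginal_w(c(3, 4, 5), model_config(L = 1)),
               log_pw(c(3, 4, 5)))
})

test_that("incomplete-beta marginal agrees with the lambda-space quadrature oracle", {
  cfg <- model_config(L = 5)
  cases <- list(c(3, 2, 1), c(10, 0, 0), c(0, 0, 0), c(20, 1, 0),
                c(7, 7, 6), c(0, 0, 40), c(1, 1, 1))
  for (cnts in cases) {
    for (v in 1:3) {
      expect_equal(log_marginal_b(cnts, v, cfg),
                   quad_marginal_b(cnts, v, L = 5),
                   tolerance = 1e-7,
                   label = sprintf("counts (%s), nu = %d",
                                   paste(cnts, collapse = ","), v))
    }
  }
  # empty data: likelihood is 1 over the whole prior
  expect_equal(log_marginal_b(c(0, 0, 0), 2, cfg), log(5), tolerance = 1e-9)
  # invariant under swapping the two minority slots
  expect_equal(log_marginal_b(c(9, 3, 1), 1, cfg),
               log_marginal_b(c(9, 1, 3), 1, cfg))
})

test_that("posteriors normalize and match the full quadrature oracle", {
  p0 <- triplet_posterior(c(0, 0, 0))
  expect_equal(exp(p0$log_post_W), 0.5, tolerance = 1e-12)
  expect_equal(exp(p0$log_post_B), 0.5, tolerance = 1e-12)

  for (cnts in list(c(20, 0, 0), c(7, 7, 6), c(5, 3, 2), c(0, 15, 1))) {
    p <- triplet_posterior(cnts)
    o <- quad_posterior(cnts)
    expect_equal(exp(p$log_post_W) + exp(p$log_post_B), 1, tolerance = 1e-10)
    expect_equal(exp(p$log_post_B), o$post_B, tolerance = 1e-7)
  }
  expect_gt(exp(triplet_posterior(c(20, 0, 0))$log_post_B), 0.99)
  expect_gt(exp(triplet_posterior(c(7, 7, 6))$log_post_W), 0.5)
})

test_that("posterior limits under deterministic count ladders", {
  # fixed skewed proportions, growing N: B wins
  pb <- vapply(c(5, 20, 80), function(n) {
    exp(triplet_posterior(c(3 * n, n, n))$log_post_B)
  }, numeric(1))
  expect_true(all(diff(pb) > 0))
  expect_gt(pb[3], 0.999)
  # exact uniformity, growing N: W wins
  pw <- vapply(c(5, 20, 80), function(n) {
    exp(triplet_posterior(c(n, n, n))$log_post_W)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[3], 0.95)
})

test_that("partition score adds the right per-triple terms", {
  cfg <- model_config()
  tab <- make_table(c("a", "b", "c"), matrix(c(1L, 0L, 0L), 1))
  post <- triplet_posterior(tab$counts, cfg)
  expect_equal(partition_score(tab, c(a = 1, b = 1, c = 1), cfg),
               post$log_post_W[1])
  expect_equal(partition_score(tab, c(a = 1, b = 1, c = 2), cfg),
               post$log_post_B[1])

  # K = 4: additivity over the four triples, list-of-blocks input
  set.seed(41)
  tab4 <- random_table(4)
  post4 <- triplet_posterior(tab4$counts, cfg)
  part <- list(c("s01", "s02"), c("s03", "s04"))
  sp <- c(s01 = 1, s02 = 1, s03 = 2, s04 = 2)
  same <- apply(matrix(sp[tab4$samples[tab4$triples]], ncol = 3), 1,
                function(z) length(unique(z)) == 1)
  expect_equal(partition_score(tab4, part, cfg),
               sum(post4$log_post_W[same]) + sum(post4$log_post_B[!same]))
  # all-singletons: every triple crosses species
  singles <- list("s01", "s02", "s03", "s04")
  expect_equal(partition_score(tab4, singles, cfg), sum(post4$log_post_B))
  expect_error(partition_score(tab4, list(c("s01", "s02"))), "missing")
})

test_that("model configuration is validated", {
  expect_error(model_config(L = 0), "L")
  expect_error(model_config(quadrature_tol = 1e-3), "quadrature_tol")
  expect_equal(model_config(L = 2)$L, 2)
})
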