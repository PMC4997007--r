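# In-code fixture builders shared across test files.

# A triplet_table with arbitrary non-negative counts, matching the internal
# layout produced by count_triplets().
make_table <- function(samples, counts = NULL, n_loci = NULL) {
  samples <- sort(samples)
  triples <- t(utils::combn(length(samples), 3L))
  storage.mode(triples) <- "integer"
  if (is.null(counts)) counts <- matrix(0L, nrow(triples), 3L)
  storage.mode(counts) <- "integer"
  structure(
    list(samples = samples, triples = triples, counts = counts,
         n_loci = if (is.null(n_loci)) max(rowSums(counts)) else n_loci),
    class = "triplet_table"
  )
}

random_table <- function(n_samples, lambda = 4) {
  samples <- paste0("s", sprintf("%02d", seq_len(n_samples)))
  n_tri <- choose(n_samples, 3)
  counts <- matrix(rpois(3L * n_tri, lambda), n_tri, 3L)
  make_table(samples, counts)
}

# random binary rooted tree over given labels (ape::rtree topology)
random_guide <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels), br = NULL)
}

# quadrature oracle for the between-species marginal: integrate the skewed
# trinomial likelihood over lambda in [0, L]. The integrand is scaled by its
# grid maximum first so that adaptive quadrature works at machine precision
# even when the marginal is astronomically small (large N).
quad_marginal_b <- function(counts, dominant, L = 5, rel.tol = 1e-10) {
  lp <- function(l) {
    vapply(l, function(li) log_pb(counts, li, dominant), numeric(1))
  }
  M <- max(lp(seq(0, L, length.out = 2001)))
  M + log(stats::integrate(function(l) exp(lp(l) - M), 0, L,
                           rel.tol = rel.tol)$value)
}

# exhaustive posterior oracle built on the quadrature marginals
quad_posterior <- function(counts, L = 5) {
  lb <- vapply(1:3, function(v) quad_marginal_b(counts, v, L), numeric(1))
  m <- max(lb)
  log_evid_b <- m + log(sum(exp(lb - m)))
  log_evid_w <- log(3 * L) + log_pw(counts)
  z <- max(log_evid_b, log_evid_w) +
    log(exp(log_evid_b - max(log_evid_b, log_evid_w)) +
        exp(log_evid_w - max(log_evid_b, log_evid_w)))
  list(post_W = exp(log_evid_w - z), post_B = exp(log_evid_b - z))
}

# rooted binarity of a phylo (every internal node has exactly two children)
is_binary_rooted_tree <- function(tree) {
  kids <- tabulate(tree$edge[, 1], nbins = ape::Ntip(tree) + tree$Nnode)
  all(kids[kids > 0] == 2L)
}

# rooted topological identity via the clade-set comparison
same_topology <- function(a, b) {
  clades <- function(t) {
    pp <- ape::prop.part(t)
    sort(vapply(pp, function(i) {
      paste(sort(attr(pp, "labels")[i]), collapse = "+")
    }, character(1)))
  }
  identical(clades(a), clades(b))
}
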