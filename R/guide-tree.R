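#' Build a guide tree from majority triplets
#'
#' Constructs a rooted binary tree over all samples from the modal (most
#' frequently observed) topology of each triple, by the Aho BUILD recursion:
#' each modal triplet `ab|c` constrains `a` and `b` to join below the point
#' where `c` attaches. At each recursion step, samples are connected whenever
#' a constraint pairs them; connected components become the children of the
#' current node. When the constraints are mutually incompatible (a single
#' component), the lowest-margin constraints — margin being the modal count
#' minus the runner-up count — are dropped until the component disconnects,
#' so weakly supported triplets yield first. Regions with no remaining signal
#' produce polytomies, which are resolved uniformly at random under `seed`.
#'
#' The builder plays the role of a rooted-triple consensus: when the modal
#' triplets are jointly compatible with a binary tree, that tree is returned.
#'
#' @param table A `triplet_table` from [count_triplets()].
#' @param seed Integer seed for resolving polytomies and incompatibility
#'   ties, or `NULL` to use the current RNG stream.
#' @param min_margin Triples whose modal margin is not above this value are
#'   ignored (default 0: any uniquely modal topology is used).
#' @return A binary rooted `phylo` over the table's samples.
#' @examples
#' trees <- replicate(10, parse_newick("((a,b),(c,d));"), simplify = FALSE)
#' write_newick(build_guide_tree(count_triplets(trees), seed = 1))
#' @export
build_guide_tree <- function(table, seed = NULL, min_margin = 0) {
  stopifnot(inherits(table, "triplet_table"))
  K <- length(table$samples)
  if (K < 3L) stop("need at least 3 samples", call. = FALSE)

  cnt <- table$counts
  ord <- t(apply(cnt, 1L, order, decreasing = TRUE))
  top <- cnt[cbind(seq_len(nrow(cnt)), ord[, 1])]
  second <- cnt[cbind(seq_len(nrow(cnt)), ord[, 2])]
  margin <- top - second
  keep <- margin > min_margin            # uniquely modal, above threshold
  # constraint rows: (pair1, pair2, outgroup, margin); slot -> pair mapping
  # for sorted triple (a,b,c): 1 = ab|c, 2 = ac|b, 3 = bc|a
  slot_pairs <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
  sl <- ord[keep, 1]
  tr <- table$triples[keep, , drop = FALSE]
  cons <- cbind(
    p1 = tr[cbind(seq_len(nrow(tr)), slot_pairs[sl, 1])],
    p2 = tr[cbind(seq_len(nrow(tr)), slot_pairs[sl, 2])],
    out = tr[cbind(seq_len(nrow(tr)), slot_pairs[sl, 3])]
  )
  w <- margin[keep]

  build <- function(set, cons, w) {
    if (length(set) == 1L) return(table$samples[set])
    if (length(set) == 2L) {
      return(sprintf("(%s,%s)", table$samples[set[1]], table$samples[set[2]]))
    }
    comp <- aho_components(set, cons[, 1], cons[, 2], w)
    groups <- split(set, comp)
    parts <- vapply(groups, function(g) {
      inside <- cons[, 1] %in% g & cons[, 2] %in% g & cons[, 3] %in% g
      build(g, cons[inside, , drop = FALSE], w[inside])
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  run <- function() {
    nwk <- paste0(build(seq_len(K), cons, w), ";")
    tree <- ape::read.tree(text = nwk)
    if (!is_binary_rooted(tree)) tree <- ape::multi2di(tree, random = TRUE)
    tree
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Connected components of the Aho graph over `set`, with incompatibility
# handling: if a single component remains, drop the lowest-margin edge class
# (ties together) and retry until the graph disconnects; with no edges left
# every element is its own component (a polytomy for the caller).
aho_components <- function(set, e1, e2, w) {
  active <- e1 %in% set & e2 %in% set
  repeat {
    comp <- union_find(set, e1[active], e2[active])
    if (length(unique(comp)) > 1L || !any(active)) return(comp)
    wmin <- min(w[active])
    active <- active & w > wmin
  }
}

union_find <- function(set, e1, e2) {
  parent <- seq_along(set)
  idx <- seq_along(set)
  names(idx) <- set
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- idx[as.character(e1)]
  b <- idx[as.character(e2)]
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_along(set), find, integer(1))
}
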