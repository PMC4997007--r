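# Per-node bookkeeping shared by the DP and the cross-score query: for every
# triple, the guide-tree node at which its three tips first meet. Triples
# mapped to node v are exactly those contained in subtree(v) with at least
# one tip in each child of v.
guide_triple_nodes <- function(guide, table) {
  pos <- match(table$samples, guide$tip.label)
  if (anyNA(pos) || length(guide$tip.label) != length(table$samples)) {
    stop("guide-tree tips and table samples differ", call. = FALSE)
  }
  pos[is.na(pos)] <- 0L
  .triple_mrca_cpp(ape::mrca(guide), node_depths(guide), as.integer(pos),
                   table$triples)
}

#' Score of the triples crossing an internal guide-tree node
#'
#' Sum of `log P(B | X)` over every triple whose tips lie within the node's
#' subtree with at least one tip in each of the two child subtrees. This is
#' the constant term that makes the delimitation score decompose over the
#' guide tree: for any delimitation that splits at this node, these crossing
#' triples span species no matter how the two halves are delimited further.
#'
#' @param table A `triplet_table`.
#' @param guide A binary rooted `phylo` over the table's samples.
#' @param node Internal node id (ape numbering: `Ntip+1 ... Ntip+Nnode`).
#' @param cfg A [model_config()].
#' @param post Optional precomputed `triplet_posterior(table, cfg)`.
#' @return Log score (0 when fewer than 3 tips descend from `node`).
#' @export
node_cross_score <- function(table, guide, node, cfg = model_config(),
                             post = NULL) {
  stopifnot(inherits(table, "triplet_table"))
  ntip <- ape::Ntip(guide)
  if (node <= ntip) stop("node is a tip", call. = FALSE)
  if (is.null(post)) post <- triplet_posterior(table$counts, cfg)
  tnode <- guide_triple_nodes(guide, table)
  sum(post$log_post_B[tnode == node])
}

#' Optimal delimitation on a guide tree
#'
#' Exact search, by dynamic programming, over every delimitation expressible
#' as a set of disjoint guide-tree subtrees covering all samples. In
#' postorder, each node `v` compares two hypotheses: LUMP — all samples under
#' `v` are one species, scoring the sum of `log P(W|X)` over triples within
#' `subtree(v)`; or SPLIT — combine the best delimitations of the two
#' children, plus [node_cross_score()] for the triples straddling them. The
#' additivity of the partition score over triples guarantees the recursion is
#' exact, at two score evaluations per node. Exact ties prefer LUMP (fewer
#' species): the model cannot distinguish one species from two species of
#' which each contributes fewer than two samples to any triple, and the
#' method is deliberately conservative against over-splitting.
#'
#' @param guide A binary rooted `phylo`; its tip set must equal the table's
#'   samples. Resolve polytomies first with [resolve_polytomies()].
#' @param table A `triplet_table` from [count_triplets()].
#' @param cfg A [model_config()].
#' @param post Optional precomputed `triplet_posterior(table, cfg)`.
#' @return A `delimitation` object: list with `partition` (named integer
#'   vector, species indexed in tip order), `log_score`, `node_choice`
#'   (per internal node, `"lump"` or `"split"`), `node_margin` (lump minus
#'   split score per internal node, for inspecting near-ties) and `guide`.
#' @examples
#' trees <- replicate(5, parse_newick("((a,b),c);"), simplify = FALSE)
#' tab <- count_triplets(trees)
#' best_delimitation(parse_newick("((a,b),c);"), tab)$partition
#' @export
best_delimitation <- function(guide, table, cfg = model_config(),
                              post = NULL) {
  stopifnot(inherits(table, "triplet_table"))
  validate_rooted_tree(guide)
  if (!is_binary_rooted(guide)) {
    stop("guide tree is not binary; resolve polytomies first ",
         "(see resolve_polytomies())", call. = FALSE)
  }
  if (!setequal(guide$tip.label, table$samples)) {
    stop("guide-tree tips and table samples differ", call. = FALSE)
  }
  if (is.null(post)) post <- triplet_posterior(table$counts, cfg)
  ntip <- ape::Ntip(guide)
  nall <- ntip + guide$Nnode
  tnode <- guide_triple_nodes(guide, table)

  # per-node sums over the triples whose MRCA is that node
  wsum <- bsum <- numeric(nall)
  wagg <- rowsum(post$log_post_W, tnode)
  bagg <- rowsum(post$log_post_B, tnode)
  wsum[as.integer(rownames(wagg))] <- wagg[, 1]
  bsum[as.integer(rownames(bagg))] <- bagg[, 1]

  kids <- vector("list", nall)
  for (e in seq_len(nrow(guide$edge))) {
    kids[[guide$edge[e, 1]]] <- c(kids[[guide$edge[e, 1]]], guide$edge[e, 2])
  }
  lump <- best <- numeric(nall)   # tips: 0
  choice <- rep(NA_character_, nall)
  # visit internal nodes deepest-first so children are solved before parents
  depth <- node_depths(guide)
  internal_po <- ((ntip + 1L):nall)[order(depth[(ntip + 1L):nall],
                                          decreasing = TRUE)]
  for (v in internal_po) {
    ch <- kids[[v]]
    lump[v] <- lump[ch[1]] + lump[ch[2]] + wsum[v]
    split <- best[ch[1]] + best[ch[2]] + bsum[v]
    if (lump[v] >= split) {        # tie -> lump (fewer species)
      best[v] <- lump[v]
      choice[v] <- "lump"
    } else {
      best[v] <- split
      choice[v] <- "split"
    }
  }
  root <- internal_po[length(internal_po)]

  # extract blocks: maximal subtrees whose root is LUMPed with no LUMP above
  species <- integer(ntip)
  next_id <- 0L
  assign_block <- function(v) {
    tips <- subtree_tips(guide, v, kids)
    next_id <<- next_id + 1L
    species[tips] <<- next_id
  }
  walk <- function(v) {
    if (v <= ntip || identical(choice[v], "lump")) assign_block(v)
    else for (ch in kids[[v]]) walk(ch)
  }
  walk(root)
  partition <- species
  names(partition) <- guide$tip.label
  internal <- (ntip + 1L):nall
  margins <- lump[internal] -
    vapply(internal, function(v) {
      ch <- kids[[v]]
      best[ch[1]] + best[ch[2]] + bsum[v]
    }, numeric(1))
  structure(
    list(partition = partition, log_score = best[root],
         node_choice = stats::setNames(choice[internal], internal),
         node_margin = stats::setNames(margins, internal),
         guide = guide),
    class = "delimitation"
  )
}

subtree_tips <- function(guide, v, kids) {
  ntip <- ape::Ntip(guide)
  if (v <= ntip) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u <= ntip) out <- c(out, u)
    else stack <- c(stack, kids[[u]])
  }
  out
}

#' @export
print.delimitation <- function(x, ...) {
  k <- length(unique(x$partition))
  cat(sprintf("delimitation: %d species over %d samples, log score %.4f\n",
              k, length(x$partition), x$log_score))
  for (s in sort(unique(x$partition))) {
    cat(sprintf("  species %d: %s\n", s,
                paste(names(x$partition)[x$partition == s], collapse = " ")))
  }
  invisible(x)
}

#' Enumerate all delimitations compatible with a guide tree
#'
#' Testing oracle: lists every partition of the tips into disjoint guide-tree
#' subtrees, by the recursion `count(v) = 1 + count(left) * count(right)`
#' (`count(tip) = 1`). Grows like `floor(1.5^S)` in the worst (balanced)
#' case, so it refuses trees with more than 20 tips.
#'
#' @param guide A binary rooted `phylo` with at most 20 tips.
#' @return A list of partitions (named integer vectors).
#' @export
enumerate_delimitations <- function(guide) {
  validate_rooted_tree(guide)
  if (!is_binary_rooted(guide)) stop("guide tree is not binary", call. = FALSE)
  ntip <- ape::Ntip(guide)
  if (ntip > 20L) {
    stop("enumeration oracle refuses trees with more than 20 tips",
         call. = FALSE)
  }
  kids <- vector("list", ntip + guide$Nnode)
  for (e in seq_len(nrow(guide$edge))) {
    kids[[guide$edge[e, 1]]] <- c(kids[[guide$edge[e, 1]]], guide$edge[e, 2])
  }
  root <- ntip + 1L
  rec <- function(v) {
    tips <- guide$tip.label[subtree_tips(guide, v, kids)]
    whole <- list(list(tips))             # subtree(v) as a single block
    if (v <= ntip) return(whole)
    left <- rec(kids[[v]][1])
    right <- rec(kids[[v]][2])
    combos <- vector("list", length(left) * length(right))
    i <- 0L
    for (pl in left) for (pr in right) {
      i <- i + 1L
      combos[[i]] <- c(pl, pr)
    }
    c(whole, combos)
  }
  lapply(rec(root), function(blocks) {
    p <- rep(seq_along(blocks), lengths(blocks))
    names(p) <- unlist(blocks)
    p[sort(names(p))]
  })
}
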