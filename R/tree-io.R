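#' Parse a rooted tree from a Newick string
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is taken as
#' rooted exactly as written; no re-rooting is performed. Branch lengths, when
#' present, are preserved but are ignored by the delimitation model, which
#' uses topology only.
#'
#' @param text A single Newick string (terminating `;` optional).
#' @return An object of class `phylo` with unique tip labels.
#' @examples
#' tr <- parse_newick("((a,b),c);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tree <- tryCatch(
    ape::read.tree(text = text),
    warning = function(w) NULL,
    error = function(e) NULL
  )
  if (is.null(tree)) {
    # locate the first structurally surprising character for the message
    bad <- regexpr("[^(),:;_'\". [:alnum:]-]", text)
    stop("malformed Newick string",
         if (bad > 0L) sprintf(" (near position %d: '%s')", bad,
                               substr(text, bad, bad)) else "",
         call. = FALSE)
  }
  validate_rooted_tree(tree)
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @return A single Newick string; `parse_newick(write_newick(t))` preserves
#'   topology, labels and branch lengths to printed precision.
#' @export
write_newick <- function(tree) {
  validate_rooted_tree(tree)
  ape::write.tree(tree)
}

# shared invariant checks for trees entering the pipeline
validate_rooted_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(labs))) stop("empty tip label", call. = FALSE)
  invisible(tree)
}

#' Randomly resolve polytomies
#'
#' Refines every multifurcation into a sequence of bifurcations chosen
#' uniformly at random (the `multi2di` behaviour), introducing zero-length
#' branches where the input carries branch lengths. Binary trees are returned
#' unchanged. Resolution is reproducible given `seed`.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A binary `phylo` whose clade set contains the input's clade set.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  validate_rooted_tree(tree)
  if (is_binary_rooted(tree)) return(tree)
  if (is.null(seed)) return(ape::multi2di(tree, random = TRUE))
  withr::with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Topology of one rooted triplet
#'
#' Classifies the induced rooted subtree of three tips. For the
#' lexicographically sorted triple `(a, b, c)` the three resolved states are
#' `"ab|c"`, `"ac|b"` and `"bc|a"`: the quoted pair is the one whose most
#' recent common ancestor lies strictly below the MRCA of all three tips.
#' `"unresolved"` is returned when all three pairwise MRCAs coincide (a
#' polytomy) and `"missing"` when any label is absent from the tree.
#'
#' @param tree A `phylo` object.
#' @param triple Character vector of three distinct labels, sorted.
#' @return One of `"ab|c"`, `"ac|b"`, `"bc|a"`, `"unresolved"`, `"missing"`.
#' @examples
#' triplet_topology(parse_newick("((a,b),(c,d));"), c("a", "c", "d"))
#' @export
triplet_topology <- function(tree, triple) {
  validate_rooted_tree(tree)
  stopifnot(length(triple) == 3L)
  if (is.unsorted(triple, strictly = TRUE)) {
    stop("triple must be lexicographically sorted and distinct", call. = FALSE)
  }
  idx <- match(triple, tree$tip.label)
  if (anyNA(idx)) return("missing")
  depth <- node_depths(tree)
  m <- ape::mrca(tree)
  d <- c(depth[m[idx[1], idx[2]]],
         depth[m[idx[1], idx[3]]],
         depth[m[idx[2], idx[3]]])
  top <- which(d == max(d))
  if (length(top) > 1L) return("unresolved")
  c("ab|c", "ac|b", "bc|a")[top]
}
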