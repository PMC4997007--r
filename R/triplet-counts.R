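#' Tally rooted-triplet topologies across loci
#'
#' Decomposes the sample set into all `choose(K, 3)` triples and counts, over
#' the gene trees, how many loci support each of the three topologies of each
#' triple. The resulting table of counts `(n1, n2, n3)` is the sufficient
#' statistic consumed by the trinomial delimitation model. Loci from which a
#' tip of a triple is missing contribute nothing to that triple, so each
#' triple carries its own number of informative loci `N <= length(gene_trees)`.
#'
#' Topology slots are fixed by lexicographic pair order relative to the
#' sorted triple `(a, b, c)`: `n1` counts `ab|c`, `n2` counts `ac|b`, `n3`
#' counts `bc|a`.
#'
#' @param gene_trees A list of `phylo` objects (or a `multiPhylo`), one per
#'   locus. Tips may be a subset of `samples`.
#' @param samples Character vector of all sample labels. Defaults to the
#'   union of tip labels over the loci.
#' @param unresolved How a locus in which a triple's three pairwise MRCAs
#'   coincide (a polytomy) contributes: `"skip"` (default; no contribution,
#'   counting is deterministic) or `"random"` (one uniformly chosen slot;
#'   prefer resolving whole trees upstream with [resolve_polytomies()] so
#'   that within-locus correlation among triples is preserved).
#' @param seed Seed used only when `unresolved = "random"`.
#' @return A `triplet_table`: list with `samples` (sorted labels), `triples`
#'   (`T x 3` integer matrix of sample indices, rows sorted), `counts`
#'   (`T x 3` integer matrix) and `n_loci`.
#' @examples
#' trees <- lapply(c("((a,b),c);", "((a,c),b);"), parse_newick)
#' tab <- count_triplets(trees)
#' tab$counts
#' @export
count_triplets <- function(gene_trees, samples = NULL,
                           unresolved = c("skip", "random"), seed = NULL) {
  unresolved <- match.arg(unresolved)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  gene_trees <- lapply(gene_trees, validate_rooted_tree)
  tip_union <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (is.null(samples)) samples <- tip_union
  samples <- sort(unique(as.character(samples)))
  extra <- setdiff(tip_union, samples)
  if (length(extra)) {
    stop("gene-tree tip labels not in samples: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  K <- length(samples)
  if (K < 3L) stop("need at least 3 samples to form triplets", call. = FALSE)
  triples <- t(utils::combn(K, 3L))
  storage.mode(triples) <- "integer"
  counts <- matrix(0L, nrow(triples), 3L)
  policy <- if (unresolved == "random") 1L else 0L
  accumulate <- function() {
    for (tree in gene_trees) {
      pos <- match(samples, tree$tip.label)
      pos[is.na(pos)] <- 0L
      m <- ape::mrca(tree)
      # mrca() rows follow tip order; reindex to 1..Ntip positions
      .count_triplets_cpp(counts, m, node_depths(tree), as.integer(pos),
                          triples, policy)
    }
  }
  if (policy == 1L && !is.null(seed)) withr::with_seed(seed, accumulate())
  else accumulate()
  structure(
    list(samples = samples, triples = triples, counts = counts,
         n_loci = length(gene_trees)),
    class = "triplet_table"
  )
}

#' @export
print.triplet_table <- function(x, ...) {
  cat(sprintf("triplet_table: %d samples, %d triples, %d loci\n",
              length(x$samples), nrow(x$triples), x$n_loci))
  cat(sprintf("informative loci per triple: %d-%d\n",
              min(rowSums(x$counts)), max(rowSums(x$counts))))
  invisible(x)
}

#' Export / import a triplet count table as TSV
#'
#' Columns `triple_a`, `triple_b`, `triple_c`, `n1`, `n2`, `n3`; a stable
#' plain-text fixture format.
#'
#' @param table A `triplet_table`.
#' @param path File path.
#' @return `write_triplet_table` returns `path` invisibly;
#'   `read_triplet_table` returns a `triplet_table` (with `n_loci` set to the
#'   maximum informative-locus count, the file not recording absent loci).
#' @export
write_triplet_table <- function(table, path) {
  stopifnot(inherits(table, "triplet_table"))
  df <- data.frame(
    triple_a = table$samples[table$triples[, 1]],
    triple_b = table$samples[table$triples[, 2]],
    triple_c = table$samples[table$triples[, 3]],
    n1 = table$counts[, 1], n2 = table$counts[, 2], n3 = table$counts[, 3]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplet_table
#' @export
read_triplet_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(rep("character", 3),
                                         rep("integer", 3)))
  samples <- sort(unique(c(df$triple_a, df$triple_b, df$triple_c)))
  triples <- cbind(match(df$triple_a, samples), match(df$triple_b, samples),
                   match(df$triple_c, samples))
  storage.mode(triples) <- "integer"
  ord <- order(triples[, 1], triples[, 2], triples[, 3])
  counts <- as.matrix(df[, c("n1", "n2", "n3")])[ord, , drop = FALSE]
  dimnames(counts) <- NULL
  structure(
    list(samples = samples, triples = triples[ord, , drop = FALSE],
         counts = counts, n_loci = max(rowSums(counts))),
    class = "triplet_table"
  )
}
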