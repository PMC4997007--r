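#' Species-tree model for coalescent simulation
#'
#' Couples an ultrametric species tree (branch lengths in generations) with
#' per-branch effective population sizes. Each branch is one panmictic
#' population in which any pair of gene lineages coalesces at rate `1/Ne`
#' per generation; looking backward in time, populations merge at speciation
#' nodes, and the ancestral population above the root extends indefinitely.
#' Under this (haploid-rate) convention the coalescent-unit length of a
#' branch is `generations / Ne`: the internal branch length lambda that
#' drives the triplet-congruence probability `1 - (2/3) exp(-lambda)`.
#'
#' @param tree Ultrametric rooted `phylo`, branch lengths in generations.
#' @param ne Effective population size: a single value used for every branch
#'   (including the root stem), or a vector indexed by node id (`ne[v]` is
#'   the size of the population on the branch above node `v`; the root entry
#'   is the ancestral population).
#' @param ploidy Multiplier applied to `ne` in the coalescence rate
#'   (`1/(ploidy * ne)`), default 1 (haploid-style rate).
#' @return A `species_tree_model`.
#' @export
species_tree_model <- function(tree, ne, ploidy = 1) {
  validate_rooted_tree(tree)
  nall <- ape::Ntip(tree) + tree$Nnode
  if (length(ne) == 1L) ne <- rep(ne, nall)
  stopifnot(length(ne) == nall, all(ne > 0), ploidy > 0)
  if (ape::Ntip(tree) > 1L) {
    ages <- node_ages(tree)
    if (max(abs(ages[seq_len(ape::Ntip(tree))])) > 1e-6 * max(ages)) {
      stop("species tree must be ultrametric (tips at time 0)", call. = FALSE)
    }
  }
  structure(list(tree = tree, ne = ne, ploidy = ploidy),
            class = "species_tree_model")
}

# node ages (time before present), assuming ultrametric input
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

#' Fixed three-species tree
#'
#' The species tree `((sp1, sp2), sp3)` with the sp1-sp2 divergence at `t1`
#' generations and the root at `t0`, and a uniform effective population
#' size. With the defaults (`t1 = 4000`, `t0 = 8000`) the internal branch is
#' `t0 - t1 = 4000` generations, i.e. `4000 / ne` coalescent units.
#'
#' @param t1 Age of the sp1-sp2 divergence (generations).
#' @param t0 Age of the root (generations); must exceed `t1`.
#' @param ne Effective population size for all branches.
#' @return A `species_tree_model`.
#' @export
three_species_tree <- function(t1 = 4000, t0 = 8000, ne = 2000) {
  stopifnot(t1 > 0)
  if (t1 >= t0) stop("t1 must be smaller than t0", call. = FALSE)
  nwk <- sprintf("((sp1:%g,sp2:%g):%g,sp3:%g);", t1, t1, t0 - t1, t0)
  species_tree_model(ape::read.tree(text = nwk), ne)
}

#' Simulate a Yule species tree rescaled to a fixed depth
#'
#' Pure-birth tree: starting from two lineages at the root, waiting times to
#' successive speciations are exponential with rate `k` times the speciation
#' rate for `k` extant lineages, the splitting lineage chosen uniformly. The
#' sampling time is drawn by the general sampling approach for trees
#' conditioned on `n` tips: a uniform point within the era during which
#' exactly `n` lineages exist (for a pure-birth process, uniform on the
#' `Exp(n * rate)` interval following the n-th speciation). All node times
#' are then rescaled so the root sits at exactly `depth` generations (which
#' makes the speciation rate irrelevant), and a uniform `ne` is attached.
#' Tips are labelled `sp1 ... spn`.
#'
#' @param n_species Number of species (tips), default 10.
#' @param depth Root age in generations, default 20000.
#' @param ne Effective population size for every branch.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return A `species_tree_model` with an ultrametric tree of root age
#'   `depth`.
#' @export
simulate_yule_species_tree <- function(n_species = 10, depth = 20000,
                                       ne = 2000, seed = NULL) {
  stopifnot(n_species >= 2, depth > 0)
  run <- function() {
    # event times from the root; lineage records: (parent id, birth time)
    n_nodes <- 2L * n_species - 1L
    parent <- integer(n_nodes)
    btime <- numeric(n_nodes)
    is_tip <- logical(n_nodes)
    nxt <- 1L
    new_node <- function(p, t) {
      id <- nxt; nxt <<- nxt + 1L
      parent[id] <<- p; btime[id] <<- t
      id
    }
    root <- new_node(0L, 0)
    active <- c(new_node(root, 0), new_node(root, 0))
    t <- 0
    while (length(active) < n_species) {
      t <- t + rexp(1, length(active))
      i <- sample.int(length(active), 1L)
      v <- active[i]
      active <- c(active[-i], new_node(v, t), new_node(v, t))
    }
    # uniform point inside the (exponential) era with exactly n lineages
    t_end <- t + runif(1) * rexp(1, n_species)
    is_tip[active] <- TRUE
    # assemble phylo: tips 1..n, internals n+1..2n-1 (root first)
    scale <- depth / t_end
    old_int <- which(!is_tip)
    old_tip <- which(is_tip)
    new_id <- integer(n_nodes)
    new_id[old_tip] <- seq_len(n_species)
    new_id[old_int] <- n_species + seq_along(old_int)  # root (id 1) first
    child <- which(parent > 0L)
    edge <- cbind(new_id[parent[child]], new_id[child])
    end_time <- ifelse(is_tip, t_end, NA_real_)
    for (v in old_int) {
      ch1 <- which(parent == v)[1]       # children share their birth time
      end_time[v] <- btime[ch1]
    }
    elen <- (end_time[child] - btime[child]) * scale
    tree <- structure(
      list(edge = edge, edge.length = elen,
           tip.label = paste0("sp", seq_len(n_species)),
           Nnode = n_species - 1L),
      class = "phylo"
    )
    tree <- ape::reorder.phylo(tree, "cladewise")
    species_tree_model(tree, ne)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate gene trees under the multispecies coalescent
#'
#' For each locus, samples' gene lineages coalesce backward in time within
#' the species-tree branches: within a branch of population size `Ne`, with
#' `k` lineages present, the waiting time to the next coalescence is
#' exponential with rate `choose(k, 2) / (ploidy * Ne)` per generation and
#' the coalescing pair is uniform; at each speciation node (backward: a
#' population merger) the surviving lineages of the two descendant branches
#' join; coalescence continues in the ancestral population above the root
#' until a single lineage remains. Loci are independent.
#'
#' @param model A `species_tree_model`.
#' @param samples_per_species Samples per species; sample labels are
#'   `<species>_<i>`.
#' @param n_loci Number of independent loci.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return An `msc_dataset`: list with `gene_trees` (list of `phylo`, branch
#'   lengths in generations), `truth` (named vector sample -> species),
#'   `model` and `params`.
#' @export
simulate_gene_trees <- function(model, samples_per_species = 10, n_loci = 1,
                                seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"),
            samples_per_species >= 1, n_loci >= 1)
  stree <- model$tree
  ntip <- ape::Ntip(stree)
  species <- stree$tip.label
  truth <- rep(species, each = samples_per_species)
  names(truth) <- paste0(rep(species, each = samples_per_species), "_",
                         seq_len(samples_per_species))
  ages <- node_ages(stree)
  root <- ntip + 1L
  internal_by_age <- order(ages)                    # tips first (age 0)
  internal_by_age <- internal_by_age[internal_by_age > ntip]
  kids <- vector("list", ntip + stree$Nnode)
  for (e in seq_len(nrow(stree$edge))) {
    kids[[stree$edge[e, 1]]] <- c(kids[[stree$edge[e, 1]]], stree$edge[e, 2])
  }
  rate_ne <- model$ne * model$ploidy

  sim_locus <- function() {
    pop <- vector("list", ntip + stree$Nnode)
    for (s in seq_len(ntip)) {
      labs <- names(truth)[truth == species[s]]
      pop[[s]] <- list(frag = as.list(labs),
                       height = numeric(length(labs)))
    }
    for (v in internal_by_age) {
      merged <- list(frag = list(), height = numeric(0))
      for (ch in kids[[v]]) {
        p <- coalesce_interval(pop[[ch]], ages[ch], ages[v], rate_ne[ch])
        merged$frag <- c(merged$frag, p$frag)
        merged$height <- c(merged$height, p$height)
      }
      pop[[v]] <- merged
    }
    # single-species model: no internal nodes, population sits at the tip
    final <- if (ntip == 1L) pop[[1L]] else pop[[root]]
    top <- coalesce_interval(final, ages[if (ntip == 1L) 1L else root], Inf,
                             rate_ne[if (ntip == 1L) 1L else root])
    ape::read.tree(text = paste0(top$frag[[1]], ";"))
  }
  run <- function() lapply(seq_len(n_loci), function(i) sim_locus())
  trees <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(gene_trees = trees, truth = truth, model = model,
         params = list(samples_per_species = samples_per_species,
                       n_loci = n_loci, seed = seed)),
    class = "msc_dataset"
  )
}

# coalesce lineages within one population over [t0, t1] (t1 may be Inf)
coalesce_interval <- function(pop, t0, t1, ne) {
  n <- length(pop$frag)
  t <- t0
  while (n >= 2L) {
    t <- t + rexp(1, n * (n - 1) / 2 / ne)
    if (t > t1) break
    ij <- sample.int(n, 2L)
    i <- ij[1]; j <- ij[2]
    frag <- sprintf("(%s:%.8g,%s:%.8g)",
                    pop$frag[[i]], t - pop$height[i],
                    pop$frag[[j]], t - pop$height[j])
    pop$frag[[i]] <- frag
    pop$height[i] <- t
    pop$frag[[j]] <- NULL
    pop$height <- pop$height[-j]
    n <- n - 1L
  }
  pop
}

#' Proportion of nonmonophyletic species across loci
#'
#' For every locus and every species represented by at least two samples,
#' tests whether the species' samples form a clade in that locus's gene
#' tree; returns the mean over loci of the fraction of such species that are
#' nonmonophyletic. This is the standard summary of the degree of incomplete
#' lineage sorting in a simulated dataset.
#'
#' @param data An `msc_dataset`.
#' @return A single proportion in `[0, 1]`.
#' @export
nonmonophyly_proportion <- function(data) {
  stopifnot(inherits(data, "msc_dataset"))
  blocks <- split(names(data$truth), data$truth)
  blocks <- blocks[lengths(blocks) >= 2L]
  if (!length(blocks)) stop("no species with >= 2 samples", call. = FALSE)
  per_locus <- vapply(data$gene_trees, function(tree) {
    mean(!species_monophyly(tree, blocks))
  }, numeric(1))
  mean(per_locus)
}

# one postorder pass: block s is monophyletic iff some node subtends exactly
# the block (its descendant-tip count equals both the block size and the
# number of block members below it)
species_monophyly <- function(tree, blocks) {
  ntip <- ape::Ntip(tree)
  nall <- ntip + tree$Nnode
  cnt <- matrix(0L, nall, length(blocks))
  for (s in seq_along(blocks)) {
    cnt[match(blocks[[s]], tree$tip.label), s] <- 1L
  }
  ndesc <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    cnt[p, ] <- cnt[p, ] + cnt[ch, ]
    ndesc[p] <- ndesc[p] + ndesc[ch]
  }
  sizes <- lengths(blocks)
  vapply(seq_along(blocks), function(s) {
    any(cnt[, s] == sizes[s] & ndesc == sizes[s])
  }, logical(1))
}

#' Compare an estimated delimitation with the truth
#'
#' @param estimated,truth Partitions over the same sample set (named vectors
#'   or lists of blocks; see [partition_score()]).
#' @return A list with `n_estimated_species` (number of blocks in
#'   `estimated`) and `n_exact_matches` (estimated blocks identical, as
#'   sets, to some true block).
#' @examples
#' match_statistics(c(a = 1, b = 1, c = 2, d = 3),
#'                  c(a = 1, b = 1, c = 2, d = 2))
#' @export
match_statistics <- function(estimated, truth) {
  if (is.list(truth)) {
    truth <- stats::setNames(rep(seq_along(truth), lengths(truth)),
                             unlist(truth))
  }
  samples <- sort(names(truth))
  est_names <- if (is.list(estimated)) unlist(estimated) else names(estimated)
  if (!setequal(est_names, samples)) stop("sample sets differ", call. = FALSE)
  truth <- as_partition(truth, samples)
  estimated <- as_partition(estimated, samples)
  est_blocks <- split(names(estimated), estimated)
  true_keys <- vapply(split(names(truth), truth),
                      function(b) paste(sort(b), collapse = "\r"),
                      character(1))
  est_keys <- vapply(est_blocks,
                     function(b) paste(sort(b), collapse = "\r"),
                     character(1))
  list(n_estimated_species = length(est_blocks),
       n_exact_matches = sum(est_keys %in% true_keys))
}
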