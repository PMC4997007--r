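# derive a per-replicate seed that is stable under extending the grid or the
# replicate count (pairing of seeds to (cell, replicate) indices never moves)
derive_seed <- function(seed, cell, replicate) {
  (as.integer(seed) %% 100000L) * 20011L + cell * 1013L + replicate
}

#' Three-species error-rate study
#'
#' Reproduces the fixed-species-tree simulation design: gene trees are
#' simulated under `((sp1, sp2), sp3)` with divergences at `t1` and `t0`
#' generations and a per-cell effective population size; four fixed
#' delimitations are scored on each replicate with [partition_score()]:
#' \describe{
#'   \item{W}{all samples one species;}
#'   \item{a}{the correct three species;}
#'   \item{b}{under-split: the sister pair sp1+sp2 lumped;}
#'   \item{c}{over-split: sp1's samples bipartitioned into two seeded random
#'     groups of equal size, four species total.}
#' }
#' The false positive rate of a cell is the fraction of replicates in which
#' the over-split hypothesis `c` is the unique best; the false negative rate
#' is the fraction in which `b` or `W` scores at least as high as `a`.
#'
#' @param ne_values Effective population sizes (one cell row per value).
#' @param loci_grid Numbers of loci at which each replicate is evaluated
#'   (prefixes of one simulated set of `max(loci_grid)` loci).
#' @param n_replicates Replicates per `ne` value.
#' @param seed Master seed; replicate seeds are derived so that enlarging
#'   `n_replicates` extends rather than perturbs earlier replicates.
#' @param samples_per_species,t1,t0 Design constants of the species tree.
#' @param L Prior bound passed to [model_config()].
#' @return A tibble with one row per `(ne, n_loci)` cell: counts of
#'   over-splits and under-splits and the rates `fpr` and `fnr`.
#' @export
run_three_species_study <- function(ne_values = c(2000, 4000, 8000, 16000,
                                                  32000),
                                    loci_grid = seq(5, 25, by = 5),
                                    n_replicates = 20, seed = 1,
                                    samples_per_species = 10,
                                    t1 = 4000, t0 = 8000, L = 5) {
  stopifnot(length(ne_values) >= 1, length(loci_grid) >= 1)
  cfg <- model_config(L = L)
  max_loci <- max(loci_grid)
  cells <- list()
  for (ni in seq_along(ne_values)) {
    ne <- ne_values[ni]
    model <- three_species_tree(t1 = t1, t0 = t0, ne = ne)
    over <- under <- matrix(0L, length(loci_grid), 1L)
    for (r in seq_len(n_replicates)) {
      rs <- derive_seed(seed, ni, r)
      data <- simulate_gene_trees(model, samples_per_species, max_loci,
                                  seed = rs)
      parts <- three_species_partitions(data$truth, seed = rs)
      for (li in seq_along(loci_grid)) {
        tab <- count_triplets(data$gene_trees[seq_len(loci_grid[li])],
                              samples = names(data$truth))
        post <- triplet_posterior(tab$counts, cfg)
        sc <- vapply(parts, partition_score, numeric(1),
                     table = tab, cfg = cfg, post = post)
        if (sc["c"] > max(sc[c("W", "a", "b")])) over[li] <- over[li] + 1L
        if (max(sc[c("b", "W")]) >= sc["a"]) under[li] <- under[li] + 1L
      }
    }
    cells[[ni]] <- tibble::tibble(
      ne = ne, n_loci = loci_grid, n_replicates = n_replicates,
      n_over_split = as.integer(over), n_under_split = as.integer(under),
      fpr = as.numeric(over) / n_replicates,
      fnr = as.numeric(under) / n_replicates
    )
  }
  out <- do.call(rbind, cells)
  attr(out, "params") <- list(seed = seed, L = L, t1 = t1, t0 = t0,
                              samples_per_species = samples_per_species)
  out
}

# the four fixed delimitation hypotheses of the three-species design
three_species_partitions <- function(truth, seed) {
  samples <- names(truth)
  w <- stats::setNames(rep(1L, length(samples)), samples)
  a <- stats::setNames(match(truth, unique(truth)), samples)
  b <- a
  b[truth %in% c("sp1", "sp2")] <- 1L
  b[truth == "sp3"] <- 2L
  cc <- a
  sp1 <- samples[truth == "sp1"]
  grp <- withr::with_seed(seed, sample(rep(1:2, length.out = length(sp1))))
  cc[sp1] <- ifelse(grp == 1L, 4L, 5L)
  cc <- stats::setNames(match(cc, unique(cc)), samples)
  list(W = w, a = a, b = b, c = cc)
}

#' Ten-species delimitation accuracy study
#'
#' Simulates Yule species trees (rescaled to `depth` generations) with
#' multispecies-coalescent gene trees, runs the guide-tree dynamic program,
#' and scores recovery of the true species. Two designs are supported:
#' `"known_guide"` uses the true species tree as the guide, each species'
#' samples attached as a seeded randomly resolved subtree (assignment of
#' samples to species known; only the lump/split positions are inferred);
#' `"estimated_guide"` builds the guide from the gene trees themselves with
#' [build_guide_tree()] (full species-discovery setting).
#'
#' @param mode `"known_guide"` or `"estimated_guide"`.
#' @param ne Effective population size (uniform over branches).
#' @param loci_grid Numbers of loci at which each replicate is evaluated.
#' @param samples_per_species Samples per species.
#' @param n_replicates Number of replicate species trees.
#' @param seed Master seed (see [run_three_species_study()] for the seed
#'   pairing guarantee).
#' @param n_species,depth Yule design constants.
#' @param L Prior bound passed to [model_config()].
#' @return A tibble with one row per `n_loci`: medians and means over
#'   replicates of the number of estimated species and of exact matches.
#'   The per-replicate rows are in `attr(, "replicates")`.
#' @export
run_ten_species_study <- function(mode = c("known_guide", "estimated_guide"),
                                  ne = 1250, loci_grid = c(5, 15, 25),
                                  samples_per_species = 10,
                                  n_replicates = 20, seed = 1,
                                  n_species = 10, depth = 20000, L = 5) {
  mode <- match.arg(mode)
  stopifnot(length(loci_grid) >= 1)
  cfg <- model_config(L = L)
  max_loci <- max(loci_grid)
  rows <- vector("list", n_replicates * length(loci_grid))
  i <- 0L
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, 1L, r)
    model <- simulate_yule_species_tree(n_species, depth, ne, seed = rs)
    data <- simulate_gene_trees(model, samples_per_species, max_loci,
                                seed = rs + 1L)
    truth <- split(names(data$truth), data$truth)
    for (li in seq_along(loci_grid)) {
      tab <- count_triplets(data$gene_trees[seq_len(loci_grid[li])],
                            samples = names(data$truth))
      guide <- switch(mode,
        known_guide = known_guide_tree(model$tree, data$truth, seed = rs + 2L),
        estimated_guide = build_guide_tree(tab, seed = rs + 2L)
      )
      fit <- best_delimitation(guide, tab, cfg)
      ms <- match_statistics(fit$partition, truth)
      i <- i + 1L
      rows[[i]] <- tibble::tibble(
        replicate = r, n_loci = loci_grid[li],
        n_estimated_species = ms$n_estimated_species,
        n_exact_matches = ms$n_exact_matches
      )
    }
  }
  detail <- do.call(rbind, rows)
  agg <- lapply(split(detail, detail$n_loci), function(d) {
    tibble::tibble(
      ne = ne, mode = mode, n_loci = d$n_loci[1],
      n_replicates = n_replicates,
      median_exact_matches = stats::median(d$n_exact_matches),
      mean_exact_matches = mean(d$n_exact_matches),
      median_n_species = stats::median(d$n_estimated_species),
      mean_n_species = mean(d$n_estimated_species)
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$n_loci), ]
  attr(out, "replicates") <- detail
  attr(out, "params") <- list(seed = seed, L = L, depth = depth, ne = ne,
                              samples_per_species = samples_per_species)
  out
}

#' Guide tree with known species structure
#'
#' Replaces each tip of a species tree by a randomly resolved subtree over
#' that species' samples (a star refined uniformly at random under `seed`).
#' The intra-species shape is irrelevant whenever the species is lumped; it
#' only matters for near-tie splits below the species level.
#'
#' @param species_tree A rooted `phylo` over species labels.
#' @param truth Named vector sample -> species.
#' @param seed Integer seed, or `NULL`.
#' @return A binary rooted `phylo` over the samples.
#' @export
known_guide_tree <- function(species_tree, truth, seed = NULL) {
  nwk <- write_newick(species_tree)
  # strip branch lengths, then expand each species tip into a sample star
  nwk <- gsub(":[0-9.eE+-]+", "", nwk)
  for (sp in species_tree$tip.label) {
    members <- names(truth)[truth == sp]
    star <- if (length(members) == 1L) members else
      paste0("(", paste(members, collapse = ","), ")")
    nwk <- sub(paste0("(?<![[:alnum:]_])", sp, "(?![[:alnum:]_])"), star,
               nwk, perl = TRUE)
  }
  resolve_polytomies(ape::read.tree(text = nwk), seed = seed)
}
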