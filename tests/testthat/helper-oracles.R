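# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (explicit enumeration, recursion,
# numerical integration) that never call the code paths they verify.

# --- brute-force split enumeration ------------------------------------------

# leaf-label set under every non-root node (one per edge)
bf_leafsets <- function(tree) {
  sets <- list()
  rec <- function(n, is_root) {
    if (length(n$children) == 0L) {
      if (!is_root) sets[[length(sets) + 1L]] <<- n$name
      return(n$name)
    }
    below <- unlist(lapply(n$children, rec, is_root = FALSE))
    if (!is_root) sets[[length(sets) + 1L]] <<- below
    below
  }
  rec(tree, TRUE)
  sets
}

# frozen label-set pair keys for all nontrivial splits on a universe
bf_split_keys <- function(tree, universe) {
  keys <- character()
  for (s in bf_leafsets(tree)) {
    a <- sort(intersect(s, universe))
    b <- sort(setdiff(universe, a))
    if (length(a) >= 2L && length(b) >= 2L) {
      ka <- paste(a, collapse = ",")
      kb <- paste(b, collapse = ",")
      keys <- c(keys, if (ka < kb) paste(ka, kb, sep = "|") else paste(kb, ka, sep = "|"))
    }
  }
  unique(keys)
}

bf_rf <- function(t1, t2) {
  u <- intersect(tree_leaves(t1), tree_leaves(t2))
  k1 <- bf_split_keys(t1, u)
  k2 <- bf_split_keys(t2, u)
  list(rf = sum(!k1 %in% k2) + sum(!k2 %in% k1),
       max_rf = length(k1) + length(k2))
}

# --- TreeKO counting law (independent recursion over evoltype labels) -------

bf_pruned_count <- function(labeled_tree) {
  rec <- function(n) {
    if (length(n$children) == 0L) return(1)
    counts <- vapply(n$children, rec, 0)
    if (identical(n$annotations$evoltype, "D")) sum(counts) else prod(counts)
  }
  rec(labeled_tree)
}

# --- random gene trees with duplicate species --------------------------------

random_gene_tree <- function(n_species, n_leaves, seed) {
  set.seed(seed)
  sp <- sample.int(n_species, n_leaves, replace = TRUE)
  copy <- stats::ave(sp, sp, FUN = seq_along)
  labels <- paste0("s", sp, "_", copy)
  pool <- lapply(labels, function(l) tree_node(name = l, dist = stats::rexp(1, 10)))
  while (length(pool) > 1L) {
    idx <- sample.int(length(pool), 2L)
    pool <- c(pool[-idx], list(tree_node(dist = stats::rexp(1, 10),
                                         children = pool[idx])))
  }
  root <- pool[[1L]]
  root$dist <- 0
  root
}

# --- pairwise leaf path lengths (recomputed from scratch) --------------------

pairwise_leaf_dists <- function(tree) {
  acc <- new.env()
  acc$d <- numeric()
  rec <- function(n) {
    if (length(n$children) == 0L) return(stats::setNames(n$dist, n$name))
    depths <- lapply(n$children, rec)
    for (i in seq_along(depths)) {
      for (j in seq_len(i - 1L)) {
        for (a in names(depths[[i]])) {
          for (b in names(depths[[j]])) {
            key <- paste(sort(c(a, b)), collapse = "~")
            acc$d[key] <- depths[[i]][[a]] + depths[[j]][[b]]
          }
        }
      }
    }
    unlist(depths) + n$dist
  }
  rec(tree)
  acc$d
}

# --- chi-square upper tail by numerical integration --------------------------

chisq_upper_oracle <- function(d, df) {
  if (d <= 0) return(1)
  stats::integrate(function(x) stats::dchisq(x, df), lower = d, upper = Inf,
                   rel.tol = 1e-12)$value
}

# --- shared fixtures ---------------------------------------------------------

fixture_taxdb <- function() {
  fx <- example_taxdump()
  files <- synthetic_taxdump(fx$spec, fx$merges, tempfile("taxdump"))
  build_taxdb(files["nodes"], files["names"], files["merged"])
}
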