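#' Build a leaf-to-species mapping function
#'
#' Gene-tree leaves are conventionally labeled `<species>_<gene copy>`;
#' by default the species is the substring before the first delimiter
#' (labels without a delimiter map to themselves, so species trees pass
#' through unchanged). An explicit table overrides the convention.
#'
#' @param delim Delimiter separating species from copy id (default `"_"`).
#' @param table Optional named character vector (`names` are leaf labels,
#'   values species) or a two-column data frame (label, species).
#' @return A function mapping a character vector of leaf labels to species
#'   labels.
#' @export
species_map <- function(delim = "_", table = NULL) {
  if (!is.null(table)) {
    if (is.data.frame(table)) {
      tab <- stats::setNames(as.character(table[[2L]]), as.character(table[[1L]]))
    } else tab <- table
    return(function(labels) {
      out <- unname(tab[labels])
      if (anyNA(out))
        stop("species map has no entry for: ",
             paste(labels[is.na(out)], collapse = ", "))
      out
    })
  }
  function(labels) {
    vapply(strsplit(labels, delim, fixed = TRUE), `[[`, "", 1L)
  }
}

as_species_map <- function(smap) {
  if (is.function(smap)) smap else species_map(table = smap)
}

# species sets under every internal node, postorder; returns annotated tree
#' Label speciation and duplication nodes by species overlap
#'
#' An internal node is a duplication when the species sets under its
#' children overlap: score = |S(a) n S(b)| / |S(a) u S(b)| for a child pair.
#' Binary nodes use their two children; a polytomy is a duplication when
#' any pair of its children overlaps beyond the threshold. Internal nodes
#' gain an `evoltype` annotation, `"D"` or `"S"`; leaves are untouched.
#'
#' @param root Gene tree (`tree_node`).
#' @param smap A [species_map()] function (or a table accepted by it).
#' @param overlap_threshold Score above which a node is called a
#'   duplication; the default 0 flags any overlap.
#' @return The annotated `tree_node`.
#' @export
detect_duplications <- function(root, smap = species_map(), overlap_threshold = 0) {
  smap <- as_species_map(smap)
  rec <- function(node) {
    if (is_leaf(node)) {
      attr(node, "spset") <- unique(smap(node$name))
      return(node)
    }
    node$children <- lapply(node$children, rec)
    sets <- lapply(node$children, attr, "spset")
    dup <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_len(i - 1L)) {
        score <- length(intersect(sets[[i]], sets[[j]])) /
          length(union(sets[[i]], sets[[j]]))
        if (score > overlap_threshold) { dup <- TRUE; break }
      }
      if (dup) break
    }
    node$annotations$evoltype <- if (dup) "D" else "S"
    attr(node, "spset") <- unique(unlist(sets, use.names = FALSE))
    node
  }
  out <- rec(root)
  attr(out, "spset") <- NULL
  strip <- function(node) {
    attr(node, "spset") <- NULL
    node$children <- lapply(node$children, strip)
    node
  }
  strip(out)
}

count_pruned <- function(node) {
  if (is_leaf(node)) return(1)
  counts <- vapply(node$children, count_pruned, 0)
  if (identical(node$annotations$evoltype, "D")) sum(counts) else prod(counts)
}

#' TreeKO decomposition into duplication-free subtrees
#'
#' Recursively splits a gene tree at duplication nodes (labeled by
#' [detect_duplications()]): a leaf yields itself; a duplication node
#' yields the union of its children's decompositions (the node's branch
#' length is folded into each subtree so path lengths survive); a
#' speciation node yields every combination of one subtree per child,
#' joined under a copy of the node. Every returned tree is
#' duplication-free and retains original branch lengths.
#'
#' @inheritParams detect_duplications
#' @param max_subtrees Hard cap on the number of pruned trees; the
#'   combination count grows geometrically with nested duplications, so
#'   enumeration stops with an error beyond this.
#' @return List of `tree_node` pruned trees.
#' @export
treeko_decompose <- function(root, smap = species_map(), overlap_threshold = 0,
                             max_subtrees = 1000) {
  if (is.null(root)) stop("empty tree")
  labeled <- detect_duplications(root, smap, overlap_threshold)
  total <- count_pruned(labeled)
  if (total > max_subtrees)
    stop(sprintf(paste0("TreeKO decomposition would produce %.0f pruned trees ",
                        "(max_subtrees = %d); raise overlap_threshold or the cap"),
                 total, max_subtrees))
  rec <- function(node) {
    if (is_leaf(node)) return(list(node))
    parts <- lapply(node$children, rec)
    if (identical(node$annotations$evoltype, "D")) {
      # union; passing through the duplication node costs its branch length
      out <- list()
      for (p in parts) {
        out <- c(out, lapply(p, function(t) { t$dist <- t$dist + node$dist; t }))
      }
      out
    } else {
      # cartesian combination of one pruned tree per child
      combos <- parts[[1L]]
      combos <- lapply(combos, list)
      for (i in seq_along(parts)[-1L]) {
        combos <- unlist(lapply(combos, function(cmb)
          lapply(parts[[i]], function(t) c(cmb, list(t)))), recursive = FALSE)
      }
      lapply(combos, function(kids) {
        joined <- node
        joined$children <- kids
        joined$annotations$evoltype <- NULL
        joined
      })
    }
  }
  out <- rec(labeled)
  lapply(out, function(t) { t$dist <- 0; t })
}

# ---- Robinson-Foulds & congruence ------------------------------------------

comparison_result <- function(rf, max_rf, shared, src_only, ref_only,
                              effective_leaves, treeko = NA_real_) {
  n_src <- length(shared) + length(src_only)
  n_ref <- length(shared) + length(ref_only)
  structure(list(
    rf = rf, max_rf = max_rf,
    norm_rf = if (max_rf > 0) rf / max_rf else 0,
    congruence_src = if (n_src > 0) 100 * length(shared) / n_src else NA_real_,
    congruence_ref = if (n_ref > 0) 100 * length(shared) / n_ref else NA_real_,
    treeko_speciation_dist = treeko,
    shared_splits = shared, src_only_splits = src_only, ref_only_splits = ref_only,
    effective_leaves = effective_leaves
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("RF = %d / %d (normalized %.4f) on %d shared leaves\n",
              x$rf, x$max_rf, x$norm_rf, x$effective_leaves))
  cat(sprintf("branch congruence: src %s%%, ref %s%%\n",
              format(x$congruence_src), format(x$congruence_ref)))
  if (!is.na(x$treeko_speciation_dist))
    cat(sprintf("TreeKO speciation distance: %.4f\n", x$treeko_speciation_dist))
  invisible(x)
}

#' Robinson-Foulds distance and split report between two trees
#'
#' Both trees are optionally filtered with [collapse_low_support()], then
#' restricted to the shared leaf-label universe (default policy), where
#' nontrivial splits are enumerated and compared. `rf` counts splits
#' present in exactly one tree; `max_rf` is the total nontrivial split
#' count of both. The comparison is symmetric: swapping the trees swaps
#' the one-sided lists and congruence percentages but leaves `rf`
#' unchanged.
#'
#' @param src,ref `tree_node` trees with unique leaf labels.
#' @param min_support Collapse edges below this support first (0 = keep all).
#' @param universe_policy `"shared"` compares on the leaf intersection
#'   (trees may differ in size); `"strict"` errors on unequal leaf sets.
#' @return A `comparison_result`.
#' @export
rf_distance <- function(src, ref, min_support = 0,
                        universe_policy = c("shared", "strict")) {
  universe_policy <- match.arg(universe_policy)
  if (min_support > 0) {
    src <- collapse_low_support(src, min_support)
    ref <- collapse_low_support(ref, min_support)
  }
  ls <- tree_leaves(src); lr <- tree_leaves(ref)
  if (anyDuplicated(ls) || anyDuplicated(lr))
    stop("duplicate leaf labels after species mapping; use the TreeKO path ",
         "(speciation_distance) for trees with duplications")
  if (universe_policy == "strict" && !setequal(ls, lr))
    stop("strict universe policy: leaf sets differ")
  shared_leaves <- intersect(ls, lr)
  if (length(shared_leaves) < 3L)
    stop("fewer than 3 shared leaves (", length(shared_leaves),
         "); no nontrivial splits to compare")
  bs <- get_bipartitions(src, universe = shared_leaves)
  br <- get_bipartitions(ref, universe = shared_leaves)
  ks <- split_keys(bs); kr <- split_keys(br)
  shared <- bs[ks %in% kr]
  src_only <- bs[!ks %in% kr]
  ref_only <- br[!kr %in% ks]
  rf <- length(src_only) + length(ref_only)
  comparison_result(rf, length(bs) + length(br), shared, src_only, ref_only,
                    effective_leaves = length(shared_leaves))
}

#' Branch congruence percentages between two trees
#'
#' The percentage of `src`'s nontrivial splits (on the shared universe)
#' also found in `ref`, and vice versa. Both are 100 exactly when the
#' normalized RF distance is 0. A tree contributing no nontrivial splits
#' (a star on the shared universe) reports `NA` rather than a vacuous 100.
#'
#' @inheritParams rf_distance
#' @return Named numeric vector `c(src = , ref = )`.
#' @export
branch_congruence <- function(src, ref, min_support = 0) {
  res <- rf_distance(src, ref, min_support = min_support)
  c(src = res$congruence_src, ref = res$congruence_ref)
}

# ---- TreeKO speciation distance --------------------------------------------

relabel_to_species <- function(node, smap) {
  if (is_leaf(node)) { node$name <- smap(node$name); return(node) }
  node$children <- lapply(node$children, relabel_to_species, smap = smap)
  node
}

# norm_rf between two single-copy trees on their shared leaves, or NA when
# fewer than 3 are shared
pair_norm_rf <- function(a, b) {
  shared <- intersect(tree_leaves(a), tree_leaves(b))
  if (length(shared) < 3L) return(c(norm_rf = NA_real_, n_shared = length(shared)))
  res <- rf_distance(a, b)
  c(norm_rf = res$norm_rf, n_shared = length(shared))
}

#' TreeKO speciation distance between two trees
#'
#' Both trees are decomposed into duplication-free pruned trees
#' ([treeko_decompose()]) whose leaves are relabeled to species. Every
#' pruned-tree pair sharing at least 3 species contributes its normalized
#' RF distance; the distance is the weighted mean over contributing pairs,
#' with weights proportional to the pair's shared-species count (or
#' uniform, by choice). Pairs below the 3-species floor carry no
#' topological signal and are excluded from both the sum and the
#' normalizer.
#'
#' @inheritParams treeko_decompose
#' @param src,ref Trees to compare (either may contain duplications).
#' @param weighting `"shared"` (default) weights pairs by shared-species
#'   count; `"uniform"` weights all contributing pairs equally.
#' @return List with `distance` (in `[0, 1]`, or `NA` with a `reason`
#'   attribute when no pair is comparable), `n_comparisons`, and `detail`,
#'   a data frame with one row per contributing pair.
#' @export
speciation_distance <- function(src, ref, smap = species_map(),
                                overlap_threshold = 0, max_subtrees = 1000,
                                weighting = c("shared", "uniform")) {
  weighting <- match.arg(weighting)
  smap <- as_species_map(smap)
  ps <- lapply(treeko_decompose(src, smap, overlap_threshold, max_subtrees),
               relabel_to_species, smap = smap)
  pr <- lapply(treeko_decompose(ref, smap, overlap_threshold, max_subtrees),
               relabel_to_species, smap = smap)
  rows <- list()
  for (i in seq_along(ps)) {
    for (j in seq_along(pr)) {
      v <- pair_norm_rf(ps[[i]], pr[[j]])
      if (!is.na(v[["norm_rf"]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          src_subtree = i, ref_subtree = j,
          n_shared = v[["n_shared"]], norm_rf = v[["norm_rf"]])
      }
    }
  }
  if (length(rows) == 0L) {
    d <- NA_real_
    attr(d, "reason") <- "no pruned-tree pair shares 3 or more species"
    return(list(distance = d, n_comparisons = 0L,
                detail = data.frame(src_subtree = integer(), ref_subtree = integer(),
                                    n_shared = integer(), norm_rf = numeric(),
                                    weight = numeric())))
  }
  detail <- do.call(rbind, rows)
  w <- if (weighting == "shared") detail$n_shared else rep(1, nrow(detail))
  detail$weight <- w / sum(w)
  list(distance = sum(detail$weight * detail$norm_rf),
       n_comparisons = nrow(detail), detail = detail)
}

# ---- gene-tree support on a species tree -----------------------------------

#' Summarize gene-tree signal on a reference species tree
#'
#' Each gene tree is TreeKO-decomposed and species-relabeled; for every
#' nontrivial split of the reference tree, the fraction of informative
#' pruned trees containing the correspondingly restricted split is
#' reported. A pruned tree is informative for a split when both restricted
#' sides keep at least 2 species. Pruned trees inherit weight 1/(pruned
#' trees of their gene tree), so each gene family contributes total weight
#' 1 regardless of how often it duplicated.
#'
#' @param ref_species_tree Single-copy reference `tree_node` (leaves are
#'   species labels).
#' @param gene_trees List of gene trees.
#' @inheritParams treeko_decompose
#' @param min_support Collapse gene-tree edges below this support first.
#' @return Data frame with one row per reference split: `branch` (a stable
#'   split key), `side_a`, `support_fraction`, `n_informative` (weighted,
#'   in gene-family units). The annotated reference tree (internal nodes
#'   gain `support_fraction` annotations) is attached as attribute `tree`.
#' @export
map_gene_tree_support <- function(ref_species_tree, gene_trees,
                                  smap = species_map(), min_support = 0,
                                  overlap_threshold = 0, max_subtrees = 1000) {
  if (length(gene_trees) == 0L) stop("empty gene-tree list")
  smap <- as_species_map(smap)
  ref_leaves <- tree_leaves(ref_species_tree)
  if (anyDuplicated(ref_leaves)) stop("reference species tree must be single-copy")
  ref_splits <- get_bipartitions(ref_species_tree)
  if (length(ref_splits) == 0L) stop("reference tree has no nontrivial splits")

  # flatten: (pruned tree, weight) pairs with precomputed split keys
  units <- list()
  for (g in gene_trees) {
    if (min_support > 0) g <- collapse_low_support(g, min_support)
    pts <- lapply(treeko_decompose(g, smap, overlap_threshold, max_subtrees),
                  relabel_to_species, smap = smap)
    w <- 1 / length(pts)
    for (p in pts) {
      sp <- tree_leaves(p)
      units[[length(units) + 1L]] <- list(
        species = sp, keys = split_keys(get_bipartitions(p)), weight = w)
    }
  }

  support <- numeric(length(ref_splits))
  informative <- numeric(length(ref_splits))
  for (k in seq_along(ref_splits)) {
    b <- ref_splits[[k]]
    for (u in units) {
      a_r <- intersect(b$side_a, u$species)
      b_r <- intersect(b$side_b, u$species)
      if (length(a_r) < 2L || length(b_r) < 2L) next
      informative[k] <- informative[k] + u$weight
      restricted_key <- make_bipartition(a_r, b_r)$key
      # splits of the pruned tree restricted to the shared species
      pkeys <- split_keys(get_bipartitions_keys_cache(u, c(a_r, b_r)))
      if (restricted_key %in% pkeys) support[k] <- support[k] + u$weight
    }
  }
  out <- data.frame(
    branch = split_keys(ref_splits),
    side_a = vapply(ref_splits, function(b) paste(b$side_a, collapse = ","), ""),
    support_fraction = ifelse(informative > 0, support / informative, NA_real_),
    n_informative = informative,
    stringsAsFactors = FALSE)
  attr(out, "tree") <- annotate_split_support(ref_species_tree, out)
  out
}

# recompute a unit's splits restricted to a species subset; units carry the
# pruned tree's species, so restriction is just a bipartition recut
get_bipartitions_keys_cache <- function(unit, universe) {
  # unit$keys are on the full pruned-tree leaf set; restrict each side
  lapply(unit$keys, function(key) {
    sides <- strsplit(key, "|", fixed = TRUE)[[1L]]
    a <- intersect(strsplit(sides[1L], ",", fixed = TRUE)[[1L]], universe)
    b <- intersect(strsplit(sides[2L], ",", fixed = TRUE)[[1L]], universe)
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    make_bipartition(a, b)
  }) -> bips
  Filter(Negate(is.null), bips)
}

annotate_split_support <- function(ref, table) {
  leaves_all <- tree_leaves(ref)
  rec <- function(node, at_root) {
    if (!is_leaf(node)) {
      node$children <- lapply(node$children, rec, at_root = FALSE)
      if (!at_root) {
        below <- tree_leaves(node)
        other <- setdiff(leaves_all, below)
        if (length(below) >= 2L && length(other) >= 2L) {
          key <- make_bipartition(below, other)$key
          hit <- match(key, table$branch)
          if (!is.na(hit)) {
            node$annotations$support_fraction <- table$support_fraction[hit]
            node$annotations$n_informative <- table$n_informative[hit]
          }
        }
      }
    }
    node
  }
  rec(ref, TRUE)
}
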