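test_that("species-overlap rule labels duplication and speciation nodes", {
  t <- detect_duplications(parse_newick("((a_1,b_1),(a_2,b_2));"))
  expect_equal(t$annotations$evoltype, "D") # overlap 2/2 = 1 > 0
  expect_equal(t$children[[1]]$annotations$evoltype, "S")
  expect_equal(t$children[[2]]$annotations$evoltype, "S")
  expect_null(t$children[[1]]$children[[1]]$annotations$evoltype) # leaves unlabeled

  # single-copy tree: all intersections empty
  sc <- detect_duplications(parse_newick("((a_1,b_1),(c_1,d_1));"))
  types <- unlist(lapply(traverse(sc), function(n) n$annotations$evoltype))
  expect_true(all(types == "S"))

  t2 <- detect_duplications(parse_newick("(((a_1,b_1),(a_2,b_2)),c_1);"))
  expect_equal(t2$annotations$evoltype, "S") # {a,b} vs {c}
  expect_equal(t2$children[[1]]$annotations$evoltype, "D")

  # threshold above the overlap score suppresses the call
  t3 <- detect_duplications(parse_newick("((a_1,b_1),(a_2,c_1));"),
                            overlap_threshold = 0.5)
  expect_equal(t3$annotations$evoltype, "S") # score 1/3 <= 0.5
})

test_that("TreeKO decomposition reproduces the worked examples", {
  pts <- treeko_decompose(parse_newick("((a_1,b_1),(a_2,b_2));"))
  expect_length(pts, 2L)
  expect_setequal(vapply(pts, function(p) paste(sort(tree_leaves(p)), collapse = ","), ""),
                  c("a_1,b_1", "a_2,b_2"))

  sc <- parse_newick("((a_1,b_1),(c_1,d_1));")
  pts2 <- treeko_decompose(sc)
  expect_length(pts2, 1L)
  expect_setequal(tree_leaves(pts2[[1]]), tree_leaves(sc))

  pts3 <- treeko_decompose(parse_newick("(((a_1,b_1),(a_2,b_2)),c_1);"))
  expect_length(pts3, 3L - 1L)
  got <- sort(vapply(pts3, function(p) paste(sort(tree_leaves(p)), collapse = ","), ""))
  expect_equal(got, c("a_1,b_1,c_1", "a_2,b_2,c_1"))
})

test_that("decomposition obeys the sum/product law and is duplication-free", {
  for (s in 1:12) {
    g <- random_gene_tree(n_species = 4, n_leaves = 8, seed = 900 + s)
    labeled <- detect_duplications(g)
    n_expected <- bf_pruned_count(labeled)
    if (n_expected > 1000) {
      expect_error(treeko_decompose(g), "max_subtrees")
      next
    }
    pts <- treeko_decompose(g)
    expect_length(pts, n_expected)
    for (p in pts) {
      types <- unlist(lapply(traverse(detect_duplications(p)),
                             function(n) n$annotations$evoltype))
      expect_false(any(types == "D"))
      sp <- species_map()(tree_leaves(p))
      expect_false(anyDuplicated(sp) > 0) # one leaf per species lineage
    }
  }
  # explosion guard fires rather than silently truncating
  deep <- "(((((a_1,a_2),(a_3,a_4)),((a_5,a_6),(a_7,a_8))),b_1),c_1);"
  expect_silent(treeko_decompose(parse_newick(deep)))
  expect_error(treeko_decompose(parse_newick(deep), max_subtrees = 3), "max_subtrees")
})

test_that("rf_distance matches hand-worked examples and stays symmetric", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")

  same <- rf_distance(t1, t1)
  expect_equal(same$rf, 0L)
  expect_equal(same$norm_rf, 0)
  expect_equal(same$congruence_src, 100)
  expect_equal(same$congruence_ref, 100)

  conf <- rf_distance(t1, t2)
  expect_equal(conf$rf, 2L)
  expect_equal(conf$max_rf, 2L)
  expect_equal(conf$norm_rf, 1)
  expect_equal(unname(branch_congruence(t1, t2)), c(0, 0))

  # symmetry: one-sided lists and congruences swap, rf unchanged
  ab <- rf_distance(t1, t2); ba <- rf_distance(t2, t1)
  expect_equal(ab$rf, ba$rf)
  expect_equal(ab$congruence_src, ba$congruence_ref)
  expect_equal(vapply(ab$src_only_splits, `[[`, "", "key"),
               vapply(ba$ref_only_splits, `[[`, "", "key"))

  # trees of different size compare on the shared universe
  src5 <- parse_newick("(((a,b),c),(d,e));")
  ref4 <- parse_newick("((a,b),(c,d));")
  mixed <- rf_distance(src5, ref4)
  expect_equal(mixed$effective_leaves, 4L)
  expect_equal(mixed$rf, sum(!bf_split_keys(src5, letters[1:4]) %in%
                               bf_split_keys(ref4, letters[1:4])) +
                         sum(!bf_split_keys(ref4, letters[1:4]) %in%
                               bf_split_keys(src5, letters[1:4])))
  expect_error(rf_distance(src5, ref4, universe_policy = "strict"), "differ")

  expect_error(rf_distance(parse_newick("(a,b);"), parse_newick("(a,b);")),
               "3 shared")
  expect_error(rf_distance(parse_newick("((a,a),(b,c));"), t1), "duplicate")
})

test_that("rf matches the brute-force oracle on random pairs", {
  for (s in 1:40) {
    n <- 4L + (s %% 5L)
    a <- random_tree(n, seed = 2 * s)
    b <- random_tree(n, seed = 2 * s + 1)
    got <- rf_distance(a, b)
    want <- bf_rf(a, b)
    expect_identical(got$rf, want$rf, info = s)
    expect_identical(got$max_rf, want$max_rf, info = s)
  }
})

test_that("rf agrees with phangorn on random same-leafset pairs", {
  skip_if_not_installed("phangorn")
  for (s in 1:15) {
    n <- 5L + (s %% 4L)
    a <- random_tree(n, seed = 3000 + 2 * s)
    b <- random_tree(n, seed = 3001 + 2 * s)
    pa <- ape::read.tree(text = write_newick(a))
    pb <- ape::read.tree(text = write_newick(b))
    expect_equal(rf_distance(a, b)$rf, as.integer(phangorn::RF.dist(pa, pb)),
                 info = s)
  }
})

test_that("raising min_support never increases max_rf", {
  for (s in 1:6) {
    a <- random_tree(8, seed = 500 + s)
    b <- random_tree(8, seed = 600 + s)
    # attach random supports to internal edges
    with_support <- function(t, seed) {
      set.seed(seed)
      rec <- function(n) {
        if (length(n$children)) {
          n$support <- stats::runif(1)
          n$children <- lapply(n$children, rec)
        }
        n
      }
      r <- rec(t); r$support <- NA_real_; r
    }
    a <- with_support(a, s); b <- with_support(b, s + 50)
    prev <- Inf
    for (ms in c(0, 0.25, 0.5, 0.75, 1)) {
      cur <- rf_distance(a, b, min_support = ms)$max_rf
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("speciation distance: identity, symmetry, exclusion, weighting", {
  t <- parse_newick("((a,b),(c,d));")
  id <- speciation_distance(t, t)
  expect_equal(id$distance, 0)
  expect_equal(id$n_comparisons, 1L)

  # all pairs share only 2 species -> no comparable pair
  res <- speciation_distance(parse_newick("((a_1,b_1),(a_2,b_2));"),
                             parse_newick("(a,b);"))
  expect_true(is.na(res$distance))
  expect_match(attr(res$distance, "reason"), "3 or more")

  # duplicated source against two conflicting references, hand-checked:
  # decomposition gives ((a,b),(c,d)) and ((a,c),(b,d)) as the two units
  src <- parse_newick("(((a_1,b_1),(c_1,d_1)),((a_2,c_2),(b_2,d_2)));")
  ref <- parse_newick("((a,b),(c,d));")
  out <- speciation_distance(src, ref)
  expect_equal(out$n_comparisons, 2L)
  # pair 1 agrees (norm 0), pair 2 conflicts (norm 1); equal 4-species weights
  expect_equal(sort(out$detail$norm_rf), c(0, 1))
  expect_equal(out$distance, 0.5)
  expect_equal(speciation_distance(ref, src)$distance, out$distance) # symmetry

  # uniform vs shared weighting differ when overlaps differ
  src2 <- parse_newick("((((a_1,b_1),(c_1,d_1)),e_1),((a_2,c_2),(b_2,d_2)));")
  ref2 <- parse_newick("(((a,b),(c,d)),e);")
  shared_w <- speciation_distance(src2, ref2, weighting = "shared")
  uniform_w <- speciation_distance(src2, ref2, weighting = "uniform")
  d <- shared_w$detail
  expect_equal(shared_w$distance,
               sum(d$n_shared * d$norm_rf) / sum(d$n_shared))
  expect_equal(uniform_w$distance, mean(d$norm_rf))
})

test_that("gene-tree signal maps onto reference branches with weights", {
  ref <- parse_newick("(((a,b),(c,d)),e);")
  agree <- parse_newick("(((a,b),(c,d)),e);")
  conflict <- parse_newick("(((a,c),(b,d)),e);")

  all_same <- map_gene_tree_support(ref, list(agree, agree))
  expect_true(all(all_same$support_fraction == 1))

  half <- map_gene_tree_support(ref, list(agree, conflict))
  ab <- half[half$side_a == "a,b", ]
  expect_equal(ab$support_fraction, 0.5)
  expect_equal(ab$n_informative, 2)

  # a gene tree missing species c is uninformative for the {c,d} split
  # (its restriction leaves d alone) but still counts for {a,b}
  missing_c <- parse_newick("((a,b),(d,e));")
  out <- map_gene_tree_support(ref, list(agree, missing_c))
  cd <- out[out$branch == "a,b,e|c,d", ]
  expect_equal(cd$n_informative, 1) # only the complete tree counts
  expect_equal(cd$support_fraction, 1)
  ab_row <- out[out$branch == "a,b|c,d,e", ]
  expect_equal(ab_row$n_informative, 2)
  expect_equal(ab_row$support_fraction, 1)

  # duplicated family contributes total weight 1 across its pruned trees
  dup <- parse_newick("((((a_1,b_1),(c_1,d_1)),e_1),(((a_2,c_2),(b_2,d_2)),e_2));")
  w <- map_gene_tree_support(ref, list(dup))
  ab2 <- w[w$side_a == "a,b", ]
  expect_equal(ab2$n_informative, 1)
  expect_equal(ab2$support_fraction, 0.5) # one pruned tree agrees, one conflicts

  expect_error(map_gene_tree_support(ref, list()), "empty")
})
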