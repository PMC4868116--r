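test_that("newick parsing reads structure, lengths, supports and dialects", {
  t <- parse_newick("(a,b);")
  expect_length(t$children, 2L)
  expect_equal(tree_leaves(t), c("a", "b"))
  expect_equal(t$children[[1]]$dist, 1) # default branch length

  t <- parse_newick("((a:1,b:2)0.9:0.5,c:3);")
  inner <- t$children[[1]]
  expect_equal(inner$support, 0.9)
  expect_equal(inner$dist, 0.5)
  expect_equal(vapply(c(inner$children, t$children[2]), `[[`, 0, "dist"), c(1, 2, 3))
  expect_true(is.na(t$children[[2]]$support)) # absent, not 1

  # internal label: numeric-in-[0,1] is support by default, name otherwise
  expect_equal(parse_newick("((a,b)90:1,c);")$children[[1]]$name, "90")
  expect_equal(parse_newick("((a,b)clade:1,c);", "named-internal")$children[[1]]$name, "clade")
  expect_equal(parse_newick("((a,b)0.5:1,c);", "named-internal")$children[[1]]$name, "0.5")
  expect_equal(parse_newick("((a,b)7:1,c);", "support-as-label")$children[[1]]$support, 7)

  # quoted labels and underscores survive verbatim
  expect_equal(tree_leaves(parse_newick("('sp one',b_2);")), c("sp one", "b_2"))
})

test_that("malformed newick fails with a character offset", {
  expect_error(parse_newick("((a,b);"), "character 1.*unbalanced")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("(a,b); junk"), "trailing")
  expect_error(parse_newick("(a,b)"), "';'")
  expect_error(parse_newick("(a:x,b);"), "branch length")
})

test_that("write_newick round-trips trees exactly", {
  for (nw in c("((a:1,b:2)0.9:0.5,c:3);",
               "(('sp one':0.1,b:2):0.5,c:3);",
               "a;",
               "((a,b)inner:2,(c,d));")) {
    dialect <- if (grepl("inner", nw)) "named-internal" else "default"
    t <- parse_newick(nw, dialect)
    expect_true(tree_equal(t, parse_newick(write_newick(t, dialect), dialect)),
                info = nw)
  }
  # property: parse . write is the identity on random trees, 1..64 leaves
  for (n in c(1L, 2L, 3L, 5L, 13L, 33L, 64L)) {
    t <- random_tree(n, seed = n)
    expect_true(tree_equal(t, parse_newick(write_newick(t))), info = n)
  }
})

test_that("traversal visits every node once in the requested order", {
  t <- parse_newick("((a,b),c);")
  post <- vapply(traverse(t, "postorder"),
                 function(n) if (nzchar(n$name)) n$name else "*", "")
  expect_equal(post, c("a", "b", "*", "c", "*"))
  pre <- traverse(t, "preorder")
  expect_true(tree_equal(pre[[1]], t)) # root first
  for (ord in c("preorder", "postorder", "levelorder")) {
    expect_length(traverse(t, ord), 5L)
    tt <- random_tree(9, seed = 3)
    expect_length(traverse(tt, ord), 17L) # 2n - 1 nodes in a rooted binary tree
  }
  expect_error(traverse(t, "inorder"))
})

test_that("bipartitions enumerate internal edges with both sides >= 2", {
  bp <- get_bipartitions(parse_newick("((a,b),(c,d));"))
  expect_length(bp, 1L)
  expect_equal(bp[[1]]$side_a, c("a", "b"))
  expect_equal(bp[[1]]$side_b, c("c", "d"))

  expect_length(get_bipartitions(parse_newick("((a,b),c);")), 0L)

  cat5 <- parse_newick("((((a,b),c),d),e);")
  keys <- vapply(get_bipartitions(cat5), `[[`, "", "key")
  expect_setequal(keys, c("a,b|c,d,e", "a,b,c|d,e"))

  expect_error(get_bipartitions(parse_newick("(a,(a,b));")), "duplicate")

  # brute-force edge-enumeration oracle on random trees up to 8 leaves
  for (n in 4:8) {
    for (s in 1:10) {
      t <- random_tree(n, seed = n * 100 + s)
      expect_setequal(vapply(get_bipartitions(t), `[[`, "", "key"),
                      bf_split_keys(t, tree_leaves(t)))
    }
  }
})

test_that("a degree-2 root contributes a single split (unrooted semantics)", {
  t <- parse_newick("((a,b),(c,d));")
  rerooted <- set_outgroup(t, "a")
  k1 <- vapply(get_bipartitions(t), `[[`, "", "key")
  k2 <- vapply(get_bipartitions(rerooted), `[[`, "", "key")
  expect_setequal(k1, k2)
  expect_equal(rf_distance(t, rerooted)$rf, 0L)
})

test_that("prune keeps the requested leaves and contracts unary nodes", {
  t <- parse_newick("((a:1,b:1):2,(c:1,d:3):1);")
  p <- prune(t, c("a", "c", "d"))
  expect_setequal(tree_leaves(p), c("a", "c", "d"))
  expect_equal(p$children[[1]]$name, "a")
  expect_equal(p$children[[1]]$dist, 3) # 1 + contracted 2

  expect_true(tree_equal(prune(t, tree_leaves(t)), t)) # identity

  single <- prune(t, "d")
  expect_equal(single$name, "d")
  expect_equal(single$dist, 4) # root -> d path length

  expect_error(prune(t, c("a", "zz")), "zz")

  # pruning commutes with pruning a superset first
  t8 <- random_tree(8, seed = 11)
  A <- paste0("t", 1:6); B <- paste0("t", c(1, 3, 5))
  expect_true(tree_equal(prune(prune(t8, A), B), prune(t8, B)))
})

test_that("set_outgroup preserves splits and leaf path lengths", {
  expect_error(set_outgroup(parse_newick("(a,b);"), "zz"), "not found")
  t <- parse_newick("((a,b),c);")
  t$name <- "r"
  expect_error(set_outgroup(t, "r"), "current root")

  for (s in 1:8) {
    t <- random_tree(7, seed = 400 + s)
    og <- sample(tree_leaves(t), 1)
    r <- set_outgroup(t, og)
    expect_setequal(tree_leaves(r), tree_leaves(t))
    expect_setequal(vapply(get_bipartitions(r), `[[`, "", "key"),
                    vapply(get_bipartitions(t), `[[`, "", "key"))
    d0 <- pairwise_leaf_dists(t)
    d1 <- pairwise_leaf_dists(r)
    expect_equal(d1[names(d0)], d0, tolerance = 1e-9)
  }
})

test_that("collapse_low_support contracts weak edges, never unsupported ones", {
  t <- parse_newick("((a,b)0.3,(c,d)0.9);")
  c1 <- collapse_low_support(t, 0.5)
  expect_length(c1$children, 3L) # polytomy (a, b, (c,d))
  expect_setequal(tree_leaves(c1), c("a", "b", "c", "d"))
  expect_equal(c1$children[[3]]$support, 0.9)

  expect_true(tree_equal(collapse_low_support(t, 0), t)) # nothing below 0

  # fully collapsed tree is a star with zero nontrivial splits
  star <- collapse_low_support(t, 1)
  expect_length(get_bipartitions(star), 0L)

  # absent support is not collapsed
  t2 <- parse_newick("((a,b),(c,d)0.9);")
  expect_true(tree_equal(collapse_low_support(t2, 0.99)$children[[1]],
                         t2$children[[1]]))
})

test_that("check_monophyly finds the smallest covering clade and intruders", {
  t <- parse_newick("((a,b),(c,d));")
  m <- check_monophyly(t, c("a", "b"))
  expect_true(m$is_monophyletic)
  expect_setequal(tree_leaves(m$clade), c("a", "b"))
  expect_length(m$intruders, 0L)

  m2 <- check_monophyly(parse_newick("((a,c),(b,d));"), c("a", "b"))
  expect_false(m2$is_monophyletic)
  expect_setequal(tree_leaves(m2$clade), c("a", "b", "c", "d")) # MRCA is root
  expect_setequal(m2$intruders, c("c", "d"))

  m3 <- check_monophyly(t, "a")
  expect_true(m3$is_monophyletic)
  expect_equal(m3$clade$name, "a")

  expect_error(check_monophyly(t, c("a", "zz")), "zz")
})

test_that("random_tree is reproducible and leaves the global RNG alone", {
  expect_identical(write_newick(random_tree(10, seed = 5)),
                   write_newick(random_tree(10, seed = 5)))
  expect_false(identical(write_newick(random_tree(10, seed = 5)),
                         write_newick(random_tree(10, seed = 6))))
  t1 <- random_tree(1, seed = 1)
  expect_equal(tree_leaves(t1), "t1")
  expect_error(random_tree(0), ">= 1")
  # binary rooted tree with n leaves has n - 1 internal nodes
  t <- random_tree(12, seed = 2)
  expect_length(traverse(t), 23L)
  set.seed(123); before <- runif(1)
  random_tree(50, seed = 9)
  set.seed(123); expect_identical(runif(1), before)
})

test_that("one-tree-per-line files are read and NHX output carries annotations", {
  f <- tempfile()
  writeLines(c("(a,b);", "", "# comment", "((a,b),c);"), f)
  trees <- read_newick(f)
  expect_length(trees, 2L)
  expect_equal(tree_leaves(trees[[2]]), c("a", "b", "c"))

  t <- parse_newick("(a:1,b:2);")
  t$children[[1]]$annotations$rank <- "species"
  expect_match(write_nhx(t), "a:1\\[&&NHX:rank=species\\]", fixed = FALSE)
})
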