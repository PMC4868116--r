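#' Construct a tree node
#'
#' The rooted-tree building block used throughout the package. A tree is
#' simply its root node; children are nested `tree_node` objects, so trees
#' are plain, copy-on-modify R values.
#'
#' @param name Node label (`""` when unnamed).
#' @param dist Branch length to the parent. Defaults to 1 when a newick
#'   string carries no `:x` suffix; the root's length is 0.
#' @param support Branch support in `[0, 1]`, or `NA` when unstated.
#'   Absent support is deliberately distinct from 0 or 1.
#' @param children List of child `tree_node` objects (empty for leaves).
#' @param annotations Named list of free-form annotations (used by the
#'   taxonomy and evolutionary-model layers).
#' @return A `tree_node` object.
#' @export
tree_node <- function(name = "", dist = 1, support = NA_real_,
                      children = list(), annotations = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  dist <- as.numeric(dist)
  if (is.na(dist) || dist < 0) stop("branch length must be a non-negative number")
  node <- list(name = name, dist = dist, support = as.numeric(support),
               children = children, annotations = annotations)
  class(node) <- "tree_node"
  node
}

is_leaf <- function(node) length(node$children) == 0L

#' @export
print.tree_node <- function(x, ...) {
  cat("<tree_node>", write_newick(x), "\n")
  cat("  leaves:", length(tree_leaves(x)), "\n")
  invisible(x)
}

# ---- newick parsing ---------------------------------------------------------

newick_error <- function(msg, offset) {
  stop(sprintf("newick parse error at character %d: %s", offset, msg), call. = FALSE)
}

# Tokenizer state is a mutable environment; recursion mirrors the grammar:
#   tree     := subtree ";"
#   subtree  := "(" subtree ("," subtree)* ")" label? | label?
#   label    := name? (":" number)?
parse_newick_impl <- function(text, dialect) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L

  peek <- function() if (st$pos > n) "" else chars[st$pos]
  advance <- function() st$pos <- st$pos + 1L
  skip_ws <- function() while (st$pos <= n && grepl("^\\s$", chars[st$pos])) advance()

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      start <- st$pos
      advance()
      out <- character()
      repeat {
        if (st$pos > n) newick_error("unterminated quoted label", start)
        ch <- chars[st$pos]
        if (ch == "'") {
          if (st$pos < n && chars[st$pos + 1L] == "'") { # escaped quote
            out <- c(out, "'"); st$pos <- st$pos + 2L
          } else { advance(); break }
        } else { out <- c(out, ch); advance() }
      }
      paste(out, collapse = "")
    } else {
      out <- character()
      while (st$pos <= n && !chars[st$pos] %in% c("(", ")", ",", ":", ";", "'")
             && !grepl("^\\s$", chars[st$pos])) {
        out <- c(out, chars[st$pos]); advance()
      }
      paste(out, collapse = "")
    }
  }

  read_dist <- function() {
    skip_ws()
    if (peek() != ":") return(NA_real_)
    advance(); skip_ws()
    start <- st$pos
    out <- character()
    while (st$pos <= n && grepl("^[-+0-9.eE]$", chars[st$pos])) {
      out <- c(out, chars[st$pos]); advance()
    }
    val <- suppressWarnings(as.numeric(paste(out, collapse = "")))
    if (length(out) == 0L || is.na(val)) newick_error("expected branch length after ':'", start)
    val
  }

  read_subtree <- function() {
    skip_ws()
    if (peek() == "(") {
      open_at <- st$pos
      advance()
      children <- list(read_subtree())
      repeat {
        skip_ws()
        if (peek() == ",") { advance(); children <- c(children, list(read_subtree())) }
        else break
      }
      skip_ws()
      if (peek() != ")") newick_error("unbalanced parentheses (unclosed '(')", open_at)
      advance()
      label <- read_label()
      dist <- read_dist()
      node <- tree_node(dist = if (is.na(dist)) 1 else dist, children = children)
      # internal-node label: support vs name depends on the dialect
      if (nzchar(label)) {
        num <- suppressWarnings(as.numeric(label))
        if (dialect == "named-internal") {
          node$name <- label
        } else if (dialect == "support-as-label") {
          if (is.na(num)) node$name <- label else node$support <- num
        } else { # default: bare numeric in [0,1] is support
          if (!is.na(num) && num >= 0 && num <= 1) node$support <- num
          else node$name <- label
        }
      }
      node
    } else {
      at <- st$pos
      label <- read_label()
      dist <- read_dist()
      if (!nzchar(label) && is.na(dist)) newick_error("expected a node", at)
      tree_node(name = label, dist = if (is.na(dist)) 1 else dist)
    }
  }

  skip_ws()
  if (st$pos > n) newick_error("empty newick string", 1L)
  root <- read_subtree()
  skip_ws()
  if (peek() != ";") newick_error("expected ';' terminator", st$pos)
  advance(); skip_ws()
  if (st$pos <= n) newick_error("trailing characters after ';'", st$pos)
  root$dist <- 0 # root has no parent edge
  root
}

#' Parse a newick string
#'
#' @param text A single newick statement terminated by `";"`.
#' @param dialect How to interpret a bare internal-node label:
#'   `"default"` reads a numeric label in `[0, 1]` as branch support and
#'   anything else as a name; `"named-internal"` always reads it as a name;
#'   `"support-as-label"` reads any numeric label as support.
#' @return The root `tree_node`.
#' @examples
#' t <- parse_newick("((a:1,b:2)0.9:0.5,c:3);")
#' tree_leaves(t)
#' @export
parse_newick <- function(text, dialect = c("default", "named-internal", "support-as-label")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  parse_newick_impl(text, dialect)
}

#' Read a one-tree-per-line newick file
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @inheritParams parse_newick
#' @param path File with one newick statement per line.
#' @return List of `tree_node` roots.
#' @export
read_newick <- function(path, dialect = "default") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_newick, dialect = dialect)
}

# shortest decimal rendering that survives a read-back
fmt_num <- function(x) {
  if (is.na(x)) return("")
  if (x == floor(x) && abs(x) < 1e15) return(sprintf("%d", as.integer(x)))
  s <- trimws(formatC(x, digits = 15, format = "g"))
  if (as.numeric(s) != x) s <- trimws(formatC(x, digits = 17, format = "g"))
  s
}

quote_label <- function(name) {
  if (grepl("[][ ():,;']", name)) {
    paste0("'", gsub("'", "''", name, fixed = TRUE), "'")
  } else name
}

#' Serialize a tree to newick
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(t))` reproduces
#' topology, names, branch lengths and supports.
#'
#' @param root A `tree_node`.
#' @param dialect `"default"` writes internal support values as bare labels
#'   (falling back to the name when support is absent); `"named-internal"`
#'   writes internal names and drops supports.
#' @return A newick string terminated by `";"`.
#' @export
write_newick <- function(root, dialect = c("default", "named-internal")) {
  dialect <- match.arg(dialect)
  wr <- function(node, is_root) {
    if (is_leaf(node)) {
      lab <- quote_label(node$name)
      return(paste0(lab, if (!is_root) paste0(":", fmt_num(node$dist))))
    }
    inner <- paste(vapply(node$children, wr, "", is_root = FALSE), collapse = ",")
    lab <- if (dialect == "named-internal") {
      quote_label(node$name)
    } else if (!is.na(node$support)) {
      fmt_num(node$support)
    } else {
      quote_label(node$name)
    }
    paste0("(", inner, ")", lab, if (!is_root) paste0(":", fmt_num(node$dist)))
  }
  paste0(wr(root, TRUE), ";")
}

#' Serialize a tree with annotations as NHX comment tags
#'
#' Like [write_newick()] but appends `[&&NHX:key=value]` tags carrying each
#' node's annotations (vector-valued annotations are joined with `|`).
#'
#' @param root A `tree_node`.
#' @return A newick/NHX string.
#' @export
write_nhx <- function(root) {
  tag <- function(node) {
    ann <- node$annotations
    ann <- ann[vapply(ann, function(v) is.atomic(v) && length(v) >= 1L, TRUE)]
    if (length(ann) == 0L) return("")
    kv <- vapply(names(ann), function(k)
      paste0(k, "=", paste(ann[[k]], collapse = "|")), "")
    paste0("[&&NHX:", paste(kv, collapse = ":"), "]")
  }
  wr <- function(node, is_root) {
    body <- if (is_leaf(node)) {
      quote_label(node$name)
    } else {
      inner <- paste(vapply(node$children, wr, "", is_root = FALSE), collapse = ",")
      lab <- if (!is.na(node$support)) fmt_num(node$support) else quote_label(node$name)
      paste0("(", inner, ")", lab)
    }
    paste0(body, if (!is_root) paste0(":", fmt_num(node$dist)), tag(node))
  }
  paste0(wr(root, TRUE), ";")
}

# ---- traversal and basic queries -------------------------------------------

#' Traverse a tree
#'
#' @param root A `tree_node`.
#' @param order `"preorder"`, `"postorder"` or `"levelorder"`.
#' @return List of `tree_node` objects, each visited exactly once.
#' @export
traverse <- function(root, order = c("preorder", "postorder", "levelorder")) {
  order <- match.arg(order)
  out <- list()
  if (order == "preorder") {
    rec <- function(node) {
      out[[length(out) + 1L]] <<- node
      for (ch in node$children) rec(ch)
    }
    rec(root)
  } else if (order == "postorder") {
    rec <- function(node) {
      for (ch in node$children) rec(ch)
      out[[length(out) + 1L]] <<- node
    }
    rec(root)
  } else {
    queue <- list(root)
    while (length(queue)) {
      node <- queue[[1L]]; queue <- queue[-1L]
      out[[length(out) + 1L]] <- node
      queue <- c(queue, node$children)
    }
  }
  out
}

#' Leaf labels of a tree
#'
#' @param root A `tree_node`.
#' @return Character vector of leaf names in tree order.
#' @export
tree_leaves <- function(root) {
  if (is_leaf(root)) return(root$name)
  unlist(lapply(root$children, tree_leaves), use.names = FALSE)
}

#' Structural tree equality
#'
#' Compares topology (with child order), names, branch lengths and supports.
#'
#' @param a,b `tree_node` objects.
#' @param tol Numeric tolerance for branch lengths and supports.
#' @return Logical scalar.
#' @export
tree_equal <- function(a, b, tol = 1e-9) {
  num_eq <- function(x, y) (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && abs(x - y) <= tol)
  if (!identical(a$name, b$name)) return(FALSE)
  if (!num_eq(a$dist, b$dist) || !num_eq(a$support, b$support)) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  for (i in seq_along(a$children)) {
    if (!tree_equal(a$children[[i]], b$children[[i]], tol)) return(FALSE)
  }
  TRUE
}

# ---- bipartitions -----------------------------------------------------------

make_bipartition <- function(side_a, side_b, support = NA_real_) {
  a <- sort(unique(side_a)); b <- sort(unique(side_b))
  ka <- paste(a, collapse = ","); kb <- paste(b, collapse = ",")
  if (kb < ka) { tmp <- a; a <- b; b <- tmp; ktmp <- ka; ka <- kb; kb <- ktmp }
  structure(list(side_a = a, side_b = b, support = support,
                 key = paste(ka, kb, sep = "|")),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(paste(x$side_a, collapse = ","), "|", paste(x$side_b, collapse = ","), "\n")
  invisible(x)
}

#' Nontrivial bipartitions induced by internal edges
#'
#' One split per internal edge whose two sides both retain at least two
#' labels after restriction to `universe`. The root carries no edge; a
#' degree-2 root's two edges induce the same split and are collapsed into
#' one (unrooted semantics), so differently rooted copies of one tree have
#' identical split sets.
#'
#' @param root A `tree_node` with unique leaf labels (after restriction).
#' @param universe Optional label set to restrict to (default: the tree's
#'   own leaf set).
#' @return List of `bipartition` objects (canonical, deduplicated).
#' @export
get_bipartitions <- function(root, universe = NULL) {
  leaves <- tree_leaves(root)
  if (is.null(universe)) universe <- leaves
  restricted <- intersect(leaves, universe)
  if (anyDuplicated(leaves[leaves %in% universe]))
    stop("duplicate leaf labels; map to species or disambiguate first")
  out <- list()
  seen <- character()
  rec <- function(node, at_root) {
    if (is_leaf(node)) {
      return(if (node$name %in% universe) node$name else character())
    }
    below <- unlist(lapply(node$children, rec, at_root = FALSE), use.names = FALSE)
    if (!at_root) {
      side_a <- below
      side_b <- setdiff(restricted, side_a)
      if (length(side_a) >= 2L && length(side_b) >= 2L) {
        bp <- make_bipartition(side_a, side_b, node$support)
        if (!bp$key %in% seen) {
          seen <<- c(seen, bp$key)
          out[[length(out) + 1L]] <<- bp
        }
      }
    }
    below
  }
  rec(root, TRUE)
  out
}

split_keys <- function(bips) vapply(bips, `[[`, "", "key")

# ---- pruning, rooting, collapsing ------------------------------------------

#' Prune a tree to a set of leaves
#'
#' Unary internal nodes arising from the pruning are contracted with branch
#' lengths summed; annotations on surviving nodes are preserved.
#'
#' @param root A `tree_node`.
#' @param keep Leaf labels to retain (must all exist; at least one).
#' @return The pruned `tree_node`.
#' @export
prune <- function(root, keep) {
  leaves <- tree_leaves(root)
  missing <- setdiff(keep, leaves)
  if (length(missing))
    stop("unknown leaf labels: ", paste(missing, collapse = ", "))
  if (length(keep) < 1L) stop("keep must contain at least one label")
  rec <- function(node) {
    if (is_leaf(node)) {
      return(if (node$name %in% keep) node else NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) { # contract unary node
      child <- kids[[1L]]
      child$dist <- child$dist + node$dist
      return(child)
    }
    node$children <- kids
    node
  }
  rec(root)
}

# path of child indices from root to the first node matching `label`
# (leaf name, or internal name); NULL when absent, integer(0) for the root.
find_path <- function(root, label) {
  rec <- function(node) {
    if (identical(node$name, label)) return(integer())
    for (i in seq_along(node$children)) {
      sub <- rec(node$children[[i]])
      if (!is.null(sub)) return(c(i, sub))
    }
    NULL
  }
  rec(root)
}

node_at <- function(root, path) {
  for (i in path) root <- root$children[[i]]
  root
}

#' Re-root a tree on the edge above a node
#'
#' Places a new degree-2 root at the midpoint of the branch above
#' `outgroup`. Leaf set, pairwise leaf-path lengths and the unrooted split
#' set are unchanged.
#'
#' @param root A `tree_node`.
#' @param outgroup Label of a leaf (or named internal node) other than the
#'   current root.
#' @return The re-rooted `tree_node`.
#' @export
set_outgroup <- function(root, outgroup) {
  path <- find_path(root, outgroup)
  if (is.null(path)) stop("outgroup '", outgroup, "' not found in tree")
  if (length(path) == 0L) stop("outgroup is the current root")
  # chain n0 (root) .. nk (target); rebuild the non-target side inside out
  chain <- vector("list", length(path) + 1L)
  chain[[1L]] <- root
  for (j in seq_along(path)) chain[[j + 1L]] <- node_at(root, path[seq_len(j)])
  k <- length(path)
  target <- chain[[k + 1L]]

  # M starts as the old root minus the path child; flipping each edge hands
  # the child's length/support to the node now hanging below it
  m <- chain[[1L]]
  m$children <- m$children[-path[1L]]
  m$dist <- chain[[2L]]$dist
  m$support <- chain[[2L]]$support
  edge_len <- chain[[k + 1L]]$dist
  if (length(m$children) == 1L) { # old degree-2 root vanishes
    only <- m$children[[1L]]
    if (is.na(only$support)) only$support <- m$support
    if (k == 1L) {
      # target and its sibling share one unrooted edge of combined length
      edge_len <- edge_len + only$dist
      only$dist <- 0
    } else {
      only$dist <- only$dist + m$dist
    }
    m <- only
  }
  if (k >= 2L) {
    for (j in 2L:k) {
      nj <- chain[[j]]
      nj$children <- c(nj$children[-path[j]], list(m))
      nj$dist <- chain[[j + 1L]]$dist
      nj$support <- chain[[j + 1L]]$support
      m <- nj
    }
  }
  half <- edge_len / 2
  target$dist <- half
  m$dist <- half
  tree_node(name = "", dist = 0, children = list(target, m))
}

#' Collapse poorly supported branches into polytomies
#'
#' Every internal edge whose support is below `min_support` is contracted:
#' its children are lifted to the grandparent with the contracted edge's
#' length added, forming a polytomy. Edges with absent support are never
#' collapsed (missing data is not evidence of weakness). Leaves are
#' untouched.
#'
#' @param root A `tree_node`.
#' @param min_support Threshold in `[0, 1]`; edges with `support <
#'   min_support` are removed.
#' @return The collapsed `tree_node`.
#' @export
collapse_low_support <- function(root, min_support) {
  stopifnot(min_support >= 0, min_support <= 1)
  rec <- function(node) {
    if (is_leaf(node)) return(list(node))
    new_kids <- list()
    for (ch in node$children) {
      pieces <- rec(ch)
      new_kids <- c(new_kids, pieces)
    }
    node$children <- new_kids
    if (!is.na(node$support) && node$support < min_support) {
      # contract this edge: lift children, preserving root-to-leaf lengths
      lifted <- lapply(node$children, function(ch) { ch$dist <- ch$dist + node$dist; ch })
      return(lifted)
    }
    list(node)
  }
  new_kids <- list()
  for (ch in root$children) new_kids <- c(new_kids, rec(ch))
  root$children <- new_kids
  root
}

#' Test monophyly of a set of leaves
#'
#' @param root A `tree_node`.
#' @param labels Non-empty set of leaf labels, all present in the tree.
#' @return List with `is_monophyletic` (logical), `clade` (the smallest
#'   clade containing all labels) and `intruders` (extra leaves inside that
#'   clade, empty when monophyletic).
#' @export
check_monophyly <- function(root, labels) {
  leaves <- tree_leaves(root)
  missing <- setdiff(labels, leaves)
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (length(missing)) stop("unknown leaf labels: ", paste(missing, collapse = ", "))
  mrca <- function(node) {
    # smallest clade whose leaf set covers `labels`
    for (ch in node$children) {
      if (all(labels %in% tree_leaves(ch))) return(mrca(ch))
    }
    node
  }
  clade <- mrca(root)
  intruders <- setdiff(tree_leaves(clade), labels)
  list(is_monophyletic = length(intruders) == 0L, clade = clade, intruders = intruders)
}

# ---- random trees -----------------------------------------------------------

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random binary tree
#'
#' Topology by repeated random joins; branch lengths are exponential with
#' mean 0.1. Fully reproducible from `seed` without disturbing the global
#' RNG state.
#'
#' @param n_leaves Number of leaves (`>= 1`).
#' @param seed Integer seed.
#' @param label_prefix Leaf labels are `paste0(label_prefix, 1:n_leaves)`.
#' @return A `tree_node`.
#' @export
random_tree <- function(n_leaves, seed = 42L, label_prefix = "t") {
  if (n_leaves < 1L) stop("n_leaves must be >= 1")
  with_seed(seed, {
    pool <- lapply(seq_len(n_leaves), function(i)
      tree_node(name = paste0(label_prefix, i), dist = stats::rexp(1, rate = 10)))
    while (length(pool) > 1L) {
      idx <- sample.int(length(pool), 2L)
      joined <- tree_node(dist = stats::rexp(1, rate = 10),
                          children = pool[idx])
      pool <- c(pool[-idx], list(joined))
    }
    root <- pool[[1L]]
    root$dist <- 0
    root
  })
}
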