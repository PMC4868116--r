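#' @title Local taxonomy databases in NCBI taxdump format
#' @description Build an offline taxonomy store from `nodes.dmp`,
#'   `names.dmp` and (optionally) `merged.dmp`, then run lineage, name and
#'   topology queries without any network access.
#' @name taxonomy
NULL

# taxdump dialect: fields separated by "\t|\t", rows terminated by "\t|"
parse_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

normalize_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Build a taxonomy database from taxdump files
#'
#' Parses the NCBI dump dialect (`\t|\t` field separators, `\t|` row
#' terminators). `nodes.dmp` supplies taxid, parent and rank; `names.dmp`
#' supplies scientific names (authoritative) and synonyms; `merged.dmp`
#' supplies old-to-new taxid redirects, with chains collapsed at build so
#' every lookup follows at most one hop.
#'
#' @param nodes_file,names_file,merged_file Paths to the dump files
#'   (`merged_file` optional).
#' @param store Optional path: when given, the built database is persisted
#'   there with [save_taxdb()] (deterministic, so rebuilding from the same
#'   dumps is byte-identical).
#' @return A `taxonomy_db` object.
#' @export
build_taxdb <- function(nodes_file, names_file, merged_file = NULL, store = NULL) {
  rows <- parse_dmp(nodes_file)
  if (length(rows) == 0L) stop("empty nodes file: ", nodes_file)
  taxid <- vapply(rows, function(r) as.integer(r[1L]), 0L)
  parent <- vapply(rows, function(r) as.integer(r[2L]), 0L)
  rank <- vapply(rows, function(r) if (length(r) >= 3L) r[3L] else "no rank", "")
  orphans <- setdiff(parent, taxid)
  if (length(orphans))
    stop("parent taxids missing from nodes: ", paste(sort(orphans), collapse = ", "))

  nrows <- parse_dmp(names_file)
  n_taxid <- vapply(nrows, function(r) as.integer(r[1L]), 0L)
  n_name <- vapply(nrows, function(r) r[2L], "")
  n_class <- vapply(nrows, function(r) if (length(r) >= 4L) r[4L] else "", "")
  sci <- stats::setNames(n_name[n_class == "scientific name"],
                         n_taxid[n_class == "scientific name"])
  nameless <- setdiff(taxid, as.integer(names(sci)))
  if (length(nameless))
    stop("taxids with no scientific name: ", paste(sort(nameless), collapse = ", "))

  syn <- list()
  for (i in which(n_class != "scientific name")) {
    key <- as.character(n_taxid[i])
    syn[[key]] <- c(syn[[key]], n_name[i])
  }

  merged <- integer()
  if (!is.null(merged_file) && file.exists(merged_file)) {
    mrows <- parse_dmp(merged_file)
    if (length(mrows)) {
      old <- vapply(mrows, function(r) as.integer(r[1L]), 0L)
      new <- vapply(mrows, function(r) as.integer(r[2L]), 0L)
      merged <- stats::setNames(new, old)
      # collapse chains so resolution is a single hop
      repeat {
        hop <- match(as.character(merged), names(merged))
        if (all(is.na(hop))) break
        merged[!is.na(hop)] <- merged[hop[!is.na(hop)]]
      }
    }
  }

  ord <- order(taxid)
  records <- data.frame(taxid = taxid[ord], parent = parent[ord],
                        rank = rank[ord],
                        sci_name = unname(sci[as.character(taxid[ord])]),
                        stringsAsFactors = FALSE)
  db <- structure(list(records = records, synonyms = syn, merged = merged),
                  class = "taxonomy_db")
  db <- index_names(db)
  if (!is.null(store)) save_taxdb(db, store)
  db
}

index_names <- function(db) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  add <- function(name, taxid) {
    key <- normalize_name(name)
    assign(key, sort(unique(c(if (exists(key, idx)) get(key, idx), taxid))), idx)
  }
  for (i in seq_len(nrow(db$records))) add(db$records$sci_name[i], db$records$taxid[i])
  for (key in names(db$synonyms)) {
    for (nm in db$synonyms[[key]]) add(nm, as.integer(key))
  }
  db$name_index <- idx
  db
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("<taxonomy_db> %d taxa, %d merge redirects\n",
              nrow(x$records), length(x$merged)))
  invisible(x)
}

#' Persist / reload a taxonomy database
#'
#' A single plain-text store file with deterministic ordering: rebuilding
#' from identical dumps yields a byte-identical store.
#'
#' @param db A `taxonomy_db`.
#' @param path Store file path.
#' @return `save_taxdb` returns `path` invisibly; `load_taxdb` returns the
#'   `taxonomy_db`.
#' @export
save_taxdb <- function(db, path) {
  con <- file(path, open = "wb") # binary mode: fixed "\n" on every platform
  on.exit(close(con))
  writeLines("#taxdb\t1", con)
  r <- db$records
  writeLines(sprintf("R\t%d\t%d\t%s\t%s", r$taxid, r$parent, r$rank, r$sci_name), con)
  for (key in as.character(sort(as.integer(names(db$synonyms))))) {
    for (nm in sort(db$synonyms[[key]]))
      writeLines(sprintf("S\t%s\t%s", key, nm), con)
  }
  if (length(db$merged)) {
    ord <- order(as.integer(names(db$merged)))
    writeLines(sprintf("M\t%s\t%d", names(db$merged)[ord], unname(db$merged)[ord]), con)
  }
  invisible(path)
}

#' @rdname save_taxdb
#' @export
load_taxdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "#taxdb"))
    stop("not a taxdb store: ", path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, "", 1L)
  rrec <- parts[tag == "R"]
  records <- data.frame(
    taxid = vapply(rrec, function(p) as.integer(p[2L]), 0L),
    parent = vapply(rrec, function(p) as.integer(p[3L]), 0L),
    rank = vapply(rrec, `[[`, "", 4L),
    sci_name = vapply(rrec, `[[`, "", 5L),
    stringsAsFactors = FALSE)
  syn <- list()
  for (p in parts[tag == "S"]) syn[[p[2L]]] <- c(syn[[p[2L]]], p[3L])
  mrec <- parts[tag == "M"]
  merged <- stats::setNames(vapply(mrec, function(p) as.integer(p[3L]), 0L),
                            vapply(mrec, `[[`, "", 2L))
  db <- structure(list(records = records, synonyms = syn, merged = merged),
                  class = "taxonomy_db")
  index_names(db)
}

#' Write synthetic taxdump files
#'
#' Emits `nodes.dmp`, `names.dmp` and `merged.dmp` in the exact dialect
#' [build_taxdb()] consumes, from an in-code description. Used for fixtures
#' and tests; no download is ever needed.
#'
#' @param spec Data frame with columns `taxid`, `parent`, `rank`, `name`;
#'   must form a tree rooted at the record whose parent equals its own
#'   taxid.
#' @param merges Optional data frame with columns `old`, `new`.
#' @param out_dir Directory to write into (created if needed).
#' @return Named character vector of the three file paths.
#' @export
synthetic_taxdump <- function(spec, merges = NULL, out_dir = tempfile("taxdump")) {
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(spec)))
  if (!all(spec$parent %in% spec$taxid)) stop("spec has parents outside the spec")
  roots <- spec$taxid[spec$taxid == spec$parent]
  if (length(roots) != 1L) stop("spec must have exactly one root (parent == taxid)")
  # cycle check: every node must reach the root
  parent_of <- stats::setNames(spec$parent, spec$taxid)
  for (t0 in spec$taxid) {
    seen <- integer(); t <- t0
    while (t != roots) {
      if (t %in% seen) stop("cycle in spec involving taxid ", t0)
      seen <- c(seen, t)
      t <- parent_of[[as.character(t)]]
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- file.path(out_dir, "nodes.dmp")
  names_f <- file.path(out_dir, "names.dmp")
  merged_f <- file.path(out_dir, "merged.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", spec$taxid, spec$parent, spec$rank), nodes)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", spec$taxid, spec$name),
             names_f)
  if (!is.null(merges) && nrow(merges)) {
    writeLines(sprintf("%d\t|\t%d\t|", merges$old, merges$new), merged_f)
  } else writeLines(character(), merged_f)
  c(nodes = nodes, names = names_f, merged = merged_f)
}

#' Canonical 5-taxon synthetic taxonomy fixture
#'
#' root(1) with superkingdoms Bacteria(2) and Eukaryota(3), genus Homo(4)
#' and species Homo sapiens(5); taxid 6 is merged into 5.
#'
#' @return List with elements `spec` and `merges`, suitable for
#'   [synthetic_taxdump()].
#' @export
example_taxdump <- function() {
  list(
    spec = data.frame(
      taxid = c(1L, 2L, 3L, 4L, 5L),
      parent = c(1L, 1L, 1L, 3L, 4L),
      rank = c("no rank", "superkingdom", "superkingdom", "genus", "species"),
      name = c("root", "Bacteria", "Eukaryota", "Homo", "Homo sapiens"),
      stringsAsFactors = FALSE),
    merges = data.frame(old = 6L, new = 5L))
}

resolve_merged <- function(db, taxids) {
  hit <- match(as.character(taxids), names(db$merged))
  taxids[!is.na(hit)] <- unname(db$merged[hit[!is.na(hit)]])
  taxids
}

db_root <- function(db) db$records$taxid[db$records$taxid == db$records$parent][1L]

#' Translate taxids to scientific names
#'
#' Merged ids are resolved first; unknown ids are collected in a `missing`
#' list rather than raising an error (batch pipelines must survive partial
#' data).
#'
#' @param db A `taxonomy_db`.
#' @param taxids Integer vector.
#' @return List with `names` (named character vector keyed by the input
#'   ids), `missing` (unknown ids) and `redirected` (ids resolved through a
#'   merge, as a named vector old -> new).
#' @export
translate_taxids <- function(db, taxids) {
  taxids <- as.integer(taxids)
  resolved <- resolve_merged(db, taxids)
  redirected <- stats::setNames(resolved[resolved != taxids], taxids[resolved != taxids])
  hit <- match(resolved, db$records$taxid)
  found <- !is.na(hit)
  list(names = stats::setNames(db$records$sci_name[hit[found]], taxids[found]),
       missing = taxids[!found],
       redirected = redirected)
}

#' Translate names to taxids
#'
#' Case-insensitive exact matching (internal whitespace collapsed) against
#' scientific names and synonyms; ambiguous names return every hit.
#'
#' @param db A `taxonomy_db`.
#' @param names Character vector.
#' @return List with `taxids` (named list name -> integer vector) and
#'   `missing`.
#' @export
translate_names <- function(db, names) {
  out <- list(); miss <- character()
  for (nm in names) {
    key <- normalize_name(nm)
    if (exists(key, db$name_index)) out[[nm]] <- get(key, db$name_index)
    else miss <- c(miss, nm)
  }
  list(taxids = out, missing = miss)
}

#' Full lineage of a taxid
#'
#' @param db A `taxonomy_db`.
#' @param taxid A known taxid (merged ids resolve first; unknown ids are an
#'   error — lineage is a single-subject query).
#' @return List with `lineage` (taxids ordered root to self) and `ranks`
#'   (character vector, named by taxid).
#' @export
get_lineage <- function(db, taxid) {
  taxid <- resolve_merged(db, as.integer(taxid)[1L])
  if (!taxid %in% db$records$taxid) stop("unknown taxid: ", taxid)
  path <- integer()
  t <- taxid
  repeat {
    path <- c(t, path)
    i <- match(t, db$records$taxid)
    p <- db$records$parent[i]
    if (p == t) break
    t <- p
  }
  ranks <- db$records$rank[match(path, db$records$taxid)]
  list(lineage = path, ranks = stats::setNames(ranks, path))
}

#' Descendant taxids of a taxon
#'
#' @param db A `taxonomy_db`.
#' @param taxid A known taxid.
#' @param rank_filter Optional rank to restrict to (e.g. `"species"`).
#' @return Sorted integer vector of strict descendants.
#' @export
get_descendants <- function(db, taxid, rank_filter = NULL) {
  taxid <- resolve_merged(db, as.integer(taxid)[1L])
  if (!taxid %in% db$records$taxid) stop("unknown taxid: ", taxid)
  kids_of <- split(db$records$taxid, db$records$parent)
  out <- integer(); frontier <- taxid
  while (length(frontier)) {
    nxt <- unlist(kids_of[as.character(frontier)], use.names = FALSE)
    nxt <- setdiff(nxt, c(out, taxid)) # root is its own parent
    out <- c(out, nxt)
    frontier <- nxt
  }
  if (!is.null(rank_filter))
    out <- out[db$records$rank[match(out, db$records$taxid)] == rank_filter]
  sort(out)
}

annotate_taxon_node <- function(node, db, taxid) {
  i <- match(taxid, db$records$taxid)
  node$annotations$taxid <- taxid
  node$annotations$sci_name <- db$records$sci_name[i]
  node$annotations$rank <- db$records$rank[i]
  node
}

#' Minimal taxonomy topology spanning a set of taxids
#'
#' Returns the pruned subtree of the taxonomy connecting the given taxids.
#' Leaves are the input taxids; an input taxid that is an ancestor of
#' another input appears as an annotated internal node rather than a
#' duplicated leaf. With `collapse_intermediate` (default), unary chains of
#' non-input taxa are contracted. Every node carries `taxid`, `sci_name`
#' and `rank` annotations and is named by its scientific name.
#'
#' @param db A `taxonomy_db`.
#' @param taxids Integer vector (at least one must be known; unknown ids
#'   are dropped with a warning).
#' @param collapse_intermediate Contract unary non-input nodes.
#' @return A `tree_node`.
#' @export
get_topology <- function(db, taxids, collapse_intermediate = TRUE) {
  taxids <- unique(resolve_merged(db, as.integer(taxids)))
  known <- taxids[taxids %in% db$records$taxid]
  if (length(known) == 0L) stop("none of the taxids are known")
  if (length(known) < length(taxids))
    warning("dropping unknown taxids: ",
            paste(setdiff(taxids, known), collapse = ", "))
  lineages <- lapply(known, function(t) get_lineage(db, t)$lineage)
  keep <- unique(unlist(lineages, use.names = FALSE))
  kids_of <- split(db$records$taxid, db$records$parent)
  build <- function(taxid) {
    kids <- setdiff(kids_of[[as.character(taxid)]], taxid)
    kids <- kids[kids %in% keep]
    node <- tree_node(dist = 1, children = lapply(sort(kids), build))
    node <- annotate_taxon_node(node, db, taxid)
    node$name <- node$annotations$sci_name
    node
  }
  # start from the LCA of the inputs (deepest common lineage element)
  common <- lineages[[1L]]
  for (l in lineages[-1L]) common <- common[seq_len(max(which(common %in% l)))]
  root <- build(common[length(common)])
  root$dist <- 0
  if (collapse_intermediate) {
    contract <- function(node) {
      node$children <- lapply(node$children, contract)
      if (length(node$children) == 1L && !node$annotations$taxid %in% known) {
        only <- node$children[[1L]]
        only$dist <- only$dist + node$dist
        return(only)
      }
      node
    }
    kids <- lapply(root$children, contract)
    root$children <- kids
  }
  root
}

leaf_taxid <- function(leaf, db, leaf_attr) {
  if (leaf_attr == "taxid-annotation") {
    t <- leaf$annotations$taxid
    if (is.null(t)) return(NA_integer_)
    return(resolve_merged(db, as.integer(t)))
  }
  nm <- leaf$name
  if (grepl("^[0-9]+$", nm)) return(resolve_merged(db, as.integer(nm)))
  hits <- translate_names(db, nm)$taxids[[nm]]
  if (is.null(hits) || length(hits) != 1L) return(NA_integer_)
  hits
}

#' Annotate a user tree with taxonomic data
#'
#' Leaves named by taxid or resolvable scientific name (or carrying a
#' `taxid` annotation) gain `taxid`, `sci_name`, `rank`, `lineage` and
#' `named_lineage` annotations; unresolvable leaves are annotated
#' `unresolved = TRUE`, never fatally. Each internal node gains the lowest
#' common ancestor taxid (plus name and rank) of its resolvable leaves.
#'
#' @param db A `taxonomy_db`.
#' @param root A `tree_node`.
#' @param leaf_attr `"name"` to resolve leaf names, `"taxid-annotation"` to
#'   use an existing `taxid` annotation.
#' @return The annotated `tree_node`.
#' @export
annotate_tree <- function(db, root, leaf_attr = c("name", "taxid-annotation")) {
  leaf_attr <- match.arg(leaf_attr)
  any_resolved <- FALSE
  rec <- function(node) {
    if (is_leaf(node)) {
      t <- leaf_taxid(node, db, leaf_attr)
      if (is.na(t) || !t %in% db$records$taxid) {
        node$annotations$unresolved <- TRUE
        attr(node, "lin") <- NULL
      } else {
        any_resolved <<- TRUE
        lin <- get_lineage(db, t)$lineage
        node <- annotate_taxon_node(node, db, t)
        node$annotations$lineage <- lin
        node$annotations$named_lineage <-
          db$records$sci_name[match(lin, db$records$taxid)]
        attr(node, "lin") <- lin
      }
      return(node)
    }
    node$children <- lapply(node$children, rec)
    lins <- Filter(Negate(is.null), lapply(node$children, attr, "lin"))
    if (length(lins)) {
      common <- lins[[1L]]
      for (l in lins[-1L]) {
        n <- 0L
        while (n < min(length(common), length(l)) && common[n + 1L] == l[n + 1L])
          n <- n + 1L
        common <- common[seq_len(n)]
      }
      node <- annotate_taxon_node(node, db, common[length(common)])
      attr(node, "lin") <- common
    } else attr(node, "lin") <- NULL
    node
  }
  out <- rec(root)
  if (!any_resolved) stop("no leaf could be resolved against the taxonomy")
  strip <- function(node) {
    attr(node, "lin") <- NULL
    node$children <- lapply(node$children, strip)
    node
  }
  strip(out)
}
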