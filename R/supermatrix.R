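ALPHABET_CHARS <- list(
  aa = c(strsplit("ACDEFGHIKLMNPQRSTVWYBZXUO*", "")[[1L]], "-", "?", "."),
  nt = c(strsplit("ACGTUNRYSWKMBDHV", "")[[1L]], "-", "?", "."))

#' Construct a multiple sequence alignment
#'
#' A thin container: an ordered, named set of equal-length gapped
#' sequences plus an alphabet tag. `-` is an alignment gap, `?` missing
#' data — the distinction matters downstream (see
#' [concat_alignments()]).
#'
#' @param seqs Named character vector, one gapped sequence per species.
#' @param alphabet `"aa"` or `"nt"`.
#' @param name Optional partition name (used in partition tables).
#' @return An `msa` object.
#' @export
msa <- function(seqs, alphabet = c("aa", "nt"), name = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must be named by its species label")
  if (anyDuplicated(names(seqs))) stop("duplicate species labels")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length: ", paste(unique(lens), collapse = ", "))
  ok <- ALPHABET_CHARS[[alphabet]]
  bad <- unique(unlist(strsplit(seqs, ""), use.names = FALSE))
  bad <- setdiff(bad, ok)
  if (length(bad))
    stop("characters outside the ", alphabet, " alphabet: ",
         paste(bad, collapse = " "))
  structure(list(seqs = seqs, alphabet = alphabet, length = unname(lens[1L]),
                 name = name),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa%s> %d species x %d %s columns\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$seqs), x$length, x$alphabet))
  invisible(x)
}

#' Read / write alignments as FASTA
#'
#' I/O goes through Biostrings; sequences are validated against the stated
#' alphabet on read.
#'
#' @param path FASTA file.
#' @param alphabet `"aa"` or `"nt"`.
#' @param name Optional partition name (defaults to the file base name).
#' @return `read_msa` returns an `msa`; `write_msa` returns `path`
#'   invisibly.
#' @export
read_msa <- function(path, alphabet = c("aa", "nt"), name = NULL) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  msa(seqs, alphabet, name = name)
}

#' @rdname read_msa
#' @param aln An `msa`.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  set <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Concatenate alignments into a supermatrix
#'
#' Columns are appended in input order. Under the `union` species policy a
#' species absent from an alignment is padded with `?` (missing data, not
#' the gap character `-`) across that partition; under `intersection` only
#' species present in every alignment are kept. The returned partition
#' table records each source alignment's 1-based inclusive column range.
#'
#' @param alignments List of `msa` objects sharing one alphabet.
#' @param species_policy `"union"` or `"intersection"`.
#' @return List with `alignment` (the concatenated `msa`) and `partitions`
#'   (data frame: `name`, `start`, `end`).
#' @export
concat_alignments <- function(alignments, species_policy = c("union", "intersection")) {
  species_policy <- match.arg(species_policy)
  if (length(alignments) < 1L) stop("need at least one alignment")
  stopifnot(all(vapply(alignments, inherits, TRUE, "msa")))
  alphabets <- unique(vapply(alignments, `[[`, "", "alphabet"))
  if (length(alphabets) != 1L)
    stop("alphabet mismatch across inputs: ", paste(alphabets, collapse = " vs "))
  species_sets <- lapply(alignments, function(a) names(a$seqs))
  species <- if (species_policy == "union") {
    unique(unlist(species_sets, use.names = FALSE)) # first-seen order
  } else {
    Reduce(intersect, species_sets)
  }
  if (length(species) == 0L)
    stop("empty species intersection; use the union policy")
  parts <- character(length(species))
  names(parts) <- species
  starts <- integer(length(alignments)); ends <- integer(length(alignments))
  pos <- 0L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    pad <- strrep("?", a$length)
    block <- ifelse(species %in% names(a$seqs), unname(a$seqs[species]), pad)
    parts <- paste0(parts, block)
    starts[i] <- pos + 1L
    ends[i] <- pos + a$length
    pos <- pos + a$length
  }
  names(parts) <- species
  part_names <- vapply(seq_along(alignments), function(i) {
    nm <- alignments[[i]]$name
    if (is.null(nm) || !nzchar(nm)) paste0("p", i) else nm
  }, "")
  list(alignment = msa(parts, alphabets, name = "supermatrix"),
       partitions = data.frame(name = part_names, start = starts, end = ends,
                               stringsAsFactors = FALSE))
}

#' Write a partition table
#'
#' @param partitions Data frame as returned by [concat_alignments()].
#' @param path Output file.
#' @param format `"raxml"` writes `MODEL, name = start-end` lines (`WAG`
#'   for amino acids, `DNA` for nucleotides); `"tsv"` writes a plain
#'   three-column table.
#' @param alphabet Alphabet of the supermatrix (selects the RAxML model
#'   token).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path, format = c("raxml", "tsv"),
                             alphabet = c("aa", "nt")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  lines <- if (format == "raxml") {
    model <- if (alphabet == "aa") "WAG" else "DNA"
    sprintf("%s, %s = %d-%d", model, partitions$name, partitions$start, partitions$end)
  } else {
    c("name\tstart\tend",
      sprintf("%s\t%d\t%d", partitions$name, partitions$start, partitions$end))
  }
  writeLines(lines, path)
  invisible(path)
}
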