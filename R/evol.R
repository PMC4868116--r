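#' Construct a fitted evolutionary model record
#'
#' Holds the summary of one codon-model fit (as produced externally by
#' maximum-likelihood engines): the log-likelihood and parameter count used
#' by the likelihood ratio test, plus optional per-branch dN/dS (omega)
#' estimates and per-site records.
#'
#' @param model_id Model name; canonical ids combine family and name, e.g.
#'   site models `"M0"`, `"M1"`, `"M2"`, `"M3"`, `"M7"`, `"M8"`, branch
#'   models `"b_free"`, `"fb"` (free-ratio), branch-site `"bsA"`/`"bsA1"`.
#' @param lnL Finite log-likelihood at the optimum.
#' @param n_params Number of free parameters (`>= 1`).
#' @param branch_omegas Named numeric vector branch-id -> omega
#'   (non-negative; `Inf` encodes a saturated dN/dS estimate).
#' @param site_records Optional data frame with columns `site` (1-based
#'   alignment column), `omega`, `p_value`, and optionally class
#'   probability columns `p0`, `p1`, ... summing to 1.
#' @return A `model_fit` object.
#' @export
model_fit <- function(model_id, lnL, n_params, branch_omegas = numeric(),
                      site_records = NULL) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  if (!is.finite(lnL)) stop("lnL must be finite")
  if (n_params < 1L) stop("n_params must be >= 1")
  if (any(branch_omegas < 0, na.rm = TRUE)) stop("omegas must be non-negative")
  if (!is.null(site_records)) {
    stopifnot(is.data.frame(site_records), all(c("site", "omega") %in% names(site_records)))
    if (anyDuplicated(site_records$site)) stop("duplicate site indices")
    pcols <- grep("^p[0-9]+$", names(site_records), value = TRUE)
    if (length(pcols)) {
      sums <- rowSums(site_records[pcols])
      if (any(abs(sums - 1) > 1e-6))
        stop("site class probabilities must sum to 1")
    }
  }
  structure(list(model_id = model_id, lnL = lnL, n_params = as.integer(n_params),
                 branch_omegas = branch_omegas, site_records = site_records),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: lnL = %.4f, %d parameters", x$model_id, x$lnL, x$n_params))
  if (length(x$branch_omegas)) cat(sprintf(", %d branch omegas", length(x$branch_omegas)))
  if (!is.null(x$site_records)) cat(sprintf(", %d sites", nrow(x$site_records)))
  cat("\n")
  invisible(x)
}

#' Registered nested model pairs
#'
#' The canonical null/alternative pairs tested by default: M1 vs M2 and
#' M7 vs M8 (site models), M0 vs M3 (rate variation), bsA1 vs bsA
#' (branch-site), M0 vs b_free and M0 vs fb (branch models). Pairs outside
#' this table need an explicit `df` override in [lrt()].
#'
#' @return Data frame with columns `null`, `alt`.
#' @export
default_model_pairs <- function() {
  data.frame(
    null = c("M1", "M7", "M0", "bsA1", "M0", "M0"),
    alt  = c("M2", "M8", "M3", "bsA",  "b_free", "fb"),
    stringsAsFactors = FALSE)
}

#' Likelihood ratio test between nested model fits
#'
#' `D = 2 (lnL_alt - lnL_null)` compared to a chi-square with
#' `df = n_params_alt - n_params_null` degrees of freedom. A negative `D`
#' (optimizer noise in real fits) is clamped to 0 with a warning. Pair
#' nestedness is asserted against [default_model_pairs()]; unregistered
#' pairs require an explicit `df`.
#'
#' @param null,alt `model_fit` objects; `alt` must have more parameters.
#' @param df Degrees-of-freedom override for unregistered pairs.
#' @param mixture Use the 50:50 chi-square/point-mass boundary mixture
#'   sometimes recommended for branch-site tests instead of the plain
#'   (conservative) chi-square.
#' @return An `lrt_result` with `statistic_D`, `df` and `p_value`.
#' @examples
#' m1 <- model_fit("M1", -1000, 2)
#' m2 <- model_fit("M2", -998, 3)
#' lrt(m1, m2)  # D = 4, df = 1, p ~ 0.0455
#' @export
lrt <- function(null, alt, df = NULL, mixture = FALSE) {
  stopifnot(inherits(null, "model_fit"), inherits(alt, "model_fit"))
  if (alt$n_params <= null$n_params)
    stop("alternative model must have more parameters than the null")
  pairs <- default_model_pairs()
  registered <- any(pairs$null == null$model_id & pairs$alt == alt$model_id)
  if (!registered && is.null(df))
    stop(sprintf("pair %s vs %s is not in the registered nested-pair table; %s",
                 null$model_id, alt$model_id, "pass an explicit df override"))
  if (is.null(df)) df <- alt$n_params - null$n_params
  d <- 2 * (alt$lnL - null$lnL)
  if (d < 0) {
    warning(sprintf("lnL(alt) < lnL(null) (D = %.4g); clamping D to 0", d))
    d <- 0
  }
  p <- if (mixture) {
    0.5 * stats::pchisq(d, df, lower.tail = FALSE) + 0.5 * (d <= 0)
  } else {
    stats::pchisq(d, df, lower.tail = FALSE)
  }
  structure(list(null_model = null$model_id, alt_model = alt$model_id,
                 statistic_D = d, df = as.integer(df), p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: D = %.4f, df = %d, p = %.4g\n",
              x$null_model, x$alt_model, x$statistic_D, x$df, x$p_value))
  invisible(x)
}

#' Compare a set of model fits with likelihood ratio tests
#'
#' Runs [lrt()] over every requested (or registered) nested pair present in
#' `fits`. Within each pair the alternative is flagged best-fitting when
#' its raw p-value is below `alpha`; Bonferroni-adjusted p-values are
#' reported alongside (adjusted = min(1, p * number of pairs)).
#'
#' @param fits List of `model_fit` objects (at least 2).
#' @param pairs Optional data frame with columns `null`, `alt` naming
#'   model ids in `fits`; defaults to the registered pairs both of whose
#'   members are present.
#' @param alpha Significance level for the best-fit flag.
#' @return Data frame with columns `null`, `alt`, `D`, `df`, `p_raw`,
#'   `p_bonferroni`, `best_fit`.
#' @export
compare_models <- function(fits, pairs = NULL, alpha = 0.05) {
  if (length(fits) < 2L) stop("need at least two model fits")
  ids <- vapply(fits, `[[`, "", "model_id")
  names(fits) <- ids
  if (is.null(pairs)) {
    pairs <- default_model_pairs()
    pairs <- pairs[pairs$null %in% ids & pairs$alt %in% ids, , drop = FALSE]
    if (nrow(pairs) == 0L) stop("no registered nested pair among the given fits")
  } else {
    absent <- setdiff(c(pairs$null, pairs$alt), ids)
    if (length(absent))
      stop("pairs reference fits that are absent: ", paste(absent, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- lrt(fits[[pairs$null[i]]], fits[[pairs$alt[i]]])
    data.frame(null = r$null_model, alt = r$alt_model, D = r$statistic_D,
               df = r$df, p_raw = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out$best_fit <- out$p_raw < alpha
  out
}

#' Classify a branch dN/dS estimate into a selective-pressure class
#'
#' The scheme used to color branches in selective-pressure plots:
#' omega below 0.2 is `purifying`, between 0.2 and 1 (inclusive on both
#' ends) `relaxed`, above 1 `positive`, and an infinite estimate
#' (zero synonymous substitutions) `saturated`.
#'
#' @param omega Numeric vector of non-negative dN/dS values (`Inf` allowed).
#' @return Factor with levels purifying < relaxed < positive < saturated.
#' @export
classify_branch_omega <- function(omega) {
  if (any(omega < 0, na.rm = TRUE)) stop("omega must be non-negative")
  out <- ifelse(is.infinite(omega), "saturated",
         ifelse(omega > 1, "positive",
         ifelse(omega >= 0.2, "relaxed", "purifying")))
  factor(out, levels = c("purifying", "relaxed", "positive", "saturated"),
         ordered = TRUE)
}

#' Classify a per-site p-value into a significance class
#'
#' `strong` below 0.01, `moderate` below 0.05, `ns` otherwise — the
#' significance bands used when highlighting positively selected sites.
#'
#' @param p_value Numeric vector in `[0, 1]`.
#' @return Factor with levels ns < moderate < strong.
#' @export
classify_site_significance <- function(p_value) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- ifelse(p_value < 0.01, "strong",
         ifelse(p_value < 0.05, "moderate", "ns"))
  factor(out, levels = c("ns", "moderate", "strong"), ordered = TRUE)
}

# ---- model-fit TSV interchange ---------------------------------------------

#' Read / write the model-fit TSV interchange format
#'
#' A neutral three-section tab-separated format decoupling this package
#' from any particular ML engine's raw output:
#' a versioned header (`model_id`, `lnL`, `n_params` key-value lines), an
#' optional `#branches` block (`branch`, `omega`; the token `inf` encodes
#' an infinite omega), and an optional `#sites` block (`site`, `omega`,
#' `p_value`, optional class-probability columns `p0`, `p1`, ...). Reading
#' a written file reproduces the `model_fit` exactly.
#'
#' @param path File path.
#' @return `read_model_tsv` returns a `model_fit`; `write_model_tsv`
#'   returns `path` invisibly.
#' @export
read_model_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "#model_fit"))
    stop("line 1: missing '#model_fit' header")
  sec_b <- which(lines == "#branches")
  sec_s <- which(lines == "#sites")
  hdr_end <- min(c(sec_b, sec_s, length(lines) + 1L)) - 1L
  hdr <- if (hdr_end >= 2L) strsplit(lines[2:hdr_end], "\t", fixed = TRUE) else list()
  keys <- vapply(hdr, `[[`, "", 1L)
  vals <- vapply(hdr, function(p) if (length(p) > 1L) p[2L] else "", "")
  need <- c("model_id", "lnL", "n_params")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("header block: missing keys ", paste(miss, collapse = ", "))
  h <- stats::setNames(vals, keys)

  branch_omegas <- numeric()
  if (length(sec_b)) {
    end <- if (length(sec_s)) sec_s - 1L else length(lines)
    body <- lines[(sec_b + 2L):end] # skip the column-header line
    body <- body[nzchar(body)]
    if (length(body)) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      ids <- vapply(parts, `[[`, "", 1L)
      om <- vapply(parts, function(p) {
        if (identical(tolower(p[2L]), "inf")) Inf else as.numeric(p[2L])
      }, 0)
      branch_omegas <- stats::setNames(om, ids)
    }
  }

  site_records <- NULL
  if (length(sec_s)) {
    cols <- strsplit(lines[sec_s + 1L], "\t", fixed = TRUE)[[1L]]
    body <- lines[seq.int(sec_s + 2L, length.out = max(0L, length(lines) - sec_s - 1L))]
    body <- body[nzchar(body)]
    if (length(body)) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[seq_along(cols)])))
      site_records <- as.data.frame(m)
      names(site_records) <- cols
      site_records$site <- as.integer(site_records$site)
      for (i in seq_along(body)) {
        if (i > 1L && site_records$site[i] <= site_records$site[i - 1L])
          stop(sprintf("line %d: site indices must be strictly increasing",
                       sec_s + 1L + i))
      }
    }
  }
  model_fit(h[["model_id"]], as.numeric(h[["lnL"]]), as.integer(h[["n_params"]]),
            branch_omegas, site_records)
}

#' @rdname read_model_tsv
#' @param fit A `model_fit`.
#' @export
write_model_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#model_fit\t1",
               paste0("model_id\t", fit$model_id),
               paste0("lnL\t", fmt_num(fit$lnL)),
               paste0("n_params\t", fit$n_params)), con)
  if (length(fit$branch_omegas)) {
    writeLines("#branches", con)
    writeLines("branch\tomega", con)
    om <- vapply(unname(fit$branch_omegas),
                 function(x) if (is.infinite(x)) "inf" else fmt_num(x), "")
    writeLines(paste(names(fit$branch_omegas), om, sep = "\t"), con)
  }
  if (!is.null(fit$site_records) && nrow(fit$site_records)) {
    sr <- fit$site_records
    writeLines("#sites", con)
    writeLines(paste(names(sr), collapse = "\t"), con)
    rows <- apply(sr, 1L, function(r) paste(vapply(as.numeric(r), fmt_num, ""),
                                            collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}
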