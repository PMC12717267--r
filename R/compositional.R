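#' Weekly genus read-count matrix
#'
#' The root object of the pipeline: a genera-by-weeks matrix of nonnegative
#' integer read counts plus per-week metadata (ISO week id, mean read length,
#' filter type, human-read fraction, total reads) and optional per-genus
#' taxonomy.
#'
#' @param counts Nonnegative numeric matrix, genera in rows, weeks in columns.
#'   Dimnames are used as genus and week identifiers (generated if absent).
#' @param meta Optional data frame with one row per week. Recognised columns:
#'   `week_id`, `year`, `week` (calendar week), `read_length` (mean bp),
#'   `filter_type`, `human_fraction`, `total_reads`.
#' @param taxonomy Optional data frame with one row per genus (column `genus`
#'   plus any ranks, e.g. `kingdom`).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, meta = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("w%04d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("genus ids must be unique")
  if (is.null(meta)) {
    meta <- data.frame(week_id = colnames(counts))
  }
  if (nrow(meta) != ncol(counts)) {
    stop("metadata rows must match week columns")
  }
  if (is.null(meta$total_reads)) meta$total_reads <- colSums(counts)
  structure(
    list(counts = counts, meta = meta, taxonomy = taxonomy),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genera x %d weeks, %.3g total reads\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Weekly relative abundances
#'
#' Divides each week's counts by its total: the number of reads assigned to a
#' genus over the total reads that week. Zeros are preserved.
#'
#' @param counts A [count_matrix()].
#' @return Numeric matrix (genera x weeks) whose columns sum to 1, with the
#'   week metadata attached as attribute `meta`.
#' @export
relative_abundance <- function(counts) {
  x <- counts$counts
  tot <- colSums(x)
  if (any(tot == 0)) {
    stop(
      "weeks with zero total reads: ",
      paste(colnames(x)[tot == 0], collapse = ", ")
    )
  }
  out <- sweep(x, 2, tot, "/")
  attr(out, "meta") <- counts$meta
  out
}

#' Prevalence filter
#'
#' Removes genera with zero read counts in at least `max_zero_fraction` of the
#' weeks; a genus is retained only if its zero-week fraction is strictly below
#' the threshold.
#'
#' @param counts A [count_matrix()].
#' @param max_zero_fraction Removal threshold on the zero-week fraction
#'   (default 2/3).
#' @return A filtered `count_matrix`, genus order preserved.
#' @export
prevalence_filter <- function(counts, max_zero_fraction = 2 / 3) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction <= 1)
  zf <- rowMeans(counts$counts == 0)
  keep <- zf < max_zero_fraction
  if (!any(keep)) stop("prevalence filter removed every genus")
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  if (!is.null(counts$taxonomy)) {
    out$taxonomy <- counts$taxonomy[keep, , drop = FALSE]
  }
  out
}

composition_matrix <- function(mat, meta = NULL, imputation = NULL) {
  structure(mat,
    meta = meta, imputation = imputation,
    class = c("composition_matrix", "matrix")
  )
}

#' @export
print.composition_matrix <- function(x, ...) {
  imp <- attr(x, "imputation")
  cat(sprintf(
    "composition_matrix: %d genera x %d weeks (%d cells imputed)\n",
    nrow(x), ncol(x), if (is.null(imp)) 0L else nrow(imp)
  ))
  invisible(x)
}

#' Geometric Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts with posterior-mean Dirichlet estimates under a
#' geometric (data-driven) prior and re-closes each week multiplicatively, so
#' that ratios between the nonzero parts are preserved. Zero cells in week
#' \eqn{w} with total \eqn{n_w} are replaced by \eqn{t_j s / (n_w + s)} where
#' \eqn{t_j} is the normalized geometric mean of genus \eqn{j}'s nonzero
#' proportions across weeks and \eqn{s = D \cdot} `prior_mass` is the total
#' prior strength for the \eqn{D} genera.
#'
#' @param counts A (typically prevalence-filtered) [count_matrix()].
#' @param prior_mass Prior mass per cell; default 0.5.
#' @return A strictly positive `composition_matrix` (genera x weeks, columns
#'   sum to 1) with an `imputation` attribute recording the replaced cells.
#' @export
impute_zeros <- function(counts, prior_mass = 0.5) {
  x <- counts$counts
  props <- relative_abundance(counts)
  d <- nrow(x)
  s <- prior_mass * d

  # geometric prior: per-genus geometric mean of nonzero proportions
  tj <- apply(props, 1, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(NA_real_)
    gmean(p)
  })
  if (anyNA(tj)) stop("genus with no nonzero week; prevalence-filter first")
  tj <- tj / sum(tj)

  out <- props
  imput <- list()
  totals <- colSums(x)
  for (w in seq_len(ncol(x))) {
    z <- x[, w] == 0
    if (!any(z)) next
    repl <- tj[z] * s / (totals[w] + s)
    out[z, w] <- repl
    out[!z, w] <- props[!z, w] * (1 - sum(repl))
    imput[[length(imput) + 1L]] <- data.frame(
      genus = rownames(x)[z], week = colnames(x)[w], value = repl,
      row.names = NULL
    )
  }
  imputation <- if (length(imput)) do.call(rbind, imput) else NULL
  composition_matrix(out, meta = counts$meta, imputation = imputation)
}

# sequential-binary-partition balance matrix for pivot coordinates:
# order[1] vs the rest, then order[2] vs the remainder, ...
pivot_balance_matrix <- function(d, ord) {
  v <- matrix(0, d, d - 1)
  for (i in seq_len(d - 1)) {
    r <- d - i
    v[ord[i], i] <- sqrt(r / (r + 1))
    v[ord[(i + 1):d], i] <- -sqrt(r / (r + 1)) / r
  }
  v
}

#' Log-ratio transforms of compositions
#'
#' Maps strictly positive weekly compositions to unconstrained coordinates:
#' centred (CLR), isometric (ILR) or pivot (PLR) log-ratios. The ILR basis is
#' a sequential binary partition; by default parts are pivot-ordered by
#' descending mean abundance. PLR is the ILR whose first pivot is a chosen
#' genus, so its first coordinate is
#' \eqn{\sqrt{(D-1)/D}\,\ln(x_{pivot}/g(\mathrm{others}))}.
#'
#' @param comp A strictly positive `composition_matrix` (genera x weeks).
#' @param kind One of `"clr"`, `"ilr"`, `"plr"`.
#' @param pivot Pivot genus name or index (PLR only; default the genus with
#'   the highest mean abundance).
#' @param order Optional explicit part ordering for the ILR/PLR partition.
#' @return A `logratio_matrix`: coordinates (weeks x D for CLR, weeks x D-1
#'   otherwise), the transform kind, the balance matrix basis and part names.
#' @export
logratio_transform <- function(comp, kind = c("clr", "ilr", "plr"),
                               pivot = NULL, order = NULL) {
  kind <- match.arg(kind)
  m <- unclass(comp)
  if (any(m <= 0)) stop("compositions must be strictly positive")
  d <- nrow(m)
  lx <- t(log(m)) # weeks x genera
  clr <- lx - rowMeans(lx)

  if (kind == "clr") {
    coords <- clr
    colnames(coords) <- rownames(m)
    basis <- NULL
    ord <- seq_len(d)
  } else {
    ord <- if (!is.null(order)) {
      if (is.character(order)) match(order, rownames(m)) else as.integer(order)
    } else {
      order(rowMeans(m), decreasing = TRUE)
    }
    if (kind == "plr") {
      if (is.null(pivot)) pivot <- ord[1]
      if (is.character(pivot)) pivot <- match(pivot, rownames(m))
      if (is.na(pivot)) stop("pivot genus not found")
      ord <- c(pivot, setdiff(ord, pivot))
    }
    basis <- pivot_balance_matrix(d, ord)
    rownames(basis) <- rownames(m)
    coords <- clr %*% basis
    colnames(coords) <- sprintf("z%02d", seq_len(d - 1))
  }
  rownames(coords) <- colnames(m)

  structure(
    list(
      coords = coords, kind = kind, basis = basis,
      parts = rownames(m), order = ord, meta = attr(comp, "meta")
    ),
    class = "logratio_matrix"
  )
}

#' @export
print.logratio_matrix <- function(x, ...) {
  cat(sprintf(
    "logratio_matrix (%s): %d weeks x %d coordinates\n",
    toupper(x$kind), nrow(x$coords), ncol(x$coords)
  ))
  invisible(x)
}

#' Invert a log-ratio transform
#'
#' Maps log-ratio coordinates back to closed compositions using the stored
#' basis; the round trip with [logratio_transform()] is exact to numerical
#' precision.
#'
#' @param lr A `logratio_matrix`.
#' @param coords Optional replacement coordinate matrix (same shape as
#'   `lr$coords`), e.g. detrended residuals.
#' @return A `composition_matrix` (genera x weeks, columns sum to 1).
#' @export
inverse_logratio <- function(lr, coords = NULL) {
  if (!inherits(lr, "logratio_matrix")) stop("unknown log-ratio object")
  z <- coords %||% lr$coords
  clr <- switch(lr$kind,
    clr = z,
    ilr = ,
    plr = z %*% t(lr$basis),
    stop("unknown transform kind: ", lr$kind)
  )
  ex <- exp(clr - apply(clr, 1, max))
  comp <- t(ex / rowSums(ex))
  rownames(comp) <- lr$parts
  colnames(comp) <- rownames(z)
  composition_matrix(comp, meta = lr$meta)
}

#' Compositional variation matrix
#'
#' Pairwise variances of log-ratios, \eqn{T_{ij} = var(\ln(x_i/x_j))} over
#' weeks (unbiased, n-1 denominator): the compositional analogue of a
#' dissimilarity matrix, invariant to re-closure.
#'
#' @param comp A strictly positive `composition_matrix`.
#' @return Symmetric genera x genera matrix with zero diagonal.
#' @export
variation_matrix <- function(comp) {
  m <- unclass(comp)
  if (ncol(m) < 3) stop("need at least 3 weeks")
  lx <- log(m) # genera x weeks
  cv <- cov(t(lx))
  v <- diag(cv)
  out <- outer(v, v, "+") - 2 * cv
  out[out < 0] <- 0
  diag(out) <- 0
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Write / read a count matrix as TSV
#'
#' Counts are written genera-in-rows with week columns; metadata goes to a
#' companion TSV with one row per week.
#'
#' @param x A [count_matrix()].
#' @param counts_path,meta_path Output TSV paths.
#' @return `write_count_matrix` returns the paths invisibly;
#'   `read_count_matrix` returns a `count_matrix`.
#' @export
write_count_matrix <- function(x, counts_path, meta_path = NULL) {
  df <- data.frame(genus = rownames(x$counts), x$counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(counts_path, meta_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, meta_path = NULL) {
  df <- read.table(counts_path, sep = "\t", header = TRUE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genus
  meta <- if (!is.null(meta_path)) {
    read.table(meta_path, sep = "\t", header = TRUE, check.names = FALSE)
  }
  count_matrix(m, meta = meta)
}
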