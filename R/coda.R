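#' Closure: normalise a positive vector to unit sum
#'
#' The canonical representation of compositional data: each part divided by
#' the total. Scale-invariant and idempotent.
#'
#' @param v non-negative numeric vector (or matrix, closed row-wise) with at
#'   least one positive entry per vector/row.
#' @return vector or matrix of the same shape summing to 1 (per row).
#' @export
#' @examples
#' closure(c(2, 2, 4))
closure <- function(v) {
  if (is.matrix(v)) {
    s <- rowSums(v)
    if (any(!is.finite(s)) || any(s <= 0) || any(v < 0)) {
      stop("each row must be non-negative with a positive sum")
    }
    return(v / s)
  }
  s <- sum(v)
  if (any(v < 0) || !is.finite(s) || s <= 0) {
    stop("input must be non-negative with a positive sum")
  }
  v / s
}

#' Geometric-mean composition of a set of spectra
#'
#' Componentwise geometric mean followed by closure — the centre of a set of
#' compositions under the Aitchison geometry (perturbation-additive, unlike
#' the arithmetic mean which is biased on the simplex).
#'
#' @param spectra matrix with one composition per row (strictly positive), or
#'   a list of equal-length positive vectors.
#' @return a single composition (unit-sum vector).
#' @export
#' @examples
#' geometric_mean_spectrum(rbind(c(0.8, 0.2), c(0.2, 0.8)))  # (0.5, 0.5)
geometric_mean_spectrum <- function(spectra) {
  if (is.list(spectra) && !is.data.frame(spectra)) {
    spectra <- do.call(rbind, spectra)
  }
  spectra <- as.matrix(spectra)
  if (!nrow(spectra)) stop("empty collection of spectra")
  if (any(spectra <= 0)) stop("spectra must be strictly positive")
  closure(exp(colMeans(log(spectra))))
}

#' Aggregate a count table into one spectrum per gene and target site
#'
#' Per-row counts are closed into sgRNA/replicate frequencies, then averaged
#' geometrically over the sgRNAs of each (gene, replicate, target site), then
#' geometrically over replicates of each (gene, target site), with closure
#' after every step. Because the geometric mean commutes with closure, raw
#' positive counts and pre-closed frequencies give the same result.
#'
#' @param table imputed count table: all seven category values strictly
#'   positive (see [impute_zeros()]).
#' @return data frame with columns `gene`, `target_site`, `n_guides` (distinct
#'   sgRNAs aggregated, summed over replicates), `n_replicates`, and the seven
#'   analysis-category frequency columns; one row per (gene, target site).
#' @export
aggregate_gene_spectra <- function(table) {
  validate_count_table(table)
  cnt <- count_matrix(table)
  if (any(cnt <= 0)) {
    stop("counts must be strictly positive; run impute_zeros() first")
  }
  if (!nrow(table)) {
    out <- data.frame(gene = character(0), target_site = character(0),
                      n_guides = integer(0), n_replicates = integer(0))
    out[analysis_categories()] <- numeric(0)
    return(out)
  }
  freq <- closure(cnt)
  log_freq <- log(freq)

  # sgRNA level -> (gene, replicate, target); gmean == exp(mean(log)).
  # rowsum() and table() both order groups by sort(unique(key)).
  grt <- paste(table$gene, table$replicate, table$target_site, sep = "\r")
  rep_log <- rowsum(log_freq, grt) / as.vector(table(grt))
  rep_freq <- closure(exp(rep_log))
  rep_key <- do.call(rbind, strsplit(rownames(rep_freq), "\r", fixed = TRUE))

  # replicate level -> (gene, target)
  gt <- paste(rep_key[, 1], rep_key[, 3], sep = "\r")
  gene_log <- rowsum(log(rep_freq), gt) / as.vector(table(gt))
  gene_freq <- closure(exp(gene_log))
  gene_key <- do.call(rbind, strsplit(rownames(gene_freq), "\r", fixed = TRUE))

  row_gt <- paste(table$gene, table$target_site, sep = "\r")
  guides <- vapply(split(table$sgrna_id, row_gt),
                   function(x) length(unique(x)), integer(1))
  reps <- vapply(split(rep_key[, 2], gt), function(x) length(unique(x)),
                 integer(1))
  ord_key <- rownames(gene_freq)
  out <- data.frame(gene = gene_key[, 1], target_site = gene_key[, 2],
                    n_guides = as.integer(guides[ord_key]),
                    n_replicates = as.integer(reps[ord_key]),
                    stringsAsFactors = FALSE)
  out[analysis_categories()] <- unname(gene_freq)
  out <- out[order(out$gene, out$target_site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Centered log-ratio transform and inverse
#'
#' `clr(x)_j = ln(x_j / g(x))` with `g` the geometric mean; coordinates sum
#' to zero. `clr_inv` maps back to the simplex via closure of the
#' exponential.
#'
#' @param x strictly positive composition (vector) or matrix of compositions
#'   (rows).
#' @return numeric vector/matrix of CLR coordinates (`clr`), or composition(s)
#'   (`clr_inv`).
#' @export
#' @examples
#' clr(c(0.25, 0.25, 0.5))
#' clr_inv(clr(c(0.25, 0.25, 0.5)))
clr <- function(x) {
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("compositions must be strictly positive")
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  if (any(x <= 0)) stop("compositions must be strictly positive")
  log(x) - mean(log(x))
}

#' @rdname clr
#' @param z CLR coordinates (vector or matrix of rows).
#' @export
clr_inv <- function(z) {
  if (is.matrix(z)) closure(exp(z)) else closure(exp(z))
}

#' Orthonormal ILR basis (Gram-Schmidt sequential binary partition)
#'
#' Contrast matrix `V` of dimension (D-1) x D whose rows are orthonormal in
#' CLR space: row i has weight `sqrt(i/(i+1))/i` on parts 1..i and
#' `-sqrt(i/(i+1))` on part i+1. With this basis
#' `ilr(x)_i = sqrt(i/(i+1)) * ln(g(x_1..x_i) / x_{i+1})`.
#'
#' @param d number of parts D.
#' @return (D-1) x D matrix.
#' @export
ilr_basis <- function(d) {
  if (d < 2) stop("need at least 2 parts")
  V <- matrix(0, d - 1, d)
  for (i in seq_len(d - 1)) {
    w <- sqrt(i / (i + 1))
    V[i, seq_len(i)] <- w / i
    V[i, i + 1] <- -w
  }
  V
}

check_ilr_basis <- function(basis, d) {
  if (!is.matrix(basis) || nrow(basis) != d - 1 || ncol(basis) != d) {
    stop("basis must be a (D-1) x D matrix")
  }
  if (max(abs(basis %*% t(basis) - diag(d - 1))) > 1e-8) {
    stop("basis rows must be orthonormal")
  }
  if (max(abs(rowSums(basis))) > 1e-8) {
    stop("basis rows must sum to zero (live in CLR space)")
  }
  invisible(basis)
}

#' Isometric log-ratio transform and inverse
#'
#' Maps a D-part composition to D-1 unconstrained Euclidean coordinates,
#' `ilr(x) = V clr(x)` for an orthonormal contrast matrix `V`. An isometry:
#' Euclidean distance between ILR vectors equals the Aitchison distance
#' between the compositions, for any orthonormal basis — which is what makes
#' downstream Mahalanobis scores basis-invariant.
#'
#' @param x strictly positive composition (vector) or matrix of compositions
#'   (rows).
#' @param basis orthonormal (D-1) x D contrast matrix; default [ilr_basis()].
#' @return ILR coordinates: length D-1 vector, or n x (D-1) matrix.
#' @export
#' @examples
#' ilr(c(0.8, 0.2))  # sqrt(1/2) * log(4)
ilr <- function(x, basis = NULL) {
  d <- if (is.matrix(x)) ncol(x) else length(x)
  if (is.null(basis)) basis <- ilr_basis(d)
  check_ilr_basis(basis, d)
  z <- clr(x)
  if (is.matrix(z)) z %*% t(basis) else as.vector(basis %*% z)
}

#' @rdname ilr
#' @param z ILR coordinates (length D-1 vector or n x (D-1) matrix).
#' @param d number of parts of the output composition.
#' @export
ilr_inv <- function(z, basis = NULL, d = NULL) {
  k <- if (is.matrix(z)) ncol(z) else length(z)
  if (is.null(d)) d <- k + 1
  if (is.null(basis)) basis <- ilr_basis(d)
  check_ilr_basis(basis, d)
  if (is.matrix(z)) clr_inv(z %*% basis) else clr_inv(as.vector(t(basis) %*% z))
}
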