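#' Robust outlier distances for the genes of one target site
#'
#' ILR-transforms the gene spectra of a single target site, fits a robust
#' (MCD) or classical centre and covariance in ILR space, and returns the
#' Mahalanobis distance of every gene to that centre. Under the working
#' assumption that most genes barely affect repair outcomes, the centre
#' approximates the wild-type spectrum and large distances flag genes whose
#' perturbation redistributes repair outcomes.
#'
#' @param spectra data frame of gene-by-target spectra as returned by
#'   [aggregate_gene_spectra()], restricted to one target site (one row per
#'   gene).
#' @param seed integer seed for the MCD subset search.
#' @param method `"mcd"` (default) or `"classical"`.
#' @param basis optional orthonormal ILR contrast matrix; default
#'   [ilr_basis()]. Distances are invariant to this choice.
#' @param support_fraction passed to [fit_center_scatter()].
#' @return data frame with columns `gene`, `target_site`, `distance`, plus the
#'   fit as attribute `fit`.
#' @export
score_target <- function(spectra, seed, method = c("mcd", "classical"),
                         basis = NULL, support_fraction = NULL) {
  method <- match.arg(method)
  if (length(unique(spectra$target_site)) != 1) {
    stop("score_target() expects spectra of exactly one target site")
  }
  if (anyDuplicated(spectra$gene)) stop("one spectrum per gene expected")
  comp <- as.matrix(spectra[analysis_categories()])
  Z <- ilr(comp, basis = basis)
  fit <- fit_center_scatter(Z, method = method,
                            support_fraction = support_fraction, seed = seed)
  out <- data.frame(gene = spectra$gene,
                    target_site = spectra$target_site,
                    distance = mahalanobis_distance(Z, fit),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Unify per-target distances into one gene score table
#'
#' Target sites differ in cut-site sequence context and coverage, so raw
#' distances are not comparable across them. Unification: (i) genes with a
#' spectrum in every target site form the reference set; (ii) each target's
#' distances are z-normalised by the mean and standard deviation (n-1
#' denominator) of the reference genes in that target; (iii) each gene's
#' unified score is the mean of its available z-scores, missing targets
#' ignored. Genes are ranked by decreasing unified score (rank 1 = strongest
#' outlier), ties broken by gene id.
#'
#' @param distances data frame with columns `gene`, `target_site`, `distance`
#'   — typically `rbind` of [score_target()] outputs.
#' @return a gene score table: data frame with one row per gene, per-target
#'   `distance_<target>` and `z_<target>` columns, `unified_score`, `rank`,
#'   `is_reference`.
#' @export
unify_scores <- function(distances) {
  req <- c("gene", "target_site", "distance")
  if (!all(req %in% names(distances))) {
    stop("distances needs columns gene, target_site, distance")
  }
  targets <- sort(unique(distances$target_site))
  genes <- sort(unique(distances$gene))
  D <- matrix(NA_real_, length(genes), length(targets),
              dimnames = list(genes, targets))
  D[cbind(match(distances$gene, genes),
          match(distances$target_site, targets))] <- distances$distance

  is_ref <- rowSums(!is.na(D)) == length(targets)
  if (sum(is_ref) < 2) {
    stop("need at least 2 reference genes present in all target sites")
  }
  Z <- D
  for (j in seq_along(targets)) {
    ref <- D[is_ref, j]
    Z[, j] <- (D[, j] - mean(ref)) / stats::sd(ref)
  }
  unified <- rowMeans(Z, na.rm = TRUE)

  ord <- order(-unified, genes)
  rank <- integer(length(genes))
  rank[ord] <- seq_along(genes)

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (j in seq_along(targets)) out[[paste0("distance_", targets[j])]] <- D[, j]
  for (j in seq_along(targets)) out[[paste0("z_", targets[j])]] <- Z[, j]
  out$unified_score <- unified
  out$rank <- rank
  out$is_reference <- unname(is_ref)
  rownames(out) <- NULL
  out
}

#' Score a whole screen across target sites
#'
#' Convenience wrapper: runs [score_target()] for every target site present
#' in `spectra` (with a per-target seed derived from `seed`) and unifies the
#' distances with [unify_scores()].
#'
#' @inheritParams score_target
#' @param spectra gene-by-target spectra for any number of target sites.
#' @return gene score table (see [unify_scores()]) with the per-target fits as
#'   attribute `fits`.
#' @export
#' @examples
#' sim <- simulate_screen(simulation_config(n_genes = 60, n_outliers = 3,
#'                                          n_targets = 2, seed = 3))
#' sp <- aggregate_gene_spectra(impute_zeros(sim$counts, seed = 3))
#' head(score_screen(sp, seed = 3))
score_screen <- function(spectra, seed, method = c("mcd", "classical"),
                         basis = NULL, support_fraction = NULL) {
  method <- match.arg(method)
  targets <- sort(unique(spectra$target_site))
  per_target <- vector("list", length(targets))
  fits <- list()
  for (j in seq_along(targets)) {
    sub <- spectra[spectra$target_site == targets[j], , drop = FALSE]
    st <- score_target(sub, seed = seed + j - 1, method = method,
                       basis = basis, support_fraction = support_fraction)
    fits[[targets[j]]] <- attr(st, "fit")
    per_target[[j]] <- st
  }
  out <- unify_scores(do.call(rbind, per_target))
  attr(out, "fits") <- fits
  out
}

#' Select pseudo-control genes
#'
#' Pseudo-controls are the genes whose spectra sit closest to the estimated
#' centre of the spectra distribution; they stand in for absent nontargeting
#' controls in downstream comparative analyses. Two modes:
#'
#' * `"unified"`: the `n` genes with the lowest unified score;
#' * `"per_target_common"`: the intersection of the per-target bottom-`n`
#'   distance sets (genes among the `n` least-distant in *every* target);
#'   this may return fewer than `n` genes.
#'
#' Boundary ties are broken by lexicographic gene id.
#'
#' @param scores gene score table from [unify_scores()] / [score_screen()].
#' @param n number of pseudo-controls; default 60.
#' @param mode `"unified"` (default) or `"per_target_common"`.
#' @return the score table with a logical `is_pseudo_control` column set.
#' @export
select_pseudo_controls <- function(scores, n = 60,
                                   mode = c("unified", "per_target_common")) {
  mode <- match.arg(mode)
  if (n > nrow(scores)) {
    stop("n = ", n, " exceeds the number of scored genes (", nrow(scores), ")")
  }
  if (mode == "unified") {
    ord <- order(scores$unified_score, scores$gene)
    chosen <- scores$gene[ord[seq_len(n)]]
  } else {
    dist_cols <- grep("^distance_", names(scores), value = TRUE)
    sets <- lapply(dist_cols, function(cl) {
      ok <- !is.na(scores[[cl]])
      ord <- order(scores[[cl]][ok], scores$gene[ok])
      scores$gene[ok][ord[seq_len(min(n, sum(ok)))]]
    })
    chosen <- Reduce(intersect, sets)
  }
  scores$is_pseudo_control <- scores$gene %in% chosen
  scores
}

#' Principal-component diagnostic of centre estimation
#'
#' Reproduces the four-scenario diagnostic of how the compositional transform
#' and the robust covariance shape the estimated centre: PCA on raw
#' frequencies or ILR coordinates, with a classical or MCD covariance. The
#' components are the eigenvectors of the chosen scatter; scores are the
#' centred data projected on the top two. For ILR input, loadings and centre
#' are mapped back to CLR space through the basis so each component can be
#' read against the mutation categories, and the centre is also returned as a
#' composition.
#'
#' @param spectra gene-by-target spectra for one target site.
#' @param transform `"ilr"` (default) or `"raw"`.
#' @param covariance `"mcd"` (default) or `"classical"`.
#' @param seed seed for the MCD search (ignored for classical).
#' @param basis optional ILR contrast matrix.
#' @return list with `scores` (n x 2 matrix, rownames = genes), `loadings`
#'   (fitting-space eigenvectors), `eigenvalues`, `center` (fitting space),
#'   and for ILR input `clr_loadings`, `clr_center` and `center_composition`.
#' @export
pca_diagnostic <- function(spectra, transform = c("ilr", "raw"),
                           covariance = c("mcd", "classical"), seed = NULL,
                           basis = NULL) {
  transform <- match.arg(transform)
  covariance <- match.arg(covariance)
  comp <- as.matrix(spectra[analysis_categories()])
  d <- ncol(comp)
  if (is.null(basis)) basis <- ilr_basis(d)
  if (transform == "ilr") {
    X <- ilr(comp, basis = basis)
    fit <- fit_center_scatter(X, method = covariance, seed = seed)
    center <- fit$location
    scatter <- fit$scatter
  } else {
    # closed spectra live on the unit-sum hyperplane, so their raw
    # covariance is singular; fit in an orthonormal parametrization of that
    # hyperplane (the contrast matrix rows span it) and map back linearly
    X <- comp
    fit <- fit_center_scatter(comp %*% t(basis), method = covariance,
                              seed = seed)
    center <- as.vector(t(basis) %*% fit$location) + 1 / d
    scatter <- t(basis) %*% fit$scatter %*% basis
  }
  eg <- eigen(scatter, symmetric = TRUE)
  scores <- sweep(X, 2, center) %*% eg$vectors[, 1:2, drop = FALSE]
  rownames(scores) <- spectra$gene
  out <- list(scores = scores, loadings = eg$vectors,
              eigenvalues = eg$values, center = center,
              transform = transform, covariance = covariance, fit = fit)
  if (transform == "ilr") {
    out$clr_loadings <- t(basis) %*% eg$vectors
    out$clr_center <- as.vector(t(basis) %*% fit$location)
    out$center_composition <- stats::setNames(clr_inv(out$clr_center),
                                              analysis_categories())
  }
  out
}
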