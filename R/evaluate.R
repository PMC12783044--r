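#' Jensen-Shannon distance between two spectra
#'
#' Square root of the Jensen-Shannon divergence
#' `JS(p, q) = KL(p || m)/2 + KL(q || m)/2`, `m = (p + q)/2`. With base-2
#' logarithms (the default) the distance is a metric bounded in \[0, 1\];
#' `base = exp(1)` switches to nats.
#'
#' @param p,q compositions of equal length (non-negative, unit sum; closed
#'   internally). Zero components contribute zero, by continuity.
#' @param base logarithm base; default 2.
#' @return distance in \[0, 1\] (for base 2).
#' @export
#' @examples
#' jensen_shannon_distance(c(1, 0), c(0, 1))  # 1
jensen_shannon_distance <- function(p, q, base = 2) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("p and q must be non-negative")
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i], base) - log(b[i], base)))
  }
  js <- kl(p, m) / 2 + kl(q, m) / 2
  sqrt(max(js, 0))
}

#' Precision-recall evaluation of a gene ranking
#'
#' Computes precision and recall at every rank of `ranking` against a gold-
#' standard gene set, and the (non-interpolated) average precision
#' `AP = sum over gold hits of precision-at-hit / |gold in universe|`. With
#' heavily imbalanced gene universes, AP against its baseline — the gold-set
#' prevalence, which is the expected AP of a random ranking — is more
#' informative than ROC curves.
#'
#' @param ranking character vector of gene ids, best first, no duplicates.
#' @param gold character vector of gold-standard gene ids; members absent
#'   from `ranking` are dropped with a warning.
#' @return list of class `ranking_evaluation`: `precision`, `recall` (per
#'   rank), `average_precision`, `baseline_ap` (prevalence), `n_gold`,
#'   `n_universe`.
#' @export
#' @examples
#' pr_ap(c("g1", "g2", "g3"), c("g1", "g3"))$average_precision  # 0.8333
pr_ap <- function(ranking, gold) {
  if (anyDuplicated(ranking)) stop("ranking contains duplicate genes")
  if (!length(gold)) stop("empty gold-standard set")
  gold <- unique(gold)
  missing <- setdiff(gold, ranking)
  if (length(missing)) {
    warning(length(missing), " gold gene(s) absent from the ranking; dropped")
    gold <- setdiff(gold, missing)
  }
  if (!length(gold)) stop("no gold-standard genes left in the ranked universe")
  hit <- ranking %in% gold
  tp <- cumsum(hit)
  precision <- tp / seq_along(ranking)
  recall <- tp / length(gold)
  structure(list(precision = precision, recall = recall,
                 average_precision = sum(precision[hit]) / length(gold),
                 baseline_ap = length(gold) / length(ranking),
                 n_gold = length(gold), n_universe = length(ranking)),
            class = "ranking_evaluation")
}

#' @export
print.ranking_evaluation <- function(x, ...) {
  cat(sprintf("<ranking_evaluation> AP = %.4f (baseline %.4f), %d gold / %d genes\n",
              x$average_precision, x$baseline_ap, x$n_gold, x$n_universe))
  invisible(x)
}

#' Average precision of random rankings
#'
#' Monte-Carlo baseline: AP of `n_perm` random permutations of the universe
#' against the gold set. Its mean approximates the prevalence.
#'
#' @param universe character vector of gene ids.
#' @param gold gold-standard gene ids.
#' @param n_perm number of shuffles; default 100.
#' @param seed integer seed.
#' @return numeric vector of `n_perm` AP values.
#' @export
ap_random_baseline <- function(universe, gold, n_perm = 100, seed = 1) {
  with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pr_ap(sample(universe), gold)$average_precision
  }, numeric(1)))
}

#' Per-category frequency differences from the pseudo-control centre
#'
#' For each target site, subtracts the geometric-mean spectrum of the control
#' genes from every gene spectrum, category by category. Rows are genes;
#' columns are (target site, category) pairs; each 7-column target block of a
#' complete row sums to zero (difference of two unit-sum compositions). A
#' gene without a spectrum in some target keeps `NA` in that block.
#'
#' @param spectra gene-by-target spectra ([aggregate_gene_spectra()]).
#' @param controls character vector of control gene ids; each target site
#'   must contain at least one control spectrum.
#' @return numeric matrix genes x (targets * 7), column names
#'   `<target>.<category>`, with attribute `control_center` (matrix of the
#'   per-target control geometric means).
#' @export
difference_matrix <- function(spectra, controls) {
  targets <- sort(unique(spectra$target_site))
  genes <- sort(unique(spectra$gene))
  cats <- analysis_categories()
  out <- matrix(NA_real_, length(genes), length(targets) * length(cats),
                dimnames = list(genes, paste(rep(targets, each = length(cats)),
                                             cats, sep = ".")))
  centers <- matrix(NA_real_, length(targets), length(cats),
                    dimnames = list(targets, cats))
  for (j in seq_along(targets)) {
    sub <- spectra[spectra$target_site == targets[j], , drop = FALSE]
    ctrl <- sub[sub$gene %in% controls, cats, drop = FALSE]
    if (!nrow(ctrl)) stop("no control spectra in target ", targets[j])
    center <- geometric_mean_spectrum(as.matrix(ctrl))
    centers[j, ] <- center
    block <- sweep(as.matrix(sub[cats]), 2, center)
    out[match(sub$gene, genes), (j - 1) * length(cats) + seq_along(cats)] <-
      block
  }
  attr(out, "control_center") <- centers
  out
}

#' Order a difference matrix by hierarchical clustering
#'
#' Clusters both axes with Ward linkage on the correlation dissimilarity
#' `1 - Pearson r`, the pairing that groups profiles by shape rather than
#' magnitude. Missing entries are imputed as 0 (no difference from the
#' control centre) for clustering only; constant rows, whose correlation is
#' undefined, are placed at distance 1 from everything. Leaf order is made
#' deterministic by seriating each merge with the tighter subtree first and
#' ties broken by label.
#'
#' @param mat numeric matrix, e.g. from [difference_matrix()].
#' @return list with `row_order` and `col_order` (integer permutations),
#'   `row_tree` and `col_tree` (`hclust` objects).
#' @export
cluster_order <- function(mat) {
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need at least a 2 x 2 matrix")
  mat[is.na(mat)] <- 0
  axis_tree <- function(m) {
    r <- suppressWarnings(stats::cor(t(m)))
    r[is.na(r)] <- 0          # constant profile: distance 1 to everything
    d <- stats::as.dist(1 - r)
    tree <- stats::hclust(d, method = "ward.D2")
    # deterministic leaf order irrespective of input row order
    stats::as.hclust(stats::reorder(stats::as.dendrogram(tree),
                                    seq_len(nrow(m))))
  }
  row_tree <- axis_tree(mat)
  col_tree <- axis_tree(t(mat))
  list(row_order = row_tree$order, col_order = col_tree$order,
       row_tree = row_tree, col_tree = col_tree)
}

#' Hypergeometric over-representation test with BH correction
#'
#' For every annotation term, tests whether the top gene set contains more
#' term members than expected by chance: upper-tail hypergeometric
#' `P(X >= k)` with `k` the overlap, `K` the term's background members, `n`
#' the top-set size and `N` the background size. P-values are Benjamini-
#' Hochberg corrected across the terms of the annotation set; terms with no
#' background members are skipped.
#'
#' @param top character vector of top-ranked gene ids (must be a subset of
#'   `background`).
#' @param background character vector of all gene ids in the screen.
#' @param annotations data frame with columns `term_id`, `gene` (one row per
#'   term-gene pair), optionally `term_name`; or a named list of gene
#'   vectors.
#' @return data frame sorted by `fdr_q`: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `gene_ratio` (k/n), `bg_ratio` (K/N), `p_value`, `fdr_q`,
#'   `genes` (comma-separated overlap).
#' @export
#' @examples
#' ann <- data.frame(term_id = "t1", gene = paste0("g", 1:5))
#' enrich_hypergeometric(paste0("g", c(1:4)), paste0("g", 1:10), ann)
enrich_hypergeometric <- function(top, background, annotations) {
  background <- unique(background)
  top <- unique(top)
  if (!all(top %in% background)) stop("top must be a subset of background")
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- data.frame(
      term_id = rep(names(annotations), lengths(annotations)),
      gene = unlist(annotations, use.names = FALSE))
  }
  if (!all(c("term_id", "gene") %in% names(annotations))) {
    stop("annotations need columns term_id and gene")
  }
  if (is.null(annotations$term_name)) annotations$term_name <- annotations$term_id
  annotations <- annotations[annotations$gene %in% background, , drop = FALSE]

  N <- length(background)
  n <- length(top)
  terms <- split(annotations, annotations$term_id)
  rows <- lapply(terms, function(tm) {
    members <- unique(tm$gene)
    K <- length(members)
    if (!K) return(NULL)
    ov <- intersect(top, members)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm$term_id[1], term_name = tm$term_name[1],
               k = k, K = K, n = n, N = N,
               gene_ratio = k / n, bg_ratio = K / N, p_value = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term has background members")
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr_q, out$p_value, out$term_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[c("term_id", "term_name", "k", "K", "n", "N", "gene_ratio", "bg_ratio",
        "p_value", "fdr_q", "genes")]
}

#' Term-membership regression on mutation frequencies
#'
#' For each (mutation category, target site), fits the ordinary least squares
#' model `frequency ~ group` where `group` indicates membership of the term
#' (cases = term members, controls = supplied control genes). For a binary
#' regressor the coefficient is exactly the case-minus-control mean frequency
#' difference; its p-value tests whether the term's genes shift that outcome.
#' Combinations with fewer than `min_cases` case spectra are excluded.
#' P-values are BH-corrected across all reported rows.
#'
#' @param spectra gene-by-target spectra ([aggregate_gene_spectra()]).
#' @param term_members character vector of case gene ids.
#' @param control_genes character vector of control gene ids (e.g. the 100
#'   lowest-scoring genes outside all enriched terms); must be non-empty and
#'   disjoint from `term_members`.
#' @param min_cases minimum case spectra per (category, target); default 3.
#' @return data frame with one row per (target_site, category):
#'   `coefficient` (case - control mean frequency), `p_value`, `fdr_q`,
#'   `n_case`, `n_control`.
#' @export
group_regression <- function(spectra, term_members, control_genes,
                             min_cases = 3) {
  if (!length(control_genes)) stop("empty control set")
  overlap <- intersect(term_members, control_genes)
  if (length(overlap)) {
    stop("genes in both case and control sets: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  cats <- analysis_categories()
  rows <- list()
  for (t in sort(unique(spectra$target_site))) {
    sub <- spectra[spectra$target_site == t, , drop = FALSE]
    case <- sub[sub$gene %in% term_members, , drop = FALSE]
    ctrl <- sub[sub$gene %in% control_genes, , drop = FALSE]
    if (nrow(case) < min_cases || !nrow(ctrl)) next
    for (o in cats) {
      y <- c(case[[o]], ctrl[[o]])
      g <- rep(c(1, 0), c(nrow(case), nrow(ctrl)))
      fit <- summary(stats::lm(y ~ g))$coefficients
      rows[[length(rows) + 1]] <- data.frame(
        target_site = t, category = o,
        coefficient = fit["g", "Estimate"],
        p_value = fit["g", "Pr(>|t|)"],
        n_case = nrow(case), n_control = nrow(ctrl),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(target_site = character(0), category = character(0),
                      coefficient = numeric(0), p_value = numeric(0),
                      fdr_q = numeric(0), n_case = integer(0),
                      n_control = integer(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[c("target_site", "category", "coefficient", "p_value", "fdr_q",
        "n_case", "n_control")]
}

#' Ranking metrics against planted simulation labels
#'
#' Evaluates how well a score table recovers the simulator's planted outlier
#' genes: recall among the top `k` ranks and the area under the
#' precision-recall curve of the outlier labels (computed as average
#' precision of the score-ordered ranking).
#'
#' @param scores gene score table ([score_screen()]).
#' @param truth simulation truth ([simulate_screen()]`$truth`).
#' @param k cutoff for recall; default = number of planted outliers.
#' @return list with `recall_at_k`, `k`, `auprc`, `n_outliers`, `n_scored`.
#' @export
recovery_report <- function(scores, truth, k = NULL) {
  common <- intersect(scores$gene, truth$gene)
  if (!length(common)) stop("score table and truth share no genes")
  truth <- truth[match(scores$gene, truth$gene), , drop = FALSE]
  outliers <- scores$gene[!is.na(truth$label) & truth$label == "outlier"]
  if (is.null(k)) k <- length(outliers)
  if (!length(outliers)) stop("no planted outliers among the scored genes")
  ranking <- scores$gene[order(scores$rank)]
  top_k <- ranking[seq_len(min(k, length(ranking)))]
  list(recall_at_k = length(intersect(top_k, outliers)) / length(outliers),
       k = k,
       auprc = pr_ap(ranking, outliers)$average_precision,
       n_outliers = length(outliers),
       n_scored = nrow(scores))
}
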