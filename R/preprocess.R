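#' Remove low-coverage sgRNA rows
#'
#' Drops rows whose total read count across the seven analysis categories is
#' strictly below `min_total`. Applied per row, i.e. per sgRNA and replicate:
#' a guide can survive in one replicate and be dropped in the other.
#'
#' @param table count table (see [build_count_table()]).
#' @param min_total minimum total read count; rows with sum `< min_total` are
#'   removed. Default 700, the cutoff used for screens of this type.
#' @return the filtered table, with a `filter_report` attribute (data frame of
#'   removed row keys with the stage and reason).
#' @export
filter_low_coverage <- function(table, min_total = 700) {
  validate_count_table(table)
  totals <- rowSums(count_matrix(table))
  drop <- totals < min_total
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- filter_report_rows(
    table[drop, , drop = FALSE], "low_coverage",
    sprintf("total %g < %g", totals[drop], min_total))
  out
}

#' Remove genes with too few surviving guides
#'
#' Within each (gene, target site, replicate) context, removes all rows of
#' genes represented by fewer than `min_guides` distinct sgRNAs. Requiring
#' several independent guides per gene protects the downstream geometric-mean
#' gene spectrum from being driven by a single, possibly off-target, guide.
#'
#' @inheritParams filter_low_coverage
#' @param min_guides minimum number of distinct sgRNAs per gene context;
#'   default 3.
#' @return the filtered table with a `filter_report` attribute.
#' @export
filter_min_guides <- function(table, min_guides = 3) {
  validate_count_table(table)
  if (!nrow(table)) {
    attr(table, "filter_report") <- filter_report_rows(table, "min_guides",
                                                       character(0))
    return(table)
  }
  ctx <- paste(table$gene, table$target_site, table$replicate, sep = "\r")
  n_guides <- vapply(split(table$sgrna_id, ctx),
                     function(x) length(unique(x)), integer(1))
  drop <- n_guides[ctx] < min_guides
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- filter_report_rows(
    table[drop, , drop = FALSE], "min_guides",
    sprintf("gene has %d < %d guides in context", n_guides[ctx][drop],
            min_guides))
  out
}

#' Remove sgRNAs with inconsistent count profiles
#'
#' Flags a row (one sgRNA in one replicate and target site) when its
#' seven-category count profile disagrees with the profiles it should
#' resemble, which is symptomatic of off-target activity or ineffective
#' perturbation. Two criteria, both on raw counts and both using Pearson
#' correlation with threshold `min_median_r` (strict `<`):
#'
#' * within-gene: median correlation against the profiles of the *other*
#'   sgRNAs of the same gene in the same replicate and target site;
#' * cross-replicate: median correlation against the profiles of the *same*
#'   sgRNA in the other replicates of the same target site.
#'
#' Both criteria are evaluated on the pre-removal profiles and removals are
#' applied jointly. A criterion with no comparison partners (single guide,
#' single replicate) is vacuous and passes. A zero-variance (constant)
#' profile, whose correlation is undefined, fails the criterion it appears in
#' and is reported as such.
#'
#' @inheritParams filter_low_coverage
#' @param min_median_r minimum median pairwise Pearson correlation; default
#'   0.6.
#' @return the filtered table with a `filter_report` attribute.
#' @export
filter_inconsistent_guides <- function(table, min_median_r = 0.6) {
  validate_count_table(table)
  n <- nrow(table)
  if (!n) {
    attr(table, "filter_report") <- filter_report_rows(table, "consistency",
                                                       character(0))
    return(table)
  }
  cnt <- count_matrix(table)
  zero_var <- apply(cnt, 1, stats::sd) == 0
  # correlation of rows i vs set js; NA (constant profile) counts as failure
  med_cor <- function(i, js) {
    if (!length(js)) return(NA_real_)  # vacuous: no partners
    r <- suppressWarnings(
      as.vector(stats::cor(cnt[i, ], t(cnt[js, , drop = FALSE]))))
    r[is.na(r)] <- -Inf
    stats::median(r)
  }

  within_r <- rep(NA_real_, n)
  gene_ctx <- paste(table$gene, table$target_site, table$replicate, sep = "\r")
  for (idx in split(seq_len(n), gene_ctx)) {
    for (i in idx) {
      others <- setdiff(idx[table$sgrna_id[idx] != table$sgrna_id[i]], i)
      within_r[i] <- med_cor(i, others)
    }
  }

  rep_r <- rep(NA_real_, n)
  guide_ctx <- paste(table$sgrna_id, table$gene, table$target_site, sep = "\r")
  for (idx in split(seq_len(n), guide_ctx)) {
    for (i in idx) {
      others <- idx[table$replicate[idx] != table$replicate[i]]
      rep_r[i] <- med_cor(i, others)
    }
  }

  fail_within <- !is.na(within_r) & within_r < min_median_r
  fail_rep <- !is.na(rep_r) & rep_r < min_median_r
  drop <- fail_within | fail_rep
  reason <- character(sum(drop))
  reason[fail_within[drop]] <- sprintf("within-gene median r %.3f < %.2f",
                                       within_r[drop][fail_within[drop]],
                                       min_median_r)
  reason[fail_rep[drop] & !fail_within[drop]] <-
    sprintf("cross-replicate median r %.3f < %.2f",
            rep_r[drop][fail_rep[drop] & !fail_within[drop]], min_median_r)
  reason[zero_var[drop]] <- paste0(reason[zero_var[drop]],
                                   " (constant profile)")
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- filter_report_rows(table[drop, , drop = FALSE],
                                                   "consistency", reason)
  out
}

#' Replace zero counts by sub-detection-limit draws
#'
#' Log-ratio transforms are undefined at zero, so every zero cell is replaced
#' by an independent draw from Uniform(0.1·DL, DL) where DL is the detection
#' limit (default 1 read). Nonzero cells are untouched and the draw is
#' reproducible given `seed`.
#'
#' @inheritParams filter_low_coverage
#' @param seed integer seed controlling the draws.
#' @param dl detection limit DL; default 1.
#' @return the table with strictly positive (real-valued) counts.
#' @export
impute_zeros <- function(table, seed, dl = 1) {
  validate_count_table(table)
  cnt <- count_matrix(table)
  zero <- cnt == 0
  if (any(zero)) {
    cnt[zero] <- with_seed(seed, stats::runif(sum(zero), 0.1 * dl, dl))
    table[analysis_categories()] <- cnt
  }
  table
}

filter_report_rows <- function(dropped, stage, reason) {
  data.frame(sgrna_id = dropped$sgrna_id, gene = dropped$gene,
             replicate = dropped$replicate, target_site = dropped$target_site,
             stage = rep_len(stage, nrow(dropped)),
             reason = rep_len(reason, nrow(dropped)),
             stringsAsFactors = FALSE)
}

#' Full preprocessing of a screen count table
#'
#' Applies the quality-control cascade in its fixed order: coverage filter,
#' minimum-guide filter, guide-consistency filter, a re-check of the
#' minimum-guide criterion (consistency removals can drop a gene below the
#' minimum), then zero imputation.
#'
#' @inheritParams filter_low_coverage
#' @inheritParams filter_min_guides
#' @inheritParams filter_inconsistent_guides
#' @inheritParams impute_zeros
#' @param recheck_min_guides re-apply the guide-count filter after the
#'   consistency filter (default `TRUE`).
#' @return list with `counts` (the filtered, imputed table) and `report`
#'   (data frame of removed rows with stage and reason).
#' @export
#' @examples
#' sim <- simulate_screen(simulation_config(n_genes = 30, n_outliers = 2,
#'                                          n_targets = 1, seed = 1))
#' pre <- preprocess_counts(sim$counts, seed = 1)
#' nrow(pre$counts); table(pre$report$stage)
preprocess_counts <- function(table, min_total = 700, min_guides = 3,
                              min_median_r = 0.6, dl = 1, seed = 1,
                              recheck_min_guides = TRUE) {
  steps <- list()
  t1 <- filter_low_coverage(table, min_total)
  steps[[1]] <- attr(t1, "filter_report")
  t2 <- filter_min_guides(t1, min_guides)
  steps[[2]] <- attr(t2, "filter_report")
  t3 <- filter_inconsistent_guides(t2, min_median_r)
  steps[[3]] <- attr(t3, "filter_report")
  if (recheck_min_guides) {
    t3 <- filter_min_guides(t3, min_guides)
    rep2 <- attr(t3, "filter_report")
    rep2$stage <- rep_len("min_guides_recheck", nrow(rep2))
    steps[[4]] <- rep2
  }
  out <- impute_zeros(t3, seed = seed, dl = dl)
  attr(out, "filter_report") <- NULL
  list(counts = out, report = do.call(rbind, steps))
}
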