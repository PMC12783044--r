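#' Configuration for the synthetic screen simulator
#'
#' Describes a perturbation screen with mutational-spectra readout the way
#' the scoring model assumes it: a large majority of null genes whose guides
#' sample around a target-specific base composition, plus a minority of
#' outlier genes whose true composition is displaced from the base by a fixed
#' Aitchison-geometry effect size, with heavy-tailed sequencing coverage and
#' occasional zero counts.
#'
#' @param n_genes total number of genes; default 525.
#' @param n_outliers number of planted outlier genes; must be fewer than half
#'   of `n_genes` (the outlier-detection assumption); default 25.
#' @param guides_per_gene sgRNAs per gene; default 5.
#' @param n_replicates biological replicates; default 2.
#' @param n_targets cut sites (1-3); default 3.
#' @param base_composition matrix `n_targets` x 7 of strictly positive
#'   unit-sum rows, the wild-type spectrum per target. Defaults emulate
#'   deletion-dominated double-strand-break repair spectra with moderate
#'   insertion and HDR fractions varying between cut sites.
#' @param concentration Dirichlet precision of per-guide spectra around the
#'   gene's true composition; larger = less biological/technical dispersion.
#'   Default 200.
#' @param effect_size Euclidean norm, in ILR coordinates, of the planted
#'   displacement of outlier genes; direction uniform on the unit sphere.
#'   Default 1.5.
#' @param coverage_median median reads per sgRNA and replicate; default 3000.
#' @param coverage_sdlog log-normal sdlog of coverage; default 1 (heavy
#'   tail, so a realistic fraction of guides falls under read-count filters).
#' @param zero_rate probability that a count cell is zeroed (drop-out);
#'   default 0.01.
#' @param seed integer seed; default 1.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 525, n_outliers = 25,
                              guides_per_gene = 5, n_replicates = 2,
                              n_targets = 3, base_composition = NULL,
                              concentration = 200, effect_size = 1.5,
                              coverage_median = 3000, coverage_sdlog = 1,
                              zero_rate = 0.01, seed = 1) {
  if (n_outliers >= n_genes / 2) {
    stop("n_outliers must be below half of n_genes")
  }
  if (!n_targets %in% 1:3 && is.null(base_composition)) {
    stop("default base compositions cover 1-3 targets; supply base_composition")
  }
  if (is.null(base_composition)) {
    defaults <- rbind(
      T1 = c(0.32, 0.15, 0.09, 0.06, 0.22, 0.06, 0.10),
      T2 = c(0.38, 0.12, 0.07, 0.05, 0.18, 0.08, 0.12),
      T3 = c(0.28, 0.18, 0.10, 0.08, 0.20, 0.05, 0.11))
    base_composition <- defaults[seq_len(n_targets), , drop = FALSE]
  }
  base_composition <- as.matrix(base_composition)
  if (ncol(base_composition) != 7 || nrow(base_composition) != n_targets) {
    stop("base_composition must be n_targets x 7")
  }
  if (any(base_composition <= 0)) {
    stop("base compositions must be strictly positive")
  }
  base_composition <- closure(base_composition)
  colnames(base_composition) <- analysis_categories()
  if (is.null(rownames(base_composition))) {
    rownames(base_composition) <- paste0("T", seq_len(n_targets))
  }
  structure(list(n_genes = n_genes, n_outliers = n_outliers,
                 guides_per_gene = guides_per_gene,
                 n_replicates = n_replicates, n_targets = n_targets,
                 base_composition = base_composition,
                 concentration = concentration, effect_size = effect_size,
                 coverage_median = coverage_median,
                 coverage_sdlog = coverage_sdlog, zero_rate = zero_rate,
                 seed = seed),
            class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a perturbation screen with mutational-spectra readout
#'
#' Generates a per-sgRNA count table over the seven analysis categories plus
#' the ground truth of planted effects. Null genes share the target's base
#' composition; each outlier gene is displaced by `effect_size` along a
#' random ILR direction (the same direction in every target, as a genuine
#' gene effect would be). Each sgRNA x replicate x target observation draws
#' its spectrum from a Dirichlet around the gene's true composition, its
#' coverage from a log-normal, and its counts from a multinomial; cells are
#' then zeroed at `zero_rate` to mimic drop-out. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (count table, see [build_count_table()] for the
#'   schema) and `truth` (data frame: `gene`, `label`, `effect_size`), plus
#'   the per-gene true compositions as attribute
#'   `true_compositions` (array gene x target x category) on `truth`.
#' @export
#' @examples
#' sim <- simulate_screen(simulation_config(n_genes = 40, n_outliers = 2,
#'                                          n_targets = 1, seed = 42))
#' head(sim$counts); table(sim$truth$label)
simulate_screen <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must come from simulation_config()")
  }
  cats <- analysis_categories()
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  targets <- rownames(config$base_composition)

  with_seed(config$seed, {
    outlier_genes <- sort(sample(genes, config$n_outliers))
    label <- ifelse(genes %in% outlier_genes, "outlier", "null")

    true_comp <- array(NA_real_, dim = c(config$n_genes, config$n_targets, 7),
                       dimnames = list(genes, targets, cats))
    base_ilr <- ilr(config$base_composition)
    if (config$n_targets == 1) base_ilr <- matrix(base_ilr, nrow = 1)
    for (i in seq_len(config$n_genes)) {
      if (label[i] == "outlier") {
        u <- stats::rnorm(6)
        delta <- config$effect_size * u / sqrt(sum(u^2))
      } else {
        delta <- rep(0, 6)
      }
      for (j in seq_len(config$n_targets)) {
        true_comp[i, j, ] <- ilr_inv(base_ilr[j, ] + delta)
      }
    }

    n_rows <- config$n_genes * config$guides_per_gene * config$n_replicates *
      config$n_targets
    sgrna_id <- character(n_rows)
    gene_col <- character(n_rows)
    replicate <- character(n_rows)
    target_site <- character(n_rows)
    cnt_mat <- matrix(0, n_rows, 7, dimnames = list(NULL, cats))
    r <- 0L
    for (i in seq_len(config$n_genes)) {
      for (s in seq_len(config$guides_per_gene)) {
        sg <- sprintf("%s_sg%d", genes[i], s)
        for (j in seq_len(config$n_targets)) {
          for (k in seq_len(config$n_replicates)) {
            p <- rdirichlet1(config$concentration * true_comp[i, j, ])
            cov_n <- max(1L, round(stats::rlnorm(
              1, meanlog = log(config$coverage_median),
              sdlog = config$coverage_sdlog)))
            cnt <- as.vector(stats::rmultinom(1, cov_n, p))
            if (config$zero_rate > 0) {
              cnt[stats::runif(7) < config$zero_rate] <- 0L
            }
            r <- r + 1L
            sgrna_id[r] <- sg
            gene_col[r] <- genes[i]
            replicate[r] <- paste0("R", k)
            target_site[r] <- targets[j]
            cnt_mat[r, ] <- cnt
          }
        }
      }
    }
    counts <- data.frame(sgrna_id = sgrna_id, gene = gene_col,
                         replicate = replicate, target_site = target_site,
                         stringsAsFactors = FALSE)
    counts[cats] <- cnt_mat

    truth <- data.frame(gene = genes, label = label,
                        effect_size = ifelse(label == "outlier",
                                             config$effect_size, 0),
                        stringsAsFactors = FALSE)
    attr(truth, "true_compositions") <- true_comp
    list(counts = validate_count_table(counts), truth = truth,
         config = config)
  })
}
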