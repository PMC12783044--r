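# Fixtures are built in code; counts are integer 7-vectors over the analysis
# categories in canonical order.

make_counts <- function(sgrna_id, gene, replicate, target_site, counts) {
  stopifnot(length(counts) == 7)
  row <- data.frame(sgrna_id = sgrna_id, gene = gene, replicate = replicate,
                    target_site = target_site, stringsAsFactors = FALSE)
  row[analysis_categories()] <- as.list(counts)
  row
}

# 12-row toy table exercising every filter stage exactly:
#  - geneA: 3 consistent guides x 2 replicates, all totals >= 700 -> survive;
#  - geneB b1/R1: total 699 -> coverage filter;
#  - geneB R1 then has 2 guides -> b2/R1, b3/R1 removed by the guide-count
#    filter;
#  - geneB b3/R2 has a scrambled profile: r vs b1/R2 and b2/R2 is ~0.40 and
#    ~0.36, so its median 0.38 < 0.6 while b1 and b2 keep medians >= 0.67
#    (r(b1,b2) = 0.98) -> only b3/R2 falls to the consistency filter (its R1
#    partner is already gone, so the cross-replicate criterion is vacuous);
#  - geneB R2 then has 2 guides -> b1/R2, b2/R2 removed by the re-check.
toy_filter_table <- function() {
  a <- c(300, 200, 100, 50, 150, 40, 60)
  rbind(
    make_counts("a1", "geneA", "R1", "T1", a),
    make_counts("a2", "geneA", "R1", "T1", 2 * a),
    make_counts("a3", "geneA", "R1", "T1", c(310, 190, 105, 45, 155, 35, 70)),
    make_counts("a1", "geneA", "R2", "T1", c(290, 210, 95, 55, 145, 45, 55)),
    make_counts("a2", "geneA", "R2", "T1", c(610, 390, 210, 90, 310, 70, 130)),
    make_counts("a3", "geneA", "R2", "T1", c(305, 195, 100, 50, 150, 40, 65)),
    make_counts("b1", "geneB", "R1", "T1", c(200, 150, 100, 80, 90, 49, 30)),
    make_counts("b2", "geneB", "R1", "T1", c(410, 290, 210, 150, 190, 90, 70)),
    make_counts("b3", "geneB", "R1", "T1", c(390, 310, 190, 160, 180, 110, 60)),
    make_counts("b1", "geneB", "R2", "T1", c(400, 300, 200, 160, 180, 100, 60)),
    make_counts("b2", "geneB", "R2", "T1", c(420, 280, 220, 140, 200, 80, 80)),
    make_counts("b3", "geneB", "R2", "T1", c(270, 170, 265, 173, 167, 295, 60))
  )
}

row_key <- function(tab) {
  paste(tab$sgrna_id, tab$replicate, tab$target_site, sep = "/")
}

random_composition <- function(d = 7) closure(stats::runif(d, 0.05, 1))

# random orthonormal ILR contrast matrix: rotate the default basis
random_ilr_basis <- function(d = 7) {
  Q <- qr.Q(qr(matrix(stats::rnorm((d - 1)^2), d - 1)))
  Q %*% ilr_basis(d)
}

# independent Benjamini-Hochberg step-up oracle
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
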