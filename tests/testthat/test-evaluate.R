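test_that("Jensen-Shannon distance matches hand-evaluated cases", {
  expect_equal(jensen_shannon_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), 1)
  # direct evaluation of the divergence sum for p=(.5,.5), q=(.9,.1), base 2
  p <- c(0.5, 0.5); q <- c(0.9, 0.1); m <- (p + q) / 2
  js <- sum(p * log2(p / m)) / 2 + sum(q * log2(q / m)) / 2
  expect_equal(jensen_shannon_distance(p, q), sqrt(js))
  # natural-log mode is smaller by sqrt(log(2))
  expect_equal(jensen_shannon_distance(p, q, base = exp(1)),
               sqrt(js * log(2)))
  expect_error(jensen_shannon_distance(c(1, 0), c(0.2, 0.3, 0.5)), "length")
})

test_that("JSD is a bounded symmetric metric on random compositions", {
  set.seed(21)
  for (i in 1:30) {
    p <- random_composition(); q <- random_composition()
    r <- random_composition()
    dpq <- jensen_shannon_distance(p, q)
    expect_gte(dpq, 0); expect_lte(dpq, 1)
    expect_equal(dpq, jensen_shannon_distance(q, p))
    expect_lte(dpq, jensen_shannon_distance(p, r) +
                 jensen_shannon_distance(r, q) + 1e-12)
  }
})

test_that("precision-recall and AP match the worked ranking", {
  ev <- pr_ap(c("g1", "g2", "g3"), c("g1", "g3"))
  expect_equal(ev$average_precision, (1 / 1 + 2 / 3) / 2)
  expect_equal(ev$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(ev$recall, c(1 / 2, 1 / 2, 1))
  expect_equal(ev$baseline_ap, 2 / 3)
  # gold = universe gives AP 1; reversed perfect ranking is minimal
  expect_equal(pr_ap(letters[1:5], letters[1:5])$average_precision, 1)
  perfect <- pr_ap(letters[1:10], letters[1:3])$average_precision
  reversed <- pr_ap(rev(letters[1:10]), letters[1:3])$average_precision
  expect_equal(perfect, 1)
  expect_equal(reversed, (1 / 8 + 2 / 9 + 3 / 10) / 3)
  set.seed(3)
  for (i in 1:20) {
    expect_gte(pr_ap(sample(letters[1:10]), letters[1:3])$average_precision,
               reversed)
  }
  expect_warning(pr_ap(letters[1:5], c("a", "z")), "absent")
  expect_error(pr_ap(letters[1:5], character(0)), "empty")
})

test_that("random rankings score at the prevalence baseline", {
  universe <- sprintf("G%03d", 1:200)
  gold <- universe[1:10]
  aps <- ap_random_baseline(universe, gold, n_perm = 500, seed = 5)
  expect_equal(mean(aps), 0.05, tolerance = 0.3)
  expect_identical(aps, ap_random_baseline(universe, gold, 500, seed = 5))
})

test_that("difference matrix subtracts the control geometric mean per target", {
  cats <- analysis_categories()
  sp <- data.frame(gene = rep(c("c1", "c2", "g1"), 2),
                   target_site = rep(c("T1", "T2"), each = 3),
                   stringsAsFactors = FALSE)
  set.seed(6)
  sp[cats] <- closure(matrix(runif(42, 0.05, 1), 6))
  dm <- difference_matrix(sp, controls = c("c1", "c2"))
  expect_equal(dim(dm), c(3L, 14L))
  # each complete 7-column target block sums to zero
  expect_equal(unname(rowSums(dm[, 1:7])), rep(0, 3), tolerance = 1e-12)
  # a gene equal to the control gmean has a zero row
  ctr <- geometric_mean_spectrum(as.matrix(sp[sp$target_site == "T1" &
                                                sp$gene != "g1", cats]))
  sp2 <- sp
  sp2[sp2$gene == "g1" & sp2$target_site == "T1", cats] <- as.list(ctr)
  dm2 <- difference_matrix(sp2, c("c1", "c2"))
  expect_equal(unname(dm2["g1", 1:7]), rep(0, 7), tolerance = 1e-12)
  # hand-computed toy: one control, so center = the control spectrum
  dm3 <- difference_matrix(sp, controls = "c1")
  expect_equal(unname(dm3["g1", 1:7]),
               unlist(sp[sp$gene == "g1" & sp$target_site == "T1", cats]) -
                 unlist(sp[sp$gene == "c1" & sp$target_site == "T1", cats]),
               ignore_attr = TRUE)
  # a missing (gene, target) pair stays missing
  dm4 <- difference_matrix(sp[-3, ], c("c1", "c2"))
  expect_true(all(is.na(dm4["g1", 1:7])))
  expect_error(difference_matrix(sp[sp$gene == "g1", ], "c9"), "control")
})

test_that("clustering merges by correlation shape with Ward linkage", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             g2 = c(2, 4, 6, 8, 10, 12, 14, 16),   # r = 1 with g1
             g3 = c(8, 7, 6, 5, 4, 3, 2, 1))       # r = -1 with g1
  co <- cluster_order(m)
  # perfectly correlated rows merge first (distance 0), the anti-correlated
  # row joins last at the maximal distance
  expect_equal(co$row_tree$merge[1, ], c(-1, -2))
  expect_equal(co$row_tree$height[1], 0)
  expect_setequal(co$row_order, 1:3)
  # scaling a row by a positive constant changes nothing (Pearson invariance)
  m2 <- m; m2[1, ] <- 5 * m2[1, ]
  co2 <- cluster_order(m2)
  expect_equal(co2$row_tree$merge, co$row_tree$merge)
  expect_equal(co2$row_tree$height, co$row_tree$height)
  # constant rows are placed at distance 1 from everything, not an error
  m3 <- rbind(m, g4 = rep(3, 8))
  expect_silent(co3 <- cluster_order(m3))
  expect_setequal(co3$row_order, 1:4)
  # leaf order is reproducible across input row permutations
  perm <- c(3, 1, 2)
  co4 <- cluster_order(m[perm, ])
  expect_equal(rownames(m[perm, ])[co4$row_order], rownames(m)[co$row_order])
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  bg <- sprintf("g%02d", 1:10)
  ann <- data.frame(term_id = "t1", gene = bg[1:5])
  res <- enrich_hypergeometric(bg[1:4], bg, ann)
  expect_equal(res$p_value, choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(res$k, 4)
  expect_equal(res$gene_ratio, 1)
  # zero overlap: P(X >= 0) = 1
  ann0 <- data.frame(term_id = "t0", gene = bg[5:8])
  res0 <- enrich_hypergeometric(bg[1:4], bg, ann0)
  expect_equal(res0$p_value, 1)
  # invariants: 0 <= k <= min(K, n) <= N and BH q >= p
  ann3 <- data.frame(term_id = rep(c("a", "b", "c"), c(5, 4, 3)),
                     gene = c(bg[1:5], bg[3:6], bg[8:10]))
  res3 <- enrich_hypergeometric(bg[1:4], bg, ann3)
  expect_true(all(res3$k <= pmin(res3$K, res3$n)))
  expect_true(all(res3$fdr_q >= res3$p_value))
  # BH equals the independent step-up oracle
  expect_equal(res3$fdr_q, bh_stepup(res3$p_value))
  # terms with no background members are skipped
  annx <- rbind(ann3, data.frame(term_id = "x", gene = "not_in_bg"))
  expect_equal(nrow(enrich_hypergeometric(bg[1:4], bg, annx)), 3)
  expect_error(enrich_hypergeometric(c(bg[1], "zz"), bg, ann), "subset")
  # GMT-style named-list input is accepted
  res_l <- enrich_hypergeometric(bg[1:4], bg, list(t1 = bg[1:5]))
  expect_equal(res_l$p_value, res$p_value)
})

test_that("group regression equals the case-control mean difference", {
  cats <- analysis_categories()
  sp <- data.frame(gene = sprintf("g%02d", 1:12), target_site = "T1",
                   stringsAsFactors = FALSE)
  set.seed(7)
  sp[cats] <- closure(matrix(runif(84, 0.05, 1), 12))
  cases <- sp$gene[1:5]; ctrls <- sp$gene[6:12]
  res <- group_regression(sp, cases, ctrls)
  for (o in cats) {
    expect_equal(res$coefficient[res$category == o],
                 mean(sp[[o]][1:5]) - mean(sp[[o]][6:12]))
  }
  expect_equal(res$fdr_q, bh_stepup(res$p_value), tolerance = 1e-12)
  # exact separation: constant 0.4 vs 0.1 gives coefficient 0.3, p ~ 0
  sp2 <- sp
  sp2[1:5, cats[1]] <- 0.4; sp2[6:12, cats[1]] <- 0.1
  # tiny jitter so residual variance is nonzero
  sp2[[cats[1]]] <- sp2[[cats[1]]] + seq(0, 1.1e-6, length.out = 12)
  res2 <- group_regression(sp2, cases, ctrls)
  expect_equal(res2$coefficient[res2$category == cats[1]], 0.3,
               tolerance = 1e-4)
  expect_lt(res2$p_value[res2$category == cats[1]], 1e-10)
  # relabelling controls changes nothing; membership is all that matters
  res3 <- group_regression(sp, cases, rev(ctrls))
  expect_equal(res3$coefficient, res$coefficient)
  # under-represented terms are excluded
  expect_equal(nrow(group_regression(sp, cases[1:2], ctrls)), 0)
  expect_error(group_regression(sp, cases, character(0)), "empty control")
  expect_error(group_regression(sp, cases, cases), "both case and control")
})

test_that("recovery metrics behave at the extremes", {
  scores <- data.frame(gene = sprintf("G%02d", 1:20),
                       unified_score = 20:1, rank = 1:20)
  truth <- data.frame(gene = scores$gene,
                      label = rep(c("outlier", "null"), c(4, 16)))
  perfect <- recovery_report(scores, truth)
  expect_equal(perfect$recall_at_k, 1)
  expect_equal(perfect$auprc, 1)
  inverted <- scores; inverted$rank <- rev(inverted$rank)
  worst <- recovery_report(inverted, truth)
  expect_equal(worst$recall_at_k, 0)
  expect_error(recovery_report(scores, data.frame(gene = "ZZ", label = "null")),
               "share no genes")
})

test_that("annotation and gene-list files parse in both dialects", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("t1\tdesc one\tg1\tg2\tg3", "t2\tdesc two\tg2\tg4"), f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 5)
  expect_equal(ann$gene[ann$term_id == "t2"], c("g2", "g4"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(term_id = "t1", gene = c("g1", "g2")), f2)
  expect_equal(read_annotations(f2)$gene, c("g1", "g2"))
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# gold standard", "g1", "", "g2"), f3)
  expect_equal(read_gene_list(f3), c("g1", "g2"))
})
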