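test_that("event categorization follows the eight-category scheme", {
  expect_equal(categorize_event("wildtype"), "WT")
  expect_equal(categorize_event("deletion", mh_length = 0), "DEL_MH0")
  expect_equal(categorize_event("deletion", mh_length = 2), "DEL_MH2")
  expect_equal(categorize_event("deletion", mh_length = 3), "DEL_MH3P")
  expect_equal(categorize_event("deletion", mh_length = 7), "DEL_MH3P")
  expect_equal(categorize_event("insertion", donor_match = TRUE), "HDR")
  expect_equal(categorize_event("insertion", donor_match = FALSE), "INS")
  expect_equal(categorize_event("deletion_insertion"), "DELINS")
  # substitutions and other rare kinds are excluded, not errors
  expect_true(is.na(categorize_event("substitution")))
  expect_true(is.na(categorize_event("other")))
  expect_error(categorize_event("inversion"), "unknown event kind")
  expect_error(categorize_event("deletion", mh_length = -1), ">= 0")
})

test_that("count tabulation sums per key and drops WT/excluded events", {
  ev <- data.frame(
    sgrna_id = c("s1", "s1", "s1", "s2", "s1"),
    gene = "g1", replicate = c("R1", "R1", "R1", "R1", "R2"),
    target_site = "T1",
    kind = c("deletion", "deletion", "substitution", "wildtype", "insertion"),
    mh_length = c(1, 1, 0, 0, 0),
    donor_match = FALSE,
    read_count = c(3, 4, 100, 500, 9),
    stringsAsFactors = FALSE)
  tab <- build_count_table(ev)
  # additivity of same-key, same-category events
  expect_equal(tab$DEL_MH1[tab$sgrna_id == "s1" & tab$replicate == "R1"], 7)
  # substitutions contribute nothing
  expect_equal(sum(as.matrix(tab[tab$sgrna_id == "s1" & tab$replicate == "R1",
                                 analysis_categories()])), 7)
  # replicate separation: s1 appears once per replicate
  expect_equal(sum(tab$sgrna_id == "s1"), 2)
  expect_equal(tab$INS[tab$replicate == "R2"], 9)
  # a WT-only key still yields a row, with all-zero analysis categories
  expect_true("s2" %in% tab$sgrna_id)
  expect_equal(sum(as.matrix(tab[tab$sgrna_id == "s2",
                                 analysis_categories()])), 0)
  # empty input is valid
  expect_equal(nrow(build_count_table(ev[0, ])), 0)
})

test_that("coverage filter removes rows strictly below the read cutoff", {
  tab <- toy_filter_table()
  out <- filter_low_coverage(tab, 700)
  expect_false("b1/R1/T1" %in% row_key(out))       # total 699: removed
  expect_true(all(rowSums(out[analysis_categories()]) >= 700))
  expect_equal(nrow(out), 11)
  rep <- attr(out, "filter_report")
  expect_equal(rep$sgrna_id, "b1")
  # boundary: exactly at the cutoff is retained; cutoff 0 is the identity
  expect_equal(nrow(filter_low_coverage(tab, 0)), nrow(tab))
  a700 <- make_counts("x", "g", "R1", "T1", c(100, 100, 100, 100, 100, 100, 100))
  expect_equal(nrow(filter_low_coverage(a700, 700)), 1)
})

test_that("guide-count filter drops genes below the minimum per context", {
  tab <- rbind(
    make_counts("s1", "g1", "R1", "T1", rep(100, 7)),
    make_counts("s2", "g1", "R1", "T1", rep(110, 7)),
    make_counts("s1", "g2", "R1", "T1", rep(100, 7)),
    make_counts("s2", "g2", "R1", "T1", rep(100, 7)),
    make_counts("s3", "g2", "R1", "T1", rep(100, 7)))
  out <- filter_min_guides(tab, 3)
  expect_setequal(unique(out$gene), "g2")          # g1 has 2 < 3 guides
  expect_equal(nrow(out), 3)
  expect_equal(nrow(filter_min_guides(tab[0, ], 3)), 0)
  # boundary: exactly 3 guides retained
  expect_equal(nrow(filter_min_guides(out, 3)), 3)
})

test_that("consistency filter removes low-correlation profiles jointly", {
  p1 <- c(700, 0, 0, 0, 0, 0, 0)
  tab <- rbind(
    make_counts("s1", "g1", "R1", "T1", p1),
    make_counts("s2", "g1", "R1", "T1", p1),
    make_counts("s3", "g1", "R1", "T1", rev(p1)))
  # hand Pearson: r(p1, rev(p1)) = -1, r(p1, p1) = 1; medians with two values
  # are means, so s1/s2 get median 0 and s3 gets -1: all below 0.6, all
  # removed on the pre-removal profiles
  out <- filter_inconsistent_guides(tab, 0.6)
  expect_equal(nrow(out), 0)
  expect_true("s3" %in% attr(out, "filter_report")$sgrna_id)

  # an sgRNA matching its replicate (r = 1) and its gene-mates (r high) stays
  tab2 <- toy_filter_table()[1:6, ]                # geneA block, consistent
  out2 <- filter_inconsistent_guides(tab2, 0.6)
  expect_equal(nrow(out2), 6)

  # a constant profile has undefined correlation and fails the criterion
  tab3 <- rbind(toy_filter_table()[1:3, ],
                make_counts("a4", "geneA", "R1", "T1", rep(5, 7)))
  out3 <- filter_inconsistent_guides(tab3, 0.6)
  expect_false("a4" %in% out3$sgrna_id)
  expect_match(attr(out3, "filter_report")$reason[
    attr(out3, "filter_report")$sgrna_id == "a4"], "constant")

  # cross-replicate criterion: same sgRNA anti-correlated across replicates
  tab4 <- rbind(make_counts("s1", "g1", "R1", "T1", p1),
                make_counts("s1", "g1", "R2", "T1", rev(p1)))
  out4 <- filter_inconsistent_guides(tab4, 0.6)
  expect_equal(nrow(out4), 0)
})

test_that("zero imputation draws within (0.1 DL, DL), reproducibly", {
  tab <- rbind(make_counts("s1", "g1", "R1", "T1", c(0, 42, 0, 1, 2, 3, 4)),
               make_counts("s2", "g1", "R1", "T1", rep(10, 7)))
  out <- impute_zeros(tab, seed = 9)
  m <- as.matrix(out[analysis_categories()])
  expect_true(all(m > 0))
  imputed <- m[1, c(1, 3)]
  expect_true(all(imputed >= 0.1 & imputed <= 1))
  expect_equal(unname(m[1, 2]), 42)                 # nonzero untouched
  expect_identical(out[2, ], tab[2, ])              # zero-free row unchanged
  expect_identical(impute_zeros(tab, seed = 9), out)       # determinism
  expect_false(identical(impute_zeros(tab, seed = 10), out))
  expect_identical(row_key(out), row_key(tab))      # row-key set preserved
  # scaled detection limit
  m5 <- as.matrix(impute_zeros(tab, seed = 9, dl = 5)[analysis_categories()])
  expect_true(all(m5[1, c(1, 3)] >= 0.5 & m5[1, c(1, 3)] <= 5))
})

test_that("preprocessing cascade removes the designed rows at each stage", {
  pre <- preprocess_counts(toy_filter_table(), seed = 3)
  expect_setequal(unique(pre$counts$gene), "geneA")
  expect_equal(nrow(pre$counts), 6)
  expect_equal(pre$report$stage[pre$report$sgrna_id == "b1" &
                                  pre$report$replicate == "R1"],
               "low_coverage")
  expect_setequal(
    row_key(pre$report[pre$report$stage == "min_guides", ]),
    c("b2/R1/T1", "b3/R1/T1"))
  expect_equal(row_key(pre$report[pre$report$stage == "consistency", ]),
               "b3/R2/T1")
  expect_setequal(
    row_key(pre$report[pre$report$stage == "min_guides_recheck", ]),
    c("b1/R2/T1", "b2/R2/T1"))
  # filters are idempotent on their own output
  again <- preprocess_counts(pre$counts, seed = 3)
  expect_equal(nrow(again$report), 0)
  expect_equal(again$counts, pre$counts)
})

test_that("event and count tables round-trip through TSV", {
  tab <- toy_filter_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(tab, f)
  expect_equal(read_counts(f), tab)
  # WT column, if present, is dropped on read
  tab_wt <- cbind(tab, WT = 99L)
  write_tsv(tab_wt, f)
  expect_equal(read_counts(f), tab)

  ev <- data.frame(sgrna_id = "s1", gene = "g1", replicate = "R1",
                   target_site = "T1", kind = "deletion", mh_length = 2,
                   donor_match = FALSE, read_count = 10,
                   stringsAsFactors = FALSE)
  write_tsv(ev, f)
  expect_equal(read_events(f), ev)
})
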