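test_that("two-group ANOVA matches hand computation and handles degeneracy", {
  r <- anova_two_group(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$F, 13.5)                       # SSB = 13.5, SSW/df = 1
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(r$df, c(1L, 4L))

  same <- anova_two_group(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  const_eq <- anova_two_group(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const_eq$F, 0)
  expect_equal(const_eq$p, 1)
  const_ne <- anova_two_group(c(2, 2, 2), c(3, 3, 3))
  expect_equal(const_ne$F, Inf)
  expect_equal(const_ne$p, 0)

  expect_error(anova_two_group(1, c(1, 2)), "at least 2")
})

test_that("ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(101)
  for (i in 1:1000) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 3))
    b <- rnorm(nb, mean = runif(1, -2, 2))
    r <- anova_two_group(a, b)
    t <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$F, unname(t$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, t$p.value, tolerance = 1e-10)
  }
})

test_that("scalar and row-wise ANOVA agree with stats::oneway.test", {
  set.seed(7)
  A <- matrix(rnorm(60), 20); B <- matrix(rnorm(60, 1), 20)
  rr <- row_anova_two_group(A, B)
  for (i in seq_len(20)) {
    ow <- oneway.test(y ~ g, data.frame(y = c(A[i, ], B[i, ]),
                                        g = rep(c("a", "b"), each = 3)),
                      var.equal = TRUE)
    expect_equal(rr$F[i], unname(ow$statistic), tolerance = 1e-12)
    expect_equal(rr$p[i], ow$p.value, tolerance = 1e-12)
  }
})

test_that("fold change uses post-replacement means with the double-low NA rule", {
  groups <- make_groups()
  rpkm_mat <- make_count_matrix(list(
    low_both = c(4, 4, 4, 2, 2, 2),
    same = c(3, 3, 3, 3, 3, 3),
    doubled = c(4, 4, 4, 2, 2, 2)), groups)
  storage.mode(rpkm_mat) <- "double"
  counts <- make_count_matrix(list(
    low_both = c(20, 20, 20, 30, 30, 30),   # both group means < 50 -> NA
    same = rep(100, 6),
    doubled = rep(100, 6)), groups)
  fc <- fold_change(rpkm_mat, counts, groups, "mutant", "control")
  expect_true(is.na(fc["low_both", "fold_change"]))
  expect_equal(fc["same", "fold_change"], 1)
  expect_equal(fc["doubled", "fold_change"], 2)
})

test_that("one group above 50 mean reads is enough to report a fold change", {
  groups <- make_groups()
  rpkm_mat <- matrix(c(6, 6, 6, 2, 2, 2), 1,
                     dimnames = list("g", names(groups)))
  counts <- matrix(as.integer(c(60, 60, 60, 20, 20, 20)), 1,
                   dimnames = list("g", names(groups)))
  fc <- fold_change(rpkm_mat, counts, groups, "mutant", "control")
  expect_equal(fc$fold_change, 3)
})

test_that("reciprocal fold changes multiply to one when reported", {
  ds <- small_sim()
  gc2 <- sum_gene_counts(ds$exon_counts, ds$gene_map)
  lib <- library_sizes(gc2)
  rel <- filter_reliable(gc2, 50)
  ab <- apply_replacement(gc2[rel, ], gene_lengths(ds$models), lib, 10)
  ab_counts <- gc2[rel, ]
  f1 <- fold_change(ab$rpkm, ab_counts, ds$groups, "mutant", "control")
  f2 <- fold_change(ab$rpkm, ab_counts, ds$groups, "control", "mutant")
  ok <- !is.na(f1$fold_change)
  expect_true(any(ok))
  expect_equal(f1$fold_change[ok] * f2$fold_change[ok], rep(1, sum(ok)),
               tolerance = 1e-12)
  expect_equal(is.na(f1$fold_change), is.na(f2$fold_change))
})

test_that("DE calling applies strict p cutoff and two-sided fold-change filter", {
  records <- data.frame(
    gene_id = c("strong_up", "at_cut", "mild_down", "na_fc", "deep_down"),
    fold_change = c(5.76, 2.0, 0.70, NA, 0.40),
    p = c(0.0146, 0.05, 0.01, 0.001, 0.02),
    stringsAsFactors = FALSE)
  calls <- call_de(records, p_cut = 0.05, fc_cut = 1.5)
  expect_true("strong_up" %in% calls$de_set)
  expect_true("strong_up" %in% calls$up_set)
  expect_false("at_cut" %in% calls$de_set)        # p = 0.05 exactly: out
  expect_true("mild_down" %in% calls$de_set)       # 0.70 > 1/1.5: not fc-filtered
  expect_false("mild_down" %in% calls$fc_set)
  expect_true("na_fc" %in% calls$de_set)           # NA fc never passes fc filter
  expect_false("na_fc" %in% calls$fc_set)
  expect_true("deep_down" %in% calls$down_set)     # 0.40 <= 1/1.5
  expect_setequal(calls$fc_set, c(calls$up_set, calls$down_set))
})

test_that("Venn classification implements the per-sample detection rules", {
  groups <- make_groups()
  counts <- make_count_matrix(list(
    all_detected = rep(50, 6),
    one_ctl_out = c(50, 50, 50, 50, 5, 50),
    one_mut_out = c(5, 50, 50, 50, 50, 50),
    both_out = c(5, 50, 50, 5, 50, 50),
    at_threshold = c(10, 50, 50, 50, 50, 50)), groups)  # 10 is NOT > 10
  v <- classify_venn(counts, groups, "mutant", "control", k_det = 10)
  cls <- setNames(as.character(v$venn_class), v$gene_id)
  expect_equal(unname(cls["all_detected"]), "common")
  expect_equal(unname(cls["one_ctl_out"]), "unique_A")
  expect_equal(unname(cls["one_mut_out"]), "unique_B")
  expect_equal(unname(cls["both_out"]), "excluded")
  expect_equal(unname(cls["at_threshold"]), "unique_B")
})

test_that("Venn classes partition every random count matrix", {
  groups <- make_groups()
  set.seed(33)
  for (i in 1:25) {
    counts <- make_count_matrix(
      lapply(1:40, function(j) rnbinom(6, mu = 15, size = 1)), groups)
    rownames(counts) <- paste0("g", 1:40)
    v <- classify_venn(counts, groups)
    expect_false(anyNA(v$venn_class))
    expect_equal(sum(table(v$venn_class)), 40L)
  }
})

test_that("de_table splits direction consistently with its calls", {
  ds <- small_sim(seed = 9)
  gc2 <- sum_gene_counts(ds$exon_counts, ds$gene_map)
  lib <- library_sizes(gc2)
  rel <- filter_reliable(gc2, 50)
  ab <- apply_replacement(gc2[rel, ], gene_lengths(ds$models), lib, 10)
  de <- de_table(ab, gc2[rel, ], ds$groups, "mutant", "control")
  expect_true(all(de$fold_change > 0, na.rm = TRUE))
  expect_true(all((de$direction == "up") == (de$fold_change > 1), na.rm = TRUE))
  expect_true(all(de$p_adj_info >= de$p - 1e-15))
  # direction classes partition the p<0.05 set
  dd <- de[de$p < 0.05, ]
  expect_equal(sum(dd$direction %in% c("up", "down", "none")), nrow(dd))
})
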