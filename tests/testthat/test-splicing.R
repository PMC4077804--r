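# small two-gene fixture: g1 has two equal-length exons, g2 one exon
splicing_fixture <- function(exon_rows, groups = make_groups(),
                             lengths = c(1000, 1000, 1000)) {
  models <- make_models(c("g1.E1", "g1.E2", "g2.E1"),
                        c("g1", "g1", "g2"), lengths)
  exon_counts <- make_count_matrix(exon_rows, groups)
  rownames(exon_counts) <- c("g1.E1", "g1.E2", "g2.E1")
  gene_map <- setNames(c("g1", "g1", "g2"), rownames(exon_counts))
  gene_counts <- sum_gene_counts(exon_counts, gene_map)
  lib <- library_sizes(gene_counts)
  rel <- filter_reliable(gene_counts, 50)
  gene_ab <- apply_replacement(gene_counts[rel, , drop = FALSE],
                               gene_lengths(models), lib, 10)
  retained <- filter_exons(exon_counts, gene_map, rel)
  exon_ab <- apply_replacement(exon_counts[retained, , drop = FALSE],
                               exon_lengths(models), lib, 1)
  list(models = models, exon_counts = exon_counts, gene_map = gene_map,
       gene_counts = gene_counts, gene_ab = gene_ab, exon_ab = exon_ab,
       rel = rel, groups = groups)
}

test_that("exon filter needs a reliable gene and one read in one sample", {
  groups <- make_groups()
  exon_counts <- make_count_matrix(list(
    e_zero = rep(0, 6),
    e_one = c(1, 0, 0, 0, 0, 0),
    e_lowgene = rep(40, 6)), groups)
  rownames(exon_counts) <- c("gA.E1", "gA.E2", "gB.E1")
  gene_map <- setNames(c("gA", "gA", "gB"), rownames(exon_counts))
  # gA reaches 50 via e_one? gA total per sample = e_zero + e_one
  gene_counts <- sum_gene_counts(exon_counts, gene_map)
  rel <- filter_reliable(gene_counts, 50)   # gB max 40 -> unreliable
  expect_false("gB" %in% rel)
  retained <- filter_exons(exon_counts, gene_map, reliable_genes = c("gA"))
  expect_false("e_zero" %in% retained)       # no reads anywhere
  expect_true("gA.E2" %in% retained)         # 1 read in one sample is enough
  expect_false("gB.E1" %in% retained)        # gene unreliable, exon counts moot
  expect_error(filter_exons(exon_counts, gene_map["gA.E1"], "gA"), "unknown gene")
})

test_that("splicing index matches the exon/gene RPKM quotient by hand", {
  # g1: equal-length exons with counts 30 and 90 -> gene count 120 >= 50
  fx <- splicing_fixture(list(c(30, 30, 30, 30, 30, 30),
                              c(90, 90, 90, 90, 90, 90),
                              c(200, 200, 200, 200, 200, 200)))
  si <- splicing_index(fx$exon_ab, fx$gene_ab, fx$gene_counts, fx$gene_map)
  expect_equal(unname(si["g1.E1", ]), rep(0.5, 6))
  expect_equal(unname(si["g1.E2", ]), rep(1.5, 6))
  # single-exon gene: exon length = gene length, SI = 1 everywhere
  expect_equal(unname(si["g2.E1", ]), rep(1, 6))
})

test_that("SI is NA for samples whose gene count is below 50", {
  fx <- splicing_fixture(list(c(24, 30, 30, 30, 30, 30),
                              c(25, 90, 90, 90, 90, 90),
                              rep(200, 6)))
  # mut_1 gene count = 49 < 50 -> NA for that sample's exons only
  si <- splicing_index(fx$exon_ab, fx$gene_ab, fx$gene_counts, fx$gene_map)
  expect_true(all(is.na(si[c("g1.E1", "g1.E2"), "mut_1"])))
  expect_false(anyNA(si[, -1]))
  sp <- exon_anova_tukey(si, fx$groups)
  g1 <- sp[sp$gene_id == "g1", ]
  expect_true(all(is.na(g1$p)))
  expect_true(all(is.na(g1$significant)))
  g2 <- sp[sp$gene_id == "g2", ]
  expect_false(anyNA(g2$p))
})

test_that("length-weighted SI sums to one per sample for clean disjoint genes", {
  ds <- small_sim(seed = 21)
  gc2 <- sum_gene_counts(ds$exon_counts, ds$gene_map)
  lib <- library_sizes(gc2)
  rel <- filter_reliable(gc2, 50)
  glen <- gene_lengths(ds$models)
  elen <- exon_lengths(ds$models)
  gene_ab <- apply_replacement(gc2[rel, ], glen, lib, 10)
  retained <- filter_exons(ds$exon_counts, ds$gene_map, rel)
  exon_ab <- apply_replacement(ds$exon_counts[retained, ], elen, lib, 1)
  si <- splicing_index(exon_ab, gene_ab, gc2[rel, ], ds$gene_map)
  gmap <- attr(si, "gene_map")
  checked <- 0L
  for (g in head(rel, 60)) {
    exons_all <- names(ds$gene_map)[ds$gene_map == g]
    exons <- rownames(si)[gmap == g]
    if (!setequal(exons_all, exons)) next      # a filtered exon breaks the sum
    w <- elen[exons] / glen[g]
    for (s in colnames(si)) {
      if (anyNA(si[exons, s])) next
      if (any(exon_ab$flag[exons, s] == "floored") ||
          any(gene_ab$flag[g, s] == "floored")) next
      expect_equal(sum(si[exons, s] * w), 1, tolerance = 1e-10)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50)
})

test_that("SI is invariant to library size before flooring", {
  # doubling every count in one sample leaves SI unchanged where nothing
  # is floored: both RPKM values scale by the same factor
  fx <- splicing_fixture(list(rep(300, 6), rep(900, 6), rep(2000, 6)))
  si1 <- splicing_index(fx$exon_ab, fx$gene_ab, fx$gene_counts, fx$gene_map)
  scaled <- splicing_fixture(list(c(600, rep(300, 5)),
                                  c(1800, rep(900, 5)),
                                  c(4000, rep(2000, 5))))
  si2 <- splicing_index(scaled$exon_ab, scaled$gene_ab, scaled$gene_counts,
                        scaled$gene_map)
  expect_equal(si1, si2, tolerance = 1e-12)
})

test_that("exon ANOVA: identical groups give F=0 p=1; Tukey p equals ANOVA p", {
  fx <- splicing_fixture(list(rep(300, 6), rep(900, 6), rep(2000, 6)))
  si <- splicing_index(fx$exon_ab, fx$gene_ab, fx$gene_counts, fx$gene_map)
  sp <- exon_anova_tukey(si, fx$groups)
  expect_equal(sp$F, rep(0, 3))
  expect_equal(sp$p, rep(1, 3))
  expect_equal(sp$significant, rep(FALSE, 3))

  # randomized SI values: two-group Tukey adjusted p == ANOVA p, and both
  # match the aov/TukeyHSD reference implementation
  set.seed(5)
  si_rand <- matrix(runif(30, 0.2, 2), 5,
                    dimnames = list(paste0("g", 1:5, ".E1"), names(fx$groups)))
  attr(si_rand, "gene_map") <- setNames(paste0("g", 1:5), rownames(si_rand))
  sp2 <- exon_anova_tukey(si_rand, fx$groups)
  # exact identity in theory; ptukey's quadrature is good to ~1e-6
  expect_equal(sp2$tukey_p, sp2$p, tolerance = 1e-5)
  for (i in 1:5) {
    df <- data.frame(y = si_rand[i, ], g = factor(fx$groups))
    fit <- aov(y ~ g, df)
    tk <- TukeyHSD(fit)$g
    expect_equal(sp2$p[i], summary(fit)[[1]][["Pr(>F)"]][1], tolerance = 1e-9)
    expect_equal(sp2$tukey_p[i], unname(tk[1, "p adj"]), tolerance = 1e-9)
    expect_equal(abs(sp2$tukey_diff[i]), abs(unname(tk[1, "diff"])),
                 tolerance = 1e-12)
  }
})

test_that("gene summary ranks by minimum exon p with the exon-count restriction", {
  records <- data.frame(
    exon_id = c(paste0("big.E", 1:10), paste0("small.E", 1:3), "na.E1"),
    gene_id = c(rep("big", 10), rep("small", 3), "na"),
    F = 1, p = c(seq(0.001, 0.9, length.out = 10), 0.0001, 0.5, 0.6, NA),
    tukey_diff = 0, tukey_p = 1,
    significant = c(seq(0.001, 0.9, length.out = 10) < 0.05,
                    c(TRUE, FALSE, FALSE), NA),
    stringsAsFactors = FALSE)
  s <- splicing_gene_summary(records, min_exons = 10)
  expect_equal(s$n_exons[s$gene_id == "big"], 10L)
  expect_true(s$ranked[s$gene_id == "big"])
  expect_false(s$ranked[s$gene_id == "small"])   # < 10 exons
  expect_false(s$ranked[s$gene_id == "na"])
  expect_equal(s$min_p[s$gene_id == "small"], 0.0001)
  expect_true(is.na(s$min_p[s$gene_id == "na"]))
})
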