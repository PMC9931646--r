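# shared fixture: helper building a minimal hand-positioned locus
mini_locus <- function(tss_list = list(100000L), strands = "+",
                       enh_mids = c(99000L, 104000L),
                       activity = NULL, n_cond = 1L,
                       contacts = distance_contact_model(5000)) {
  n <- length(enh_mids)
  regions <- data.frame(chrom = "chr1", start = enh_mids - 250L,
                        end = enh_mids + 250L,
                        region_id = sprintf("E%d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (is.null(activity))
    activity <- matrix(seq_len(n * n_cond), n, n_cond)
  genes <- data.frame(gene_id = sprintf("G%d", seq_along(tss_list)),
                      chrom = "chr1", strand = strands,
                      stringsAsFactors = FALSE)
  genes$tss <- tss_list
  list(enhancers = enhancer_set(regions, activity), genes = genes,
       contacts = contacts)
}

test_that("window membership uses midpoints and the union over anchor TSSs", {
  loc <- mini_locus(tss_list = list(c(100000L, 300000L)),
                    enh_mids = c(104999L, 105001L, 296000L))
  g <- loc$genes[1, , drop = FALSE]
  # window 10 kb total -> +/- 5 kb around each TSS
  r_all <- enhancers_in_window(g, loc$enhancers, window = 10000, use_all_tss = TRUE)
  expect_setequal(r_all$region_id, c("E1", "E3"))  # E2 at 5001 bp: out
  r_5p <- enhancers_in_window(g, loc$enhancers, window = 10000, use_all_tss = FALSE)
  expect_equal(r_5p$region_id, "E1")               # E3 only via second TSS

  e3 <- loc$enhancers$regions[3, , drop = FALSE]
  gw <- genes_in_window(e3, loc$genes, window = 10000)
  expect_equal(gw$gene_id, "G1")
  expect_equal(nrow(genes_in_window(e3, loc$genes, window = 2000)), 0L)
})

test_that("adapted activity apportions by relative contact and is scale invariant", {
  expect_equal(adapted_activity(5, 3, 3), 5)               # single gene
  expect_equal(adapted_activity(2, 1, c(1, 3)), 0.5)
  expect_equal(adapted_activity(2, 3, c(1, 3)), 1.5)
  expect_equal(adapted_activity(2, 10 * 3, 10 * c(1, 3)),
               adapted_activity(2, 3, c(1, 3)))            # contact scaling
  expect_warning(z <- adapted_activity(2, 0, c(0, 0)),
                 class = "gabc_zero_denominator")
  expect_equal(z, 0)
})

test_that("forced score examples hold and per-gene scores sum to one", {
  # equal contacts, activities (2, 3) -> ABC scores (0.4, 0.6)
  cm <- contact_map("chr1", 5000, bin_i = c(19L, 21L), bin_j = c(20L, 20L),
                    value = c(4, 4), pseudocount = 0)
  loc <- mini_locus(tss_list = list(102500L), enh_mids = c(97500L, 107500L),
                    activity = matrix(c(2, 3), 2, 1), contacts = cm)
  cfg <- scoring_config(window = 50000, use_adapted_activity = FALSE,
                        use_all_tss = FALSE)
  sc <- score_gene(loc$genes[1, ], loc$enhancers, loc$genes, loc$contacts, cfg)
  expect_equal(sc$score, c(0.4, 0.6))
  expect_equal(sum(sc$score), 1, tolerance = 1e-9)

  # a single candidate with positive activity * contact always scores 1
  loc1 <- mini_locus(enh_mids = 99000L, activity = matrix(7, 1, 1))
  sc1 <- score_gene(loc1$genes[1, ], loc1$enhancers, loc1$genes,
                    loc1$contacts, scoring_config(window = 1e5))
  expect_equal(sc1$score, 1)
})

test_that("single-TSS genes make gABC collapse to the adapted score, and a lone gene to plain ABC", {
  loc <- make_toy_locus(3, n_genes = 1, n_tss_per_gene = 1, n_enhancers = 5)
  cfg5 <- scoring_config(window = 1e6, use_adapted_activity = TRUE,
                         use_all_tss = TRUE)
  cfg4 <- scoring_config(window = 1e6, use_adapted_activity = TRUE,
                         use_all_tss = FALSE)
  cfg1 <- scoring_config(window = 1e6, use_adapted_activity = FALSE,
                         use_all_tss = FALSE)
  g <- loc$genes[1, , drop = FALSE]
  s5 <- score_gene(g, loc$enhancers, loc$genes, loc$contacts, cfg5)
  s4 <- score_gene(g, loc$enhancers, loc$genes, loc$contacts, cfg4)
  s1 <- score_gene(g, loc$enhancers, loc$genes, loc$contacts, cfg1)
  expect_identical(s5$score, s4$score)   # sum over one TSS degenerates
  expect_identical(s5$score, s1$score)   # one gene in window: ratio is 1
})

test_that("production scores match the brute-force equation oracle on seeded loci", {
  for (seed in 1:12) {
    loc <- make_toy_locus(seed, n_genes = sample(2:4, 1),
                          n_tss_per_gene = sample(1:3, 1),
                          n_enhancers = sample(4:10, 1), n_conditions = 2)
    window <- 1e6
    for (mode in c("abc", "adapted", "gabc")) {
      cfg <- scoring_config(window = window,
                            use_adapted_activity = mode != "abc",
                            use_all_tss = mode == "gabc")
      for (gi in seq_len(nrow(loc$genes))) {
        want <- oracle_gene_scores(gi, loc, window, mode, condition = 1)
        got <- score_gene(loc$genes[gi, , drop = FALSE], loc$enhancers,
                          loc$genes, loc$contacts, cfg)
        got1 <- got[got$condition == "ct1", ]
        expect_equal(setNames(got1$score, got1$region_id), want,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("raising one enhancer's activity raises its score and lowers the others'", {
  loc <- make_toy_locus(5, n_genes = 2, n_enhancers = 6, n_conditions = 1)
  cfg <- scoring_config(window = 1e6)
  base <- score_all(loc$enhancers, loc$genes, loc$contacts, cfg)
  act2 <- loc$enhancers$activity
  act2["E3", ] <- act2["E3", ] * 3
  bumped <- score_all(enhancer_set(loc$enhancers$regions, act2),
                      loc$genes, loc$contacts, cfg)
  for (gid in loc$genes$gene_id) {
    b <- base[base$gene_id == gid & base$condition == "ct1", ]
    u <- bumped[bumped$gene_id == gid & bumped$condition == "ct1", ]
    e3 <- b$region_id == "E3"
    expect_true(all(u$score_gABC[e3] > b$score_gABC[e3]))
    expect_true(all(u$score_gABC[!e3] < b$score_gABC[!e3]))
  }
})

test_that("adapted activity never exceeds raw activity; equality iff one target gene", {
  loc <- make_toy_locus(9, n_genes = 3, n_enhancers = 8)
  sc <- score_all(loc$enhancers, loc$genes, loc$contacts,
                  scoring_config(window = 1e6))
  ok <- !is.na(sc$A_rg)
  expect_true(all(sc$A_rg[ok] <= sc$A_r[ok] + 1e-12))
  # every enhancer here sees all 3 genes in a 1 Mb window -> strict
  expect_true(all(sc$A_rg[ok & sc$A_r > 0] < sc$A_r[ok & sc$A_r > 0]))

  solo <- make_toy_locus(9, n_genes = 1, n_enhancers = 4)
  s1 <- score_all(solo$enhancers, solo$genes, solo$contacts,
                  scoring_config(window = 1e6))
  expect_equal(s1$A_rg, s1$A_r)
})

test_that("scaling the whole contact map (pseudocount included) leaves scores unchanged", {
  loc <- make_toy_locus(13, n_genes = 3, n_enhancers = 6)
  cm <- loc$contacts
  t <- methods::as(cm$mat, "TsparseMatrix")
  scaled <- contact_map(cm$chrom, cm$resolution, t@i, t@j, t@x * 10,
                        pseudocount = cm$pseudocount * 10)
  cfg <- scoring_config(window = 1e6)
  a <- score_all(loc$enhancers, loc$genes, loc$contacts, cfg)
  b <- score_all(loc$enhancers, loc$genes, scaled, cfg)
  expect_equal(a$score_gABC, b$score_gABC, tolerance = 1e-12)
  expect_equal(a$score_ABC, b$score_ABC, tolerance = 1e-12)
})

test_that("interaction calling is inclusive at the cutoff and keeps many-to-many links", {
  sc <- data.frame(region_id = c("E1", "E2", "E1"), gene_id = c("G1", "G1", "G2"),
                   condition = "ct1", score = c(0.4, 0.6, 0.02))
  expect_equal(nrow(call_interactions(sc, 0.5)), 1L)
  expect_equal(nrow(call_interactions(sc, 0.02)), 3L)    # exact tie kept
  expect_equal(nrow(call_interactions(sc, 0)), 3L)
  called <- call_interactions(sc, 0.02)
  expect_equal(sum(called$region_id == "E1"), 2L)        # E1 keeps 2 genes
})

test_that("multi-condition batching reproduces independent per-condition runs exactly", {
  loc <- make_toy_locus(21, n_genes = 3, n_enhancers = 7, n_conditions = 3)
  cfg <- scoring_config(window = 1e6)
  multi <- score_all(loc$enhancers, loc$genes, loc$contacts, cfg)
  for (cond in colnames(loc$enhancers$activity)) {
    single <- score_all(
      enhancer_set(loc$enhancers$regions,
                   loc$enhancers$activity[, cond, drop = FALSE]),
      loc$genes, loc$contacts, cfg)
    m <- multi[multi$condition == cond, ]
    rownames(m) <- NULL
    expect_identical(m, single)
  }
  # permuting condition columns permutes output, values unchanged
  perm <- score_all(enhancer_set(loc$enhancers$regions,
                                 loc$enhancers$activity[, c(3, 1, 2)]),
                    loc$genes, loc$contacts, cfg)
  for (cond in colnames(loc$enhancers$activity)) {
    a <- multi[multi$condition == cond, ]; rownames(a) <- NULL
    b <- perm[perm$condition == cond, ]; rownames(b) <- NULL
    expect_identical(a, b)
  }
})

test_that("all-zero activity columns score zero with a structured warning", {
  loc <- mini_locus(enh_mids = c(99000L, 104000L),
                    activity = matrix(0, 2, 1))
  expect_warning(
    sc <- score_gene(loc$genes[1, ], loc$enhancers, loc$genes, loc$contacts,
                     scoring_config(window = 1e5)),
    class = "gabc_degenerate_gene")
  expect_equal(sc$score, c(0, 0))
})
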