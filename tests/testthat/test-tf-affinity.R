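test_that("background composition skips non-ACGT and floors absent bases", {
  bg <- background_composition("AACC")
  expect_equal(sum(bg), 1)
  expect_equal(unname(bg["A"]), unname(bg["C"]))
  expect_true(all(bg[c("G", "T")] > 0))          # floored, not zero
  expect_true(bg["A"] > 0.49)

  expect_equal(unname(background_composition("ACGT")), rep(0.25, 4))
  bg2 <- background_composition("AANN")
  expect_gt(unname(bg2["A"]), 0.99)
  expect_error(background_composition("NNNN"), class = "gabc_invalid_input")
})

test_that("PFM-to-energy conversion zeroes the consensus and matches the closed formula", {
  uni <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  pfm <- motif_pfm("flat", matrix(10, 3, 4))
  em <- pfm_to_energy(pfm, uni)
  expect_equal(unname(em$energy), matrix(0, 3, 4))  # no preference, no energy

  counts <- rbind(c(20, 2, 2, 0), c(0, 24, 0, 0), c(6, 6, 6, 6))
  pfm2 <- motif_pfm("toy3", counts)
  prm <- trap_params()
  em2 <- pfm_to_energy(pfm2, uni, prm)
  # hand evaluation: regularized counts c+1, E = ln((cmax/cb)*(bg/bg*)) / lambda
  reg <- counts + 1
  for (p in 1:3) {
    cmax <- max(reg[p, ])
    want <- pmax(log((cmax / reg[p, ]) * (0.25 / 0.25)) / 0.7, 0)
    expect_equal(unname(em2$energy[p, ]), unname(want), tolerance = 1e-12)
    expect_equal(unname(em2$energy[p, which.max(reg[p, ])]), 0)  # consensus at zero
  }
  expect_equal(em2$R0, exp(0.584 * 3 - 5.66))
})

test_that("skewed backgrounds keep consensus energy zero and others non-negative", {
  bg <- c(A = 0.7, C = 0.1, G = 0.1, T = 0.1)
  pfm <- motif_pfm("skew", rbind(c(1, 30, 1, 1), c(30, 1, 1, 1)))
  em <- pfm_to_energy(pfm, bg)
  expect_true(all(em$energy >= 0))
  expect_equal(unname(em$energy[1, "C"]), 0)
  expect_equal(unname(em$energy[2, "A"]), 0)
})

test_that("zero-energy affinity has the closed form n * R0 / (1 + R0)", {
  W <- 10
  pfm <- motif_pfm("flat10", matrix(5, W, 4))
  em <- pfm_to_energy(pfm, c(A = .25, C = .25, G = .25, T = .25))
  set.seed(4)
  L <- 63
  seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  n_sites <- 2 * (L - W + 1)
  R0 <- exp(0.584 * W - 5.66)
  expect_equal(trap_region_affinity(em, seq), n_sites * R0 / (1 + R0))
  expect_equal(trap_region_affinity(em, "ACGTACGT"), 0)   # shorter than motif
})

test_that("affinities match the per-site brute-force oracle, strands and Ns included", {
  for (seed in 1:6) {
    fx <- make_motif_fixture(seed, W = 6, n_planted_sites = 2,
                             sequence_length = 80)
    bg <- background_composition(fx$sequences)
    em <- pfm_to_energy(fx$pfm, bg)
    for (s in fx$sequences)
      expect_equal(trap_region_affinity(em, s), oracle_trap_affinity(em, s),
                   tolerance = 1e-12)
    # ambiguous bases take the worst energy but do not invalidate the site
    with_n <- sub("^(...)", "N\\1N", fx$sequences[["background"]])
    with_n <- substr(with_n, 1, 80)
    expect_equal(trap_region_affinity(em, with_n),
                 oracle_trap_affinity(em, with_n), tolerance = 1e-12)
  }
})

test_that("planted consensus sites raise affinity over matched background", {
  wins <- vapply(1:40, function(seed) {
    fx <- make_motif_fixture(seed, W = 8, n_planted_sites = 3,
                             sequence_length = 300)
    bg <- background_composition(fx$sequences)
    em <- pfm_to_energy(fx$pfm, bg)
    trap_region_affinity(em, fx$sequences[["planted"]]) >
      trap_region_affinity(em, fx$sequences[["background"]])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("affinity grows under concatenation and scales linearly in summaries", {
  fx <- make_motif_fixture(2, W = 6, sequence_length = 60)
  em <- pfm_to_energy(fx$pfm, background_composition(fx$sequences))
  a <- fx$sequences[["planted"]]; b <- fx$sequences[["background"]]
  ab <- paste0(a, b)
  expect_gte(trap_region_affinity(em, ab), trap_region_affinity(em, a))
  expect_gte(trap_region_affinity(em, ab), trap_region_affinity(em, b))
})

test_that("length normalization leaves only R0 and site-count differences for flat motifs", {
  uni <- c(A = .25, C = .25, G = .25, T = .25)
  seq <- paste(rep("ACGT", 20), collapse = "")
  L <- nchar(seq)
  for (W in c(4, 9)) {
    em <- pfm_to_energy(motif_pfm(paste0("flat", W), matrix(3, W, 4)), uni)
    R0 <- exp(0.584 * W - 5.66)
    af <- trap_region_affinity(em, seq)
    expect_equal(af / W, 2 * (L - W + 1) * (R0 / (1 + R0)) / W)
  }
})

test_that("gene-level summarization matches the brute-force oracle in all modes", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 3
    regions <- data.frame(
      region_id = sprintf("R%d", 1:n),
      A_r = runif(n, 1, 10),
      A_rg = runif(n, 0.1, 3),
      C_rg = runif(n, 0.5, 6),
      distance = c(0, 5000, sample(3000:40000, 1)),
      length = sample(300:900, n),
      stringsAsFactors = FALSE
    )
    aff <- matrix(runif(n * 2, 0, 4), n, 2,
                  dimnames = list(regions$region_id, c("TFa", "TFb")))
    widths <- c(TFa = 8, TFb = 11)
    c_max <- 7.5
    for (mode in c("window", "gabc", "abc")) {
      got <- summarize_gene_tf(regions, aff, widths, mode = mode,
                               c_max = c_max)
      want <- oracle_summarize(regions, aff, widths, mode, c_max = c_max)
      expect_equal(unlist(got[, names(want)]), want, tolerance = 1e-12)
      # linearity: scaling one TF's affinities scales its summary
      aff2 <- aff; aff2[, "TFa"] <- aff2[, "TFa"] * 3
      got2 <- summarize_gene_tf(regions, aff2, widths, mode = mode,
                                c_max = c_max)
      expect_equal(got2$TFa, 3 * got$TFa, tolerance = 1e-12)
      expect_equal(got2$TFb, got$TFb)
    }
  }
})

test_that("the distance decay equals exp(-1) one decay length from the TSS", {
  regions <- data.frame(region_id = c("R1", "R2"), A_r = c(1, 1),
                        A_rg = c(1, 1), C_rg = c(1, 1),
                        distance = c(0, 5000), length = c(500, 500),
                        stringsAsFactors = FALSE)
  aff <- matrix(1, 2, 1, dimnames = list(regions$region_id, "TF"))
  out1 <- summarize_gene_tf(regions[1, ], aff, c(TF = 1), mode = "window")
  out2 <- summarize_gene_tf(regions[2, ], aff, c(TF = 1), mode = "window")
  expect_equal(out1$TF, 1)            # e^0
  expect_equal(out2$TF, exp(-1))      # d = d0 = 5000 bp
})

test_that("proximal regions are summarized identically in abc and gabc modes", {
  regions <- data.frame(region_id = c("R1", "R2"), A_r = c(2, 3),
                        A_rg = c(0.5, 1), C_rg = c(1, 2),
                        distance = c(1000, 2500), length = c(400, 600),
                        stringsAsFactors = FALSE)
  aff <- matrix(c(1, 2), 2, 1, dimnames = list(regions$region_id, "TF"))
  g <- summarize_gene_tf(regions, aff, c(TF = 5), mode = "gabc")
  a <- summarize_gene_tf(regions, aff, c(TF = 5), mode = "abc", c_max = 4)
  expect_identical(g$TF, a$TF)
})

test_that("gene features report count, mean distance, mean length; empty set gives missing", {
  regions <- data.frame(region_id = c("a", "b"), distance = c(1000, 3000),
                        length = c(500, 1500))
  f <- gene_features(regions)
  expect_equal(f, list(n_regions = 2L, mean_tss_distance = 2000,
                       mean_region_length = 1000))
  f1 <- gene_features(regions[1, ])
  expect_equal(f1$mean_tss_distance, 1000)
  f0 <- gene_features(regions[0, ])
  expect_equal(f0$n_regions, 0L)
  expect_true(is.na(f0$mean_tss_distance) && is.na(f0$mean_region_length))
})

test_that("end-to-end gene x TF matrices are computed for every condition", {
  loc <- make_toy_locus(17, n_genes = 3, n_enhancers = 6, n_conditions = 2)
  cfg <- scoring_config(window = 1e6)
  scored <- score_all(loc$enhancers, loc$genes, loc$contacts, cfg)
  pfms <- list(TOY = motif_pfm("TOY", rbind(c(21, 1, 1, 1), c(1, 1, 1, 21),
                                            c(1, 1, 21, 1), c(21, 1, 1, 1))))
  mats <- gene_tf_matrix(scored, loc$enhancers, loc$genes, loc$genome, pfms,
                         mode = "gabc", config = cfg)
  expect_named(mats, c("ct1", "ct2"))
  for (m in mats) {
    expect_equal(m$gene_id, loc$genes$gene_id)
    expect_true(all(m$TOY >= 0))
    expect_true(all(m$n_regions >= 0))
  }
  # abc mode without any contact fails only when C_max is unusable
  mats_abc <- gene_tf_matrix(scored, loc$enhancers, loc$genes, loc$genome,
                             pfms, mode = "abc", config = cfg)
  expect_named(mats_abc, c("ct1", "ct2"))
})
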