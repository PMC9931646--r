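#' Scoring configuration
#'
#' Bundles the tunable parameters of ABC/gABC scoring.
#'
#' The ABC score of enhancer r for gene g is the activity-contact product
#' relative to all candidate enhancers of the gene,
#' `ABC(r,g) = A_r C_rg / sum_i A_i C_ig`.  The generalized score (gABC)
#' additionally (i) replaces `A_r` by a gene-specific activity
#' `A_rg = A_r * C_rg / sum_j C_rj` apportioned over all genes j in the
#' window around r, and (ii) sums numerator and denominator over every
#' annotated TSS of the gene.
#'
#' @param window total window span in bp around a TSS; an enhancer is a
#'   candidate when its midpoint lies within `window/2` of a TSS
#'   (default 5 Mb).
#' @param cutoff interaction-calling threshold on the score, inclusive
#'   (default 0.02).
#' @param use_adapted_activity apportion enhancer activity among candidate
#'   target genes by relative contact (default TRUE).
#' @param use_all_tss anchor windows on, and sum over, all annotated TSSs
#'   rather than the 5'-most one (default TRUE).
#' @param tss_proximal_bp distance below which a region counts as
#'   TSS-proximal in affinity summarization (default 2500).
#' @param decay_d0 length scale of the exponential distance decay used in
#'   affinity summarization (default 5000 bp).
#' @return list of class `"ScoringConfig"`.
#' @export
scoring_config <- function(window = 5e6, cutoff = 0.02,
                           use_adapted_activity = TRUE, use_all_tss = TRUE,
                           tss_proximal_bp = 2500, decay_d0 = 5000) {
  if (window <= 0) stop_gabc("window must be > 0", "gabc_invalid_input")
  if (cutoff < 0 || cutoff > 1) stop_gabc("cutoff must be in [0,1]", "gabc_invalid_input")
  if (tss_proximal_bp < 0) stop_gabc("tss_proximal_bp must be >= 0", "gabc_invalid_input")
  if (decay_d0 <= 0) stop_gabc("decay_d0 must be > 0", "gabc_invalid_input")
  structure(list(window = window, cutoff = cutoff,
                 use_adapted_activity = use_adapted_activity,
                 use_all_tss = use_all_tss,
                 tss_proximal_bp = tss_proximal_bp, decay_d0 = decay_d0),
            class = "ScoringConfig")
}

#' Candidate enhancers of a gene
#'
#' Enhancers whose midpoint lies within `window/2` of any anchor TSS of the
#' gene (union over all annotated TSSs when `use_all_tss`, else the
#' 5'-most TSS), restricted to the gene's chromosome and ordered by
#' coordinate.
#'
#' @param gene one-row slice of a gene table (see [read_gene_annotation()]).
#' @param enhancers an `EnhancerSet` or region data.frame.
#' @param window total window span in bp.
#' @param use_all_tss anchor on all TSSs (default TRUE).
#' @return region data.frame of the candidates.
#' @export
enhancers_in_window <- function(gene, enhancers, window, use_all_tss = TRUE) {
  regions <- if (inherits(enhancers, "EnhancerSet")) enhancers$regions else enhancers
  idx <- candidate_indices(gene, regions, window, use_all_tss)
  regions[idx, , drop = FALSE]
}

# Indices (into regions) of a gene's candidates, ordered by start coordinate.
candidate_indices <- function(gene, regions, window, use_all_tss) {
  anchor <- tss_anchor(gene, use_all_tss)
  on_chr <- which(regions$chrom == gene$chrom)
  if (length(on_chr) == 0L) return(integer())
  mids <- region_midpoints(regions[on_chr, , drop = FALSE])
  keep <- nearest_distance(mids, anchor) <= window / 2
  sel <- on_chr[keep]
  sel[order(regions$start[sel])]
}

#' Genes in the window around an enhancer
#'
#' Genes with at least one annotated TSS within `window/2` of the enhancer
#' midpoint — the candidate target set over which the gene-specific
#' activity is apportioned.
#'
#' @param enhancer one-row region data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param genes gene table.
#' @param window total window span in bp.
#' @return subset of `genes`.
#' @export
genes_in_window <- function(enhancer, genes, window) {
  mid <- floor((enhancer$start + enhancer$end) / 2)
  keep <- vapply(seq_len(nrow(genes)), function(i) {
    genes$chrom[i] == enhancer$chrom &&
      min(abs(genes$tss[[i]] - mid)) <= window / 2
  }, logical(1))
  genes[keep, , drop = FALSE]
}

#' Gene-specific (adapted) enhancer activity
#'
#' Apportions an enhancer's activity to one target according to the
#' target's share of the enhancer's total contacts:
#' `A_rg = A_r * C(r, target) / sum_j C(r, gene_j)`, where the sum runs
#' over one representative contact per candidate target gene (each gene's
#' TSS nearest to the enhancer).  With a positive pseudocount the
#' denominator is always positive; if it is exactly zero the adapted
#' activity is 0 and a warning is raised.
#'
#' @param a_r enhancer activity.
#' @param c_target contact frequency between the enhancer and the scored
#'   TSS of the target gene.
#' @param c_genes contact frequencies between the enhancer and each
#'   candidate target gene (target included).
#' @return adapted activity `A_rg` (<= `a_r`).
#' @export
adapted_activity <- function(a_r, c_target, c_genes) {
  den <- sum(c_genes)
  if (den == 0) {
    warn_gabc("zero contact denominator; adapted activity set to 0",
              "gabc_zero_denominator")
    return(0)
  }
  a_r * (c_target / den)
}

# Per-enhancer denominator of the gene-specific activity:
# D_r = sum over genes j with a TSS in window of C(r, nearest TSS of j).
# `mids` are enhancer midpoints on `chrom`; returns a vector along `mids`.
adapted_denominator <- function(mids, chrom, genes, contacts, window) {
  den <- numeric(length(mids))
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    tss <- genes$tss[[i]]
    near <- vapply(mids, function(m) tss[which.min(abs(tss - m))], numeric(1))
    inwin <- abs(near - mids) <= window / 2
    if (!any(inwin)) next
    cv <- contact_between(contacts, mids[inwin], near[inwin])
    den[inwin] <- den[inwin] + cv
  }
  den
}

# Contact-dependent score weights of one gene's candidates.  The score of
# candidate r in condition c is then  A[r,c] * w[r] / sum_i A[i,c] * w[i].
#   plain ABC:  w = C(r, anchor TSS)
#   adapted:    w = sum_t (C(r,t)/D_r) * C(r,t)  over the scored TSS set
# The contact ratio is formed before multiplying so that a single-gene,
# single-TSS locus reduces to plain ABC bit-for-bit.
gene_weights <- function(gene, regions, contacts, config, denom = NULL,
                         cand = NULL) {
  if (is.null(cand))
    cand <- candidate_indices(gene, regions, config$window, config$use_all_tss)
  n <- length(cand)
  tss_all <- gene$tss[[1]]
  scored_tss <- if (config$use_all_tss) tss_all else
    tss_five_prime(tss_all, gene$strand)
  if (n == 0L) {
    return(list(cand = integer(), w = numeric(), c_rg = numeric(),
                a_ratio = numeric(), distance = numeric()))
  }
  mids <- region_midpoints(regions[cand, , drop = FALSE])
  # contact to every scored TSS: n x n_tss
  C <- matrix(0, nrow = n, ncol = length(scored_tss))
  for (k in seq_along(scored_tss))
    C[, k] <- contact_between(contacts, mids, scored_tss[k])
  dist <- nearest_distance(mids, tss_all)
  near_tss <- vapply(mids, function(m) tss_all[which.min(abs(tss_all - m))],
                     numeric(1))
  c_near <- contact_between(contacts, mids, near_tss)
  if (config$use_adapted_activity) {
    if (is.null(denom))
      stop_gabc("adapted activity requires per-enhancer contact denominators",
                "gabc_invalid_input")
    ratio <- C / denom            # recycles denom down rows
    w <- rowSums(ratio * C)
    a_ratio <- ifelse(denom > 0, c_near / denom, 0)
  } else {
    w <- rowSums(C)
    a_ratio <- rep(NA_real_, n)
  }
  list(cand = cand, w = w, c_rg = c_near, a_ratio = a_ratio, distance = dist)
}

# Turn weights + an activity matrix into score columns (one per condition).
weights_to_scores <- function(w, act) {
  num <- act * w                       # recycles w down rows
  den <- colSums(num)
  zero <- den == 0
  if (any(zero) && length(w) > 0)
    warn_gabc("all-zero activity-contact products for a gene/condition; scores set to 0",
              "gabc_degenerate_gene")
  den[zero] <- 1
  sweep(num, 2L, den, "/")
}

#' Score all candidate enhancers of one gene
#'
#' Computes, for every candidate enhancer of the gene and every activity
#' condition, the ABC-type score selected by `config`:
#' plain ABC (`use_adapted_activity = FALSE`, `use_all_tss = FALSE`),
#' the adapted-activity score, or the full gABC score summing over all
#' annotated TSSs.  Per gene and condition the scores sum to 1 whenever any
#' candidate has a positive activity-contact product.
#'
#' @param gene one-row slice of the gene table.
#' @param enhancers an `EnhancerSet`.
#' @param genes full gene table (needed to apportion enhancer activity
#'   among all candidate target genes).
#' @param contacts a `"ContactMap"` or `"DistanceContactModel"`.
#' @param config a [scoring_config()].
#' @return data.frame with one row per (candidate, condition):
#'   `region_id`, `gene_id`, `condition`, `A_r`, `A_rg`, `C_rg`, `score`,
#'   `distance` (midpoint to nearest TSS).
#' @export
score_gene <- function(gene, enhancers, genes, contacts, config = scoring_config()) {
  regions <- enhancers$regions
  cand <- candidate_indices(gene, regions, config$window, config$use_all_tss)
  denom <- NULL
  if (config$use_adapted_activity) {
    mids <- region_midpoints(regions[cand, , drop = FALSE])
    denom <- adapted_denominator(mids, gene$chrom, genes, contacts,
                                 config$window)
  }
  gw <- gene_weights(gene, regions, contacts, config, denom = denom,
                     cand = cand)
  n <- length(gw$cand)
  conds <- colnames(enhancers$activity)
  if (n == 0L) {
    return(data.frame(region_id = character(), gene_id = character(),
                      condition = character(), A_r = numeric(),
                      A_rg = numeric(), C_rg = numeric(), score = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  act <- enhancers$activity[gw$cand, , drop = FALSE]
  scores <- weights_to_scores(gw$w, act)
  a_rg <- if (config$use_adapted_activity) act * gw$a_ratio else
    matrix(NA_real_, n, length(conds))
  data.frame(
    region_id = rep(regions$region_id[gw$cand], times = length(conds)),
    gene_id = gene$gene_id,
    condition = rep(conds, each = n),
    A_r = as.vector(act),
    A_rg = as.vector(a_rg),
    C_rg = rep(gw$c_rg, times = length(conds)),
    score = as.vector(scores),
    distance = rep(gw$distance, times = length(conds)),
    stringsAsFactors = FALSE
  )
}

#' Score every enhancer-gene pair, batched over conditions
#'
#' Runs ABC and gABC scoring for all genes across every activity column in
#' one pass.  All contact lookups, candidate-window computations and
#' per-enhancer contact denominators are performed once and reused across
#' conditions and across the two scores, so results are identical to
#' scoring each condition separately.  The plain ABC score anchors the
#' candidate window on the 5'-most TSS; the gABC score anchors on (and sums
#' over) all annotated TSSs.  Rows are the union of the two candidate sets;
#' a score is `NA` for enhancers outside the corresponding window.
#'
#' @param enhancers an `EnhancerSet`.
#' @param genes gene table.
#' @param contacts a `"ContactMap"` or `"DistanceContactModel"`.
#' @param config a [scoring_config()]; `use_adapted_activity`/`use_all_tss`
#'   flags are ignored here (both scores are emitted).
#' @param gene_universe gene table over which enhancer activity is
#'   apportioned (defaults to `genes`; set when scoring a subset of genes
#'   so the adapted-activity denominators still cover every candidate
#'   target gene).
#' @return data.frame with columns `region_id`, `gene_id`, `condition`,
#'   `A_r`, `A_rg`, `C_rg`, `score_ABC`, `score_gABC`, `distance`, ordered
#'   by gene, coordinate, condition.
#' @export
score_all <- function(enhancers, genes, contacts, config = scoring_config(),
                      gene_universe = genes) {
  regions <- enhancers$regions
  conds <- colnames(enhancers$activity)
  cfg_abc <- config
  cfg_abc$use_adapted_activity <- FALSE
  cfg_abc$use_all_tss <- FALSE
  cfg_gabc <- config
  cfg_gabc$use_adapted_activity <- TRUE
  cfg_gabc$use_all_tss <- TRUE

  # per-enhancer contact denominator, shared by all genes and conditions
  mids_all <- region_midpoints(regions)
  denom_by_chr <- lapply(split(seq_len(nrow(regions)), regions$chrom),
                         function(ix) {
    setNames(adapted_denominator(mids_all[ix], regions$chrom[ix][1L],
                                 gene_universe, contacts, config$window), NULL)
  })

  out <- vector("list", nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, , drop = FALSE]
    cand_g <- candidate_indices(gene, regions, config$window, TRUE)
    cand_a <- candidate_indices(gene, regions, config$window, FALSE)
    chr_ix <- which(regions$chrom == gene$chrom)
    den_g <- denom_by_chr[[gene$chrom]][match(cand_g, chr_ix)]
    gw_g <- gene_weights(gene, regions, contacts, cfg_gabc,
                         denom = den_g, cand = cand_g)
    gw_a <- gene_weights(gene, regions, contacts, cfg_abc, cand = cand_a)
    all_cand <- sort(union(gw_g$cand, gw_a$cand))
    n <- length(all_cand)
    if (n == 0L) next
    act <- enhancers$activity[all_cand, , drop = FALSE]
    sc_g <- matrix(NA_real_, n, length(conds))
    sc_a <- matrix(NA_real_, n, length(conds))
    if (length(gw_g$cand))
      sc_g[match(gw_g$cand, all_cand), ] <-
        weights_to_scores(gw_g$w, enhancers$activity[gw_g$cand, , drop = FALSE])
    if (length(gw_a$cand))
      sc_a[match(gw_a$cand, all_cand), ] <-
        weights_to_scores(gw_a$w, enhancers$activity[gw_a$cand, , drop = FALSE])
    c_rg <- a_ratio <- dist <- rep(NA_real_, n)
    gmap <- match(gw_g$cand, all_cand)
    c_rg[gmap] <- gw_g$c_rg
    a_ratio[gmap] <- gw_g$a_ratio
    dist[gmap] <- gw_g$distance
    amap <- match(gw_a$cand, all_cand)
    c_rg[amap[is.na(c_rg[amap])]] <- gw_a$c_rg[is.na(c_rg[amap])]
    dist[amap[is.na(dist[amap])]] <- gw_a$distance[is.na(dist[amap])]
    out[[gi]] <- data.frame(
      region_id = rep(regions$region_id[all_cand], times = length(conds)),
      gene_id = gene$gene_id,
      condition = rep(conds, each = n),
      A_r = as.vector(act),
      A_rg = as.vector(act * a_ratio),
      C_rg = rep(c_rg, times = length(conds)),
      score_ABC = as.vector(sc_a),
      score_gABC = as.vector(sc_g),
      distance = rep(dist, times = length(conds)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(region_id = character(), gene_id = character(),
                      condition = character(), A_r = numeric(),
                      A_rg = numeric(), C_rg = numeric(),
                      score_ABC = numeric(), score_gABC = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Call interactions above a score cutoff
#'
#' Keeps rows with `score >= cutoff` (inclusive).  Many-to-many links are
#' preserved: a gene may keep several enhancers and an enhancer several
#' genes.
#'
#' @param scored data.frame from [score_gene()] or [score_all()].
#' @param cutoff inclusive threshold (default 0.02).
#' @param score_column column to threshold (default `"score_gABC"` if
#'   present, else `"score"`).
#' @return the filtered data.frame.
#' @export
call_interactions <- function(scored, cutoff = 0.02, score_column = NULL) {
  if (is.null(score_column))
    score_column <- if ("score_gABC" %in% names(scored)) "score_gABC" else "score"
  s <- scored[[score_column]]
  scored[!is.na(s) & s >= cutoff, , drop = FALSE]
}

#' Write an interaction table
#'
#' Tab-separated export of a scored interaction table; a `.gz` suffix
#' triggers gzip compression.
#'
#' @param scored data.frame from [score_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(scored, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(scored, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
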