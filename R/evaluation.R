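#' Precision-recall curve and AUPRC
#'
#' Precision and recall at every distinct score threshold (descending),
#' with tied scores grouped into a single threshold.  The area under the
#' curve is the step-wise sum of precision times recall increment — the
#' convention matching average precision, chosen over trapezoidal
#' interpolation for reproducibility.
#'
#' @param score numeric prediction scores.
#' @param label logical (or 0/1) vector, `TRUE` = positive.
#' @return list with `curve` (data.frame `threshold`, `precision`,
#'   `recall`) and `auprc`.
#' @export
pr_curve_auprc <- function(score, label) {
  label <- as.logical(label)
  if (!any(label)) stop_gabc("no positive labels", "gabc_invalid_input")
  if (all(label)) stop_gabc("no negative labels", "gabc_invalid_input")
  if (any(!is.finite(score))) stop_gabc("non-finite score", "gabc_invalid_input")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- label[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  n_seen <- grp_end
  precision <- tp / n_seen
  recall <- tp / sum(label)
  auprc <- sum(precision * diff(c(0, recall)))
  list(curve = data.frame(threshold = s[grp_end], precision = precision,
                          recall = recall),
       auprc = auprc)
}

#' ROC AUC by the rank statistic
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted one half (the Mann-Whitney construction).
#'
#' @inheritParams pr_curve_auprc
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  if (!any(label) || all(label))
    stop_gabc("both classes required for ROC AUC", "gabc_invalid_input")
  r <- rank(score)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# placements: for each positive, the fraction of negatives it outranks
# (ties = 1/2), and symmetrically for negatives.
delong_placements <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  psi <- function(x, ys) mean((x > ys) + 0.5 * (x == ys))
  list(v10 = vapply(pos, psi, numeric(1), ys = neg),
       v01 = vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                    numeric(1)))
}

#' Paired comparison of two ROC AUCs
#'
#' Tests whether two score sets over the same labeled pairs differ in AUC,
#' using the covariance of placement values (DeLong construction) with a
#' two-sided normal reference.  A permutation alternative (randomly
#' swapping the two scores per observation) is available for very small
#' samples.
#'
#' @param score_a,score_b numeric scores over the identical observations.
#' @param label logical labels shared by both.
#' @param method `"delong"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list with `auc_a`, `auc_b`, `delta` (a minus b) and `p_value`.
#' @export
compare_roc_paired <- function(score_a, score_b, label,
                               method = c("delong", "permutation"),
                               n_perm = 2000) {
  method <- match.arg(method)
  label <- as.logical(label)
  if (length(score_a) != length(score_b) || length(score_a) != length(label))
    stop_gabc("paired comparison needs identical observation sets",
              "gabc_invalid_input")
  auc_a <- roc_auc(score_a, label)
  auc_b <- roc_auc(score_b, label)
  delta <- auc_a - auc_b
  if (method == "permutation") {
    perm <- replicate(n_perm, {
      flip <- runif(length(label)) < 0.5
      sa <- ifelse(flip, score_b, score_a)
      sb <- ifelse(flip, score_a, score_b)
      roc_auc(sa, label) - roc_auc(sb, label)
    })
    p <- (1 + sum(abs(perm) >= abs(delta))) / (1 + n_perm)
    return(list(auc_a = auc_a, auc_b = auc_b, delta = delta, p_value = p))
  }
  pa <- delong_placements(score_a, label)
  pb <- delong_placements(score_b, label)
  n_pos <- sum(label); n_neg <- sum(!label)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  p <- if (v <= 0) {
    if (delta == 0) 1 else 0      # degenerate variance: identical or trivially split
  } else {
    2 * pnorm(-abs(delta) / sqrt(v))
  }
  list(auc_a = auc_a, auc_b = auc_b, delta = delta, p_value = p)
}

#' Rank correlation between scores and effect sizes
#'
#' Spearman correlation (ties mid-ranked) between interaction scores and
#' measured effect sizes, e.g. the absolute expression change in a
#' perturbation screen.
#'
#' @param score numeric scores.
#' @param effect_size numeric effect sizes, same length.
#' @return the correlation coefficient, or `NA` when either input is
#'   constant.
#' @export
score_effect_correlation <- function(score, effect_size) {
  keep <- is.finite(score) & is.finite(effect_size)
  if (sum(keep) < 3L)
    stop_gabc("need >= 3 pairs with effect sizes", "gabc_invalid_input")
  s <- score[keep]; e <- effect_size[keep]
  if (sd(s) == 0 || sd(e) == 0) {
    warn_gabc("constant input; rank correlation undefined", "gabc_degenerate")
    return(NA_real_)
  }
  cor(s, e, method = "spearman")
}

#' Recall of eQTL-supported pairs among the top-k interactions
#'
#' The denominator is the set of (enhancer, gene) pairs supported by
#' eQTLs: the enhancer contains an eQTL variant (`start <= pos < end`)
#' and the eQTL's target gene has a TSS within `window/2` of the enhancer
#' midpoint.  The numerator is the subset of those pairs found among the
#' `k` highest-scored interactions (ties at rank k are all included).
#'
#' @param scored interaction table with `region_id`, `gene_id` and a score
#'   column.
#' @param eqtls data.frame with `chrom`, `pos`, `gene_id`.
#' @param enhancers `EnhancerSet` or region data.frame.
#' @param genes gene table.
#' @param window total scoring window span in bp.
#' @param k number of top interactions to consider.
#' @param score_column score used for ranking (default `"score_gABC"` if
#'   present, else `"score"`).
#' @return list with `recall`, `n_supported`, `n_found`; `recall` is `NA`
#'   with a warning when no pair is supported.
#' @export
eqtl_recall_at_k <- function(scored, eqtls, enhancers, genes, window, k,
                             score_column = NULL) {
  if (k < 1) stop_gabc("k must be >= 1", "gabc_invalid_input")
  regions <- if (inherits(enhancers, "EnhancerSet")) enhancers$regions else enhancers
  if (is.null(score_column))
    score_column <- if ("score_gABC" %in% names(scored)) "score_gABC" else "score"
  supported <- character()
  for (i in seq_len(nrow(eqtls))) {
    gi <- match(eqtls$gene_id[i], genes$gene_id)
    if (is.na(gi)) next
    hit <- which(regions$chrom == eqtls$chrom[i] &
                 regions$start <= eqtls$pos[i] & eqtls$pos[i] < regions$end)
    if (length(hit) == 0L) next
    tss <- genes$tss[[gi]]
    mids <- region_midpoints(regions[hit, , drop = FALSE])
    ok <- genes$chrom[gi] == eqtls$chrom[i] &
      nearest_distance(mids, tss) <= window / 2
    supported <- c(supported,
                   paste(regions$region_id[hit[ok]], eqtls$gene_id[i], sep = "\r"))
  }
  supported <- unique(supported)
  if (length(supported) == 0L) {
    warn_gabc("no eQTL-supported pairs in the window", "gabc_empty_denominator")
    return(list(recall = NA_real_, n_supported = 0L, n_found = 0L))
  }
  s <- scored[[score_column]]
  keep <- !is.na(s)
  sc <- scored[keep, , drop = FALSE]
  s <- s[keep]
  if (k < length(s)) {
    thr <- sort(s, decreasing = TRUE)[k]
    top <- sc[s >= thr, , drop = FALSE]       # ties at rank k included
  } else {
    top <- sc
  }
  top_pairs <- unique(paste(top$region_id, top$gene_id, sep = "\r"))
  n_found <- sum(supported %in% top_pairs)
  list(recall = n_found / length(supported),
       n_supported = length(supported), n_found = n_found)
}

#' Select cell-type-specific genes
#'
#' A gene is specific to a condition when its expression there is both
#' non-negligible (`TPM >= tpm_min`) and an outlier across conditions
#' (z-score `>= z_min`, using the population standard deviation over
#' conditions).  Genes with zero variance are never specific.
#'
#' @param expression numeric matrix, rows = genes (rownames = gene ids),
#'   columns = conditions (TPM).
#' @param z_min z-score threshold (default 2).
#' @param tpm_min expression floor (default 0.5).
#' @return named list (per condition) of gene-id character vectors.
#' @export
select_cs_genes <- function(expression, z_min = 2, tpm_min = 0.5) {
  if (ncol(expression) < 3L)
    stop_gabc("need >= 3 conditions for a meaningful z-score",
              "gabc_invalid_input")
  mu <- rowMeans(expression)
  n <- ncol(expression)
  sdev <- sqrt(rowSums((expression - mu)^2) / n)   # population sd
  out <- lapply(colnames(expression), function(cond) {
    x <- expression[, cond]
    z <- ifelse(sdev > 0, (x - mu) / sdev, -Inf)
    rownames(expression)[x >= tpm_min & z >= z_min]
  })
  setNames(out, colnames(expression))
}

#' Interaction sharing across conditions
#'
#' For every non-empty subset of conditions, the number of
#' (region, gene) pairs called in exactly that subset — the tabulation
#' behind an upset plot — plus each condition's fraction of interactions
#' shared with all conditions and fraction unique to it.
#'
#' @param interaction_sets named list of data.frames (or of
#'   `"region\rgene"` keys) of called interactions per condition.
#' @return list with `subsets` (data.frame `subset`, `count`) and
#'   `per_condition` (data.frame `condition`, `n`, `frac_shared_all`,
#'   `frac_unique`).
#' @export
interaction_overlap_summary <- function(interaction_sets) {
  if (length(interaction_sets) < 2L)
    stop_gabc("need >= 2 conditions", "gabc_invalid_input")
  keys <- lapply(interaction_sets, function(x) {
    if (is.data.frame(x)) unique(paste(x$region_id, x$gene_id, sep = "\r"))
    else unique(as.character(x))
  })
  conds <- names(keys)
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, conds))
  sig <- apply(member, 1L, function(m) paste(conds[m], collapse = "&"))
  tab <- table(sig)
  subsets <- data.frame(subset = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  all_sig <- paste(conds, collapse = "&")
  per <- do.call(rbind, lapply(conds, function(cond) {
    mine <- member[, cond]
    n <- sum(mine)
    data.frame(condition = cond, n = n,
               frac_shared_all = if (n) sum(mine & sig == all_sig) / n else NA_real_,
               frac_unique = if (n) sum(mine & sig == cond) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(subsets = subsets, per_condition = per)
}
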