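# Independent brute-force oracles used to check the production code.
# Everything here is a literal transliteration of the scoring equations
# with explicit loops; deliberately no code is shared with R/.

oracle_contact <- function(contacts, a, b) {
  if (inherits(contacts, "DistanceContactModel")) {
    1 / max(abs(a - b), contacts$min_distance)
  } else {
    res <- contacts$resolution
    bi <- min(floor(a / res), floor(b / res)) + 1
    bj <- max(floor(a / res), floor(b / res)) + 1
    v <- if (bj <= nrow(contacts$mat)) as.numeric(contacts$mat[bi, bj]) else 0
    v + contacts$pseudocount
  }
}

oracle_5prime <- function(tss, strand) if (strand == "-") max(tss) else min(tss)

# candidate enhancer ids of a gene (midpoint within window/2 of anchor set)
oracle_candidates <- function(gene_i, locus, window, all_tss) {
  genes <- locus$genes
  regions <- locus$enhancers$regions
  anchors <- if (all_tss) genes$tss[[gene_i]] else
    oracle_5prime(genes$tss[[gene_i]], genes$strand[gene_i])
  keep <- c()
  for (r in seq_len(nrow(regions))) {
    if (regions$chrom[r] != genes$chrom[gene_i]) next
    mid <- floor((regions$start[r] + regions$end[r]) / 2)
    if (any(abs(mid - anchors) <= window / 2)) keep <- c(keep, r)
  }
  keep[order(regions$start[keep])]
}

# sum over genes j with a TSS within window/2 of mid of C(r, nearest TSS of j)
oracle_denominator <- function(mid, chrom, locus, window, contacts) {
  genes <- locus$genes
  den <- 0
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != chrom) next
    tss <- genes$tss[[j]]
    near <- tss[which.min(abs(tss - mid))]
    if (abs(near - mid) <= window / 2)
      den <- den + oracle_contact(contacts, mid, near)
  }
  den
}

# per-gene score vectors under "abc" (plain), "adapted" (gene-specific
# activity, single TSS) or "gabc" (adapted + all TSSs), one condition
oracle_gene_scores <- function(gene_i, locus, window, mode, condition = 1) {
  genes <- locus$genes
  regions <- locus$enhancers$regions
  act <- locus$enhancers$activity[, condition]
  contacts <- locus$contacts
  cand <- oracle_candidates(gene_i, locus, window, all_tss = (mode == "gabc"))
  if (length(cand) == 0) return(numeric())
  t5 <- oracle_5prime(genes$tss[[gene_i]], genes$strand[gene_i])
  tss_set <- if (mode == "gabc") genes$tss[[gene_i]] else t5
  nums <- numeric(length(cand))
  for (k in seq_along(cand)) {
    r <- cand[k]
    mid <- floor((regions$start[r] + regions$end[r]) / 2)
    if (mode == "abc") {
      nums[k] <- act[r] * oracle_contact(contacts, mid, t5)
    } else {
      D <- oracle_denominator(mid, regions$chrom[r], locus, window, contacts)
      s <- 0
      for (t in tss_set) {
        Ct <- oracle_contact(contacts, mid, t)
        Art <- act[r] * Ct / D              # gene-specific activity share
        s <- s + Art * Ct
      }
      nums[k] <- s
    }
  }
  den <- sum(nums)
  out <- if (den > 0) nums / den else rep(0, length(nums))
  names(out) <- regions$region_id[cand]
  out
}

# ---- TRAP oracles -------------------------------------------------------

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_site_energy <- function(em, word) {
  ch <- strsplit(word, "")[[1]]
  e <- 0
  for (p in seq_along(ch)) {
    b <- match(ch[p], c("A", "C", "G", "T"))
    e <- e + unname(if (is.na(b)) max(em$energy[p, ]) else em$energy[p, b])
  }
  e
}

oracle_trap_affinity <- function(em, seq) {
  W <- em$width
  L <- nchar(seq)
  if (L < W) return(0)
  total <- 0
  for (strand_seq in c(seq, oracle_revcomp(seq))) {
    for (i in 1:(nchar(strand_seq) - W + 1)) {
      e <- oracle_site_energy(em, substr(strand_seq, i, i + W - 1))
      x <- em$R0 * exp(-e)
      total <- total + x / (1 + x)
    }
  }
  total
}

# window/gabc/abc summarization by direct looping
oracle_summarize <- function(regions, aff, widths, mode, c_max = NULL,
                             d0 = 5000, prox = 2500) {
  tfs <- colnames(aff)
  out <- setNames(rep(0, length(tfs)), tfs)
  for (k in seq_len(nrow(regions))) {
    d <- regions$distance[k]
    m <- if (mode == "window") {
      regions$A_r[k] * exp(-d / d0)
    } else if (d <= prox) {
      regions$A_r[k] * exp(-d / d0)
    } else if (mode == "gabc") {
      regions$A_rg[k]
    } else {
      regions$A_r[k] * regions$C_rg[k] / c_max
    }
    for (tf in tfs)
      out[tf] <- out[tf] + aff[regions$region_id[k], tf] / widths[tf] * m
  }
  out
}

# ---- metric oracles -----------------------------------------------------

oracle_auprc <- function(score, label) {
  ths <- sort(unique(score), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (th in ths) {
    sel <- score >= th
    precision <- sum(label[sel]) / sum(sel)
    recall <- sum(label[sel]) / sum(label)
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

oracle_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# jackknife variance of an AUC difference over paired score sets
oracle_jackknife_var_delta <- function(sa, sb, label) {
  n <- length(label)
  d_full <- oracle_auc(sa, label) - oracle_auc(sb, label)
  d_i <- vapply(seq_len(n), function(i) {
    oracle_auc(sa[-i], label[-i]) - oracle_auc(sb[-i], label[-i])
  }, numeric(1))
  (n - 1) / n * sum((d_i - mean(d_i))^2)
}

oracle_recall_at_k <- function(scored, supported_keys, k, score_col) {
  s <- scored[[score_col]]
  keep <- !is.na(s)
  scored <- scored[keep, ]
  s <- s[keep]
  ord <- order(s, decreasing = TRUE)
  kk <- k
  if (k < length(s)) {                # extend through ties at rank k
    thr <- s[ord][k]
    kk <- sum(s >= thr)
  }
  top <- scored[ord[seq_len(min(kk, length(s)))], ]
  top_keys <- unique(paste(top$region_id, top$gene_id))
  sum(supported_keys %in% top_keys) / length(supported_keys)
}
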