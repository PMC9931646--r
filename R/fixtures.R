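#' Generate a seeded synthetic toy locus
#'
#' Builds a fully self-consistent miniature locus — gene models with
#' multiple TSSs, candidate enhancers with per-condition activities, a
#' binned contact map following an inverse-distance decay plus planted
#' "loops", and a random genome sequence with planted motif consensus
#' sites — so that every pipeline stage can be exercised without external
#' data.  All randomness is governed by `seed`; the same seed yields
#' byte-identical files.
#'
#' Contacts between two bins at distance `d` bp are
#' `round(K / max(d, resolution))` with `K = 5e5`, giving a contact of 100
#' at one-bin distance, decaying with the inverse of distance like a
#' fractal-globule expectation.  One planted loop joins the first enhancer
#' to the most distant gene with a contact of 250, well above the decay
#' background and far above the default pseudocount of `1e-6`.
#'
#' @param seed integer RNG seed.
#' @param n_genes,n_tss_per_gene,n_enhancers,n_conditions locus size
#'   (all >= 1).
#' @param resolution contact-map bin size in bp (default 5000).
#' @param chrom chromosome name (default `"chrS"`).
#' @param chrom_length chromosome length in bp; defaults to a span
#'   comfortably holding all elements.
#' @param pseudocount contact pseudocount (default 1e-6).
#' @param dir when non-NULL, the locus is also written to disk in this
#'   directory as `enhancers.bed`, `genes.gtf`, `activity.tsv`,
#'   `contacts.tsv` and `genome.fa`.
#' @return list of class `"ToyLocus"`: `enhancers` (`EnhancerSet`),
#'   `genes`, `contacts` (`ContactMap`), `genome` (`DNAStringSet`),
#'   `truth` (planted loop and motif metadata) and, when written, `paths`.
#' @export
make_toy_locus <- function(seed, n_genes = 3, n_tss_per_gene = 2,
                           n_enhancers = 6, n_conditions = 2,
                           resolution = 5000, chrom = "chrS",
                           chrom_length = NULL, pseudocount = 1e-6,
                           dir = NULL) {
  stopifnot(n_genes >= 1, n_tss_per_gene >= 1, n_enhancers >= 1,
            n_conditions >= 1)
  set.seed(seed)
  if (is.null(chrom_length))
    chrom_length <- max(60L, (n_genes + n_enhancers) * 8L) * resolution
  n_bins <- floor(chrom_length / resolution)
  usable <- seq(3L, n_bins - 4L)
  if (length(usable) < 2L * (n_genes + n_enhancers))
    stop_gabc("chromosome too short for requested element counts",
              "gabc_invalid_input")
  picks <- sample(usable, n_genes + n_enhancers)
  enh_bins <- sort(picks[seq_len(n_enhancers)])
  gene_bins <- sort(picks[n_enhancers + seq_len(n_genes)])

  # enhancers: random length, centred on their bin midpoints
  lens <- sample(seq(200L, 1000L, by = 2L), n_enhancers, replace = TRUE)
  mids <- enh_bins * resolution + resolution %/% 2L
  regions <- data.frame(chrom = chrom, start = as.integer(mids - lens %/% 2L),
                        end = as.integer(mids + lens %/% 2L),
                        region_id = sprintf("E%d", seq_len(n_enhancers)),
                        stringsAsFactors = FALSE)
  act <- round(matrix(rgamma(n_enhancers * n_conditions, shape = 2, rate = 0.2),
                      n_enhancers, n_conditions), 4)
  colnames(act) <- sprintf("ct%d", seq_len(n_conditions))
  enhancers <- enhancer_set(regions, act)

  # genes: first TSS inside the gene's bin, further TSSs shifted 3' so
  # that multi-TSS genes span more than one contact bin now and then
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss_list <- lapply(seq_len(n_genes), function(i) {
    base <- gene_bins[i] * resolution + sample.int(resolution, 1L) - 1L
    extra <- if (n_tss_per_gene > 1L)
      base + cumsum(sample(seq(800L, 2L * resolution), n_tss_per_gene - 1L,
                           replace = TRUE)) else integer()
    sort(unique(pmin(c(base, extra), chrom_length - resolution)))
  })
  genes <- data.frame(gene_id = sprintf("G%d", seq_len(n_genes)),
                      chrom = chrom, strand = strands,
                      stringsAsFactors = FALSE)
  genes$tss <- tss_list

  # contacts among all bins hosting enhancer midpoints or TSSs
  tss_bins <- unique(floor(unlist(tss_list) / resolution))
  bins <- sort(unique(c(enh_bins, tss_bins)))
  pairs <- expand.grid(i = bins, j = bins)
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  K <- 5e5
  d <- abs(pairs$j - pairs$i) * resolution
  val <- round(K / pmax(d, resolution))
  keep <- val > 0
  tri <- data.frame(i = pairs$i[keep], j = pairs$j[keep], value = val[keep])

  # planted loop: first enhancer <-> gene whose nearest TSS is furthest away
  loop_gene <- which.max(vapply(tss_list, function(t) min(abs(t - mids[1L])),
                                numeric(1)))
  loop_tss <- tss_list[[loop_gene]][which.min(abs(tss_list[[loop_gene]] - mids[1L]))]
  li <- min(enh_bins[1L], floor(loop_tss / resolution))
  lj <- max(enh_bins[1L], floor(loop_tss / resolution))
  hit <- tri$i == li & tri$j == lj
  if (any(hit)) tri$value[hit] <- tri$value[hit] + 250 else
    tri <- rbind(tri, data.frame(i = li, j = lj, value = 250))
  tri <- tri[order(tri$i, tri$j), , drop = FALSE]
  contacts <- contact_map(chrom, resolution, tri$i, tri$j, tri$value,
                          pseudocount = pseudocount)

  # genome with a fixed consensus planted at the centre of odd enhancers
  consensus <- "TGACGTCA"
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
  planted_at <- integer()
  for (i in seq(1L, n_enhancers, by = 2L)) {
    at <- mids[i] - nchar(consensus) %/% 2L            # 0-based start
    seq_chars[(at + 1L):(at + nchar(consensus))] <-
      strsplit(consensus, "")[[1L]]
    planted_at <- c(planted_at, at)
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- chrom

  out <- structure(list(
    enhancers = enhancers, genes = genes, contacts = contacts,
    genome = genome,
    truth = list(loop_region = regions$region_id[1L],
                 loop_gene = genes$gene_id[loop_gene],
                 consensus = consensus, planted_at = planted_at),
    params = list(seed = seed, resolution = resolution, chrom = chrom,
                  chrom_length = chrom_length, pseudocount = pseudocount,
                  decay_K = K)
  ), class = "ToyLocus")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      regions = file.path(dir, "enhancers.bed"),
      annotation = file.path(dir, "genes.gtf"),
      activity = file.path(dir, "activity.tsv"),
      contacts = file.path(dir, "contacts.tsv"),
      genome = file.path(dir, "genome.fa")
    )
    write_regions(regions, paths$regions)
    writeLines(toy_gtf_lines(genes, chrom_length), paths$annotation)
    writeLines(c(paste(c("region_id", colnames(act)), collapse = "\t"),
                 vapply(seq_len(n_enhancers), function(i) {
                   paste(c(regions$region_id[i], sprintf("%.4f", act[i, ])),
                         collapse = "\t")
                 }, character(1))), paths$activity)
    writeLines(sprintf("%d\t%d\t%d", tri$i * resolution, tri$j * resolution,
                       as.integer(tri$value)), paths$contacts)
    fa <- c(paste0(">", chrom),
            vapply(seq(1L, chrom_length, by = 70L), function(s) {
              paste(seq_chars[s:min(s + 69L, chrom_length)], collapse = "")
            }, character(1)))
    writeLines(fa, paths$genome)
    out$paths <- paths
  }
  out
}

# GTF transcript lines (1-based, inclusive) reproducing each TSS of each gene.
toy_gtf_lines <- function(genes, chrom_length) {
  unlist(lapply(seq_len(nrow(genes)), function(i) {
    tss <- genes$tss[[i]]
    strand <- genes$strand[i]
    vapply(seq_along(tss), function(k) {
      t1 <- tss[k] + 1L                       # 0-based TSS -> 1-based
      if (strand == "+") {
        s <- t1; e <- min(t1 + 1999L, chrom_length)
      } else {
        e <- t1; s <- max(t1 - 1999L, 1L)
      }
      sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.T%d\";",
              genes$chrom[i], s, e, strand, genes$gene_id[i],
              genes$gene_id[i], k)
    }, character(1))
  }))
}

#' Generate a labeled benchmark from a toy locus
#'
#' Samples positive and negative (enhancer, gene) pairs from the scored
#' interactions of a toy locus.  Positives are drawn with probability
#' increasing in the true gABC score (exponential weighting by the
#' standardized score times `signal_strength`); at `signal_strength = 0`
#' labels are independent of the scores, giving a null benchmark with
#' expected AUC 0.5.  An `effect_size` column mimics a perturbation
#' readout: proportional to the true score plus unit noise, attenuated at
#' low signal.
#'
#' @param seed integer RNG seed.
#' @param locus a `"ToyLocus"`.
#' @param n_positive,n_negative pair counts (feasible given the locus).
#' @param signal_strength >= 0; strength of the label-score association.
#' @param config [scoring_config()] used to score the locus.
#' @return data.frame `region_id`, `gene_id`, `score`, `label`,
#'   `effect_size`.
#' @export
make_labeled_benchmark <- function(seed, locus, n_positive = 5,
                                   n_negative = 10, signal_strength = 1,
                                   config = scoring_config()) {
  scored <- score_all(locus$enhancers, locus$genes, locus$contacts, config)
  scored <- scored[scored$condition == scored$condition[1L] &
                     !is.na(scored$score_gABC), , drop = FALSE]
  n <- nrow(scored)
  if (n_positive + n_negative > n)
    stop_gabc("locus too small for requested label counts",
              "gabc_invalid_input")
  set.seed(seed)
  s <- scored$score_gABC
  z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, n)
  wt <- exp(2 * signal_strength * z)
  pos <- sample.int(n, n_positive, prob = wt)
  rest <- setdiff(seq_len(n), pos)
  neg <- rest[sample.int(length(rest), n_negative)]
  sel <- c(pos, neg)
  data.frame(region_id = scored$region_id[sel],
             gene_id = scored$gene_id[sel],
             score = s[sel],
             label = rep(c(TRUE, FALSE), c(n_positive, n_negative)),
             effect_size = signal_strength * z[sel] + rnorm(length(sel)),
             stringsAsFactors = FALSE)
}

#' Generate a motif fixture with planted binding sites
#'
#' Draws a random consensus of width `W`, builds a sharply peaked PFM for
#' it, and emits two equal-length sequences: `"planted"`, carrying the
#' consensus at `n_planted_sites` known non-overlapping positions, and
#' `"background"`, plain random sequence.
#'
#' @param seed integer RNG seed.
#' @param W motif width (<= `sequence_length`).
#' @param n_planted_sites number of consensus insertions.
#' @param sequence_length length of each sequence.
#' @param dir when non-NULL, writes `motif.jaspar` and `sequences.fa`
#'   there.
#' @return list with `pfm` (`MotifPFM`), `consensus`, `positions`
#'   (0-based plant starts), `sequences` (named character vector) and,
#'   when written, `paths`.
#' @export
make_motif_fixture <- function(seed, W = 8, n_planted_sites = 3,
                               sequence_length = 400, dir = NULL) {
  if (W > sequence_length)
    stop_gabc("motif wider than sequence", "gabc_invalid_input")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  consensus <- sample(bases, W, replace = TRUE)
  counts <- matrix(1, W, 4L, dimnames = list(NULL, bases))
  counts[cbind(seq_len(W), match(consensus, bases))] <- 21
  pfm <- motif_pfm("TOY_TF", counts)
  background <- sample(bases, sequence_length, replace = TRUE)
  planted <- background
  positions <- integer()
  if (n_planted_sites > 0L) {
    slots <- seq(1L, sequence_length - W + 1L, by = 2L * W)
    if (length(slots) < n_planted_sites)
      stop_gabc("sequence too short for requested planted sites",
                "gabc_invalid_input")
    positions <- sort(slots[sample.int(length(slots), n_planted_sites)]) - 1L
    for (p in positions) planted[(p + 1L):(p + W)] <- consensus
  }
  sequences <- c(planted = paste(planted, collapse = ""),
                 background = paste(background, collapse = ""))
  out <- list(pfm = pfm, consensus = paste(consensus, collapse = ""),
              positions = positions, sequences = sequences)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(motif = file.path(dir, "motif.jaspar"),
                  fasta = file.path(dir, "sequences.fa"))
    writeLines(c(">TOY_TF TOY_TF",
                 vapply(seq_len(4L), function(b) {
                   sprintf("%s  [ %s ]", bases[b],
                           paste(format(counts[, b]), collapse = " "))
                 }, character(1))), paths$motif)
    writeLines(c(">planted", sequences[["planted"]],
                 ">background", sequences[["background"]]), paths$fasta)
    out$paths <- paths
  }
  out
}
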