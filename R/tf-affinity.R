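#' Average nucleotide composition of a region set
#'
#' Base frequencies of A, C, G, T over the concatenated sequences of all
#' candidate regulatory regions, used as the background model when
#' converting PFMs to energy matrices.  Non-ACGT characters are skipped.
#' Bases absent from the set are floored at `1e-4` before normalization so
#' that mismatch energies stay finite.
#'
#' @param sequences a `Biostrings::DNAStringSet` or character vector.
#' @return named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
background_composition <- function(sequences) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  counts <- colSums(Biostrings::alphabetFrequency(sequences)[, c("A", "C", "G", "T"),
                                                             drop = FALSE])
  if (sum(counts) == 0)
    stop_gabc("no usable A/C/G/T bases in region sequences", "gabc_invalid_input")
  freq <- counts / sum(counts)
  freq <- pmax(freq, 1e-4)
  freq / sum(freq)
}

#' TRAP model parameters
#'
#' Defaults of the biophysical occupancy model: energy scale
#' `lambda = 0.7`, equilibrium-constant factor `ln R0 = 0.584 * W - 5.66`
#' as a function of motif width `W`, and a PFM regularization pseudocount
#' of 1.
#'
#' @param lambda energy scale (> 0).
#' @param lnR0_slope,lnR0_intercept coefficients of `ln R0` in the motif
#'   width.
#' @param pseudocount added to every PFM count before conversion.
#' @return list of class `"TrapParams"`.
#' @export
trap_params <- function(lambda = 0.7, lnR0_slope = 0.584,
                        lnR0_intercept = -5.66, pseudocount = 1) {
  if (lambda <= 0) stop_gabc("lambda must be > 0", "gabc_invalid_input")
  structure(list(lambda = lambda, lnR0_slope = lnR0_slope,
                 lnR0_intercept = lnR0_intercept, pseudocount = pseudocount),
            class = "TrapParams")
}

#' Convert a PFM to a position-specific energy matrix
#'
#' Per motif position, the regularized count `c_b` of base `b` is turned
#' into a mismatch energy
#' `E(pos, b) = (1/lambda) * ln((c_max / c_b) * (bg_b / bg_b*))`,
#' where `c_max` is the position's maximal count, `b*` its base (the
#' consensus base, energy 0 by construction; ties resolved in A<C<G<T
#' order) and `bg` the background composition.  Energies are clamped at 0.
#' The equilibrium factor is `R0 = exp(lnR0_slope * W + lnR0_intercept)`.
#'
#' @param pfm a `"MotifPFM"`.
#' @param background named base frequencies from [background_composition()].
#' @param params a [trap_params()].
#' @return object of class `"EnergyMatrix"`: list with `tf_name`, `width`,
#'   `energy` (W x 4), `lambda`, `R0`.
#' @export
pfm_to_energy <- function(pfm, background, params = trap_params()) {
  counts <- pfm$counts + params$pseudocount
  if (any(rowSums(pfm$counts) <= 0))
    stop_gabc(sprintf("motif %s: all-zero PFM position", pfm$tf_name),
              "gabc_invalid_input")
  bg <- background[c("A", "C", "G", "T")]
  W <- nrow(counts)
  E <- matrix(0, W, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in seq_len(W)) {
    cmax <- max(counts[p, ])
    bstar <- which.max(counts[p, ])
    e <- log((cmax / counts[p, ]) * (bg / bg[bstar])) / params$lambda
    e[bstar] <- 0
    E[p, ] <- pmax(e, 0)
  }
  structure(list(tf_name = pfm$tf_name, width = W, energy = E,
                 lambda = params$lambda,
                 R0 = exp(params$lnR0_slope * W + params$lnR0_intercept)),
            class = "EnergyMatrix")
}

# site energies of all W-mers of `codes` (1..4 = ACGT, NA = other) under
# energy matrix E; non-ACGT bases get the position's worst (maximal) energy.
site_energies <- function(codes, E) {
  W <- nrow(E)
  L <- length(codes)
  n <- L - W + 1L
  if (n < 1L) return(numeric())
  worst <- apply(E, 1L, max)
  Eext <- cbind(E, worst)
  codes[is.na(codes)] <- 5L
  out <- numeric(n)
  for (k in seq_len(W))
    out <- out + Eext[k, codes[k:(k + n - 1L)]]
  out
}

#' TRAP binding affinity of a TF in one region
#'
#' Expected number of TF molecules bound in a sequence: the sum over all
#' W-mer sites on both strands of the occupancy
#' `R0 * exp(-E_i) / (1 + R0 * exp(-E_i))`, where `E_i` is the summed
#' mismatch energy of the site.  Low affinities are retained — no
#' threshold is applied.  Sequences shorter than the motif yield 0.
#'
#' @param em an `"EnergyMatrix"`.
#' @param sequence a single `DNAString`/character sequence.
#' @return non-negative affinity `af_r,tf`.
#' @export
trap_region_affinity <- function(em, sequence) {
  seq <- toupper(as.character(sequence))
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  if (length(codes) < em$width) return(0)
  # reverse strand = forward scan with reversed, complemented matrix
  E_rc <- em$energy[em$width:1L, c(4L, 3L, 2L, 1L), drop = FALSE]
  e <- c(site_energies(codes, em$energy), site_energies(codes, E_rc))
  x <- em$R0 * exp(-e)
  sum(x / (1 + x))
}

#' Region x TF affinity matrix
#'
#' @param energies list of `"EnergyMatrix"` objects (e.g. from mapping
#'   [pfm_to_energy()] over [read_pfms()] output).
#' @param sequences named character vector or `DNAStringSet` of region
#'   sequences.
#' @return numeric matrix, rows = regions, columns = TFs; attribute
#'   `motif_widths` carries each TF's motif length.
#' @export
trap_affinities <- function(energies, sequences) {
  seqs <- setNames(as.character(sequences), names(sequences))
  out <- vapply(energies, function(em) {
    vapply(seqs, function(s) trap_region_affinity(em, s), numeric(1))
  }, numeric(length(seqs)))
  out <- matrix(out, nrow = length(seqs),
                dimnames = list(names(seqs),
                                vapply(energies, `[[`, character(1), "tf_name")))
  attr(out, "motif_widths") <- vapply(energies, `[[`, numeric(1), "width")
  out
}

#' Summarize TF affinities for one gene
#'
#' Combines per-region affinities into a gene-level affinity
#' `af_g,tf = sum_r (af_r,tf / ml_tf) * m_r`, where `ml_tf` is the motif
#' length and the multiplier `m_r` depends on the region-to-gene
#' assignment regime:
#' \describe{
#'   \item{window}{`A_r * exp(-d_rg / d0)` for every candidate region in
#'     the window.}
#'   \item{gabc}{TSS-proximal regions (`d_rg <= 2500` bp) keep the decay
#'     multiplier; distal regions use the adapted activity `A_rg`.}
#'   \item{abc}{proximal regions as above; distal regions use
#'     `A_r * C_rg / C_max` with `C_max` the maximum contact over all
#'     region-gene pairs of the run.}
#' }
#' `d_rg` is the region midpoint to nearest-TSS distance and `d0 = 5000`
#' bp by default.
#'
#' @param regions data.frame of the regions assigned to the gene, with
#'   columns `region_id`, `A_r`, `distance`, `length`, and (for
#'   abc/gabc modes) `A_rg`, `C_rg`.
#' @param affinities region x TF affinity matrix (rows matching
#'   `regions$region_id`).
#' @param motif_widths named vector of motif lengths per TF.
#' @param mode `"window"`, `"abc"` or `"gabc"`.
#' @param config a [scoring_config()] (supplies `tss_proximal_bp`,
#'   `decay_d0`).
#' @param c_max maximum contact over all region-gene pairs (abc mode only).
#' @return one-row data.frame: `n_regions`, `mean_tss_distance`,
#'   `mean_region_length`, then one column per TF.
#' @export
summarize_gene_tf <- function(regions, affinities, motif_widths,
                              mode = c("gabc", "abc", "window"),
                              config = scoring_config(), c_max = NULL) {
  mode <- match.arg(mode)
  tfs <- colnames(affinities)
  n <- nrow(regions)
  feats <- data.frame(n_regions = n,
                      mean_tss_distance = if (n) mean(regions$distance) else NA_real_,
                      mean_region_length = if (n) mean(regions$length) else NA_real_)
  if (n == 0L) {
    af <- as.data.frame(as.list(setNames(rep(0, length(tfs)), tfs)),
                        check.names = FALSE)
    return(cbind(feats, af))
  }
  if (is.null(rownames(affinities)))
    stop_gabc("affinity matrix must carry region ids as rownames",
              "gabc_invalid_input")
  decay <- regions$A_r * exp(-regions$distance / config$decay_d0)
  prox <- regions$distance <= config$tss_proximal_bp
  m <- switch(mode,
    window = decay,
    gabc = ifelse(prox, decay, regions$A_rg),
    abc = {
      if (is.null(c_max) || c_max <= 0)
        stop_gabc("abc-mode summarization needs a positive C_max",
                  "gabc_invalid_input")
      ifelse(prox, decay, regions$A_r * regions$C_rg / c_max)
    })
  A <- affinities[match(regions$region_id, rownames(affinities)), , drop = FALSE]
  af <- colSums((A / rep(motif_widths[tfs], each = n)) * m)
  cbind(feats, as.data.frame(as.list(af), check.names = FALSE))
}

#' Auxiliary gene features
#'
#' Count, mean TSS distance and mean length of the regions assigned to a
#' gene; all three are themselves predictive of expression.
#'
#' @param regions assigned-region data.frame with `distance`, `length`.
#' @return list with `n_regions`, `mean_tss_distance`,
#'   `mean_region_length` (means `NA` when no region is assigned).
#' @export
gene_features <- function(regions) {
  n <- nrow(regions)
  list(n_regions = n,
       mean_tss_distance = if (n) mean(regions$distance) else NA_real_,
       mean_region_length = if (n) mean(regions$length) else NA_real_)
}

#' Gene x TF affinity matrices for every condition
#'
#' End-to-end TF-affinity stage: derives the background composition from
#' the candidate regions, converts PFMs to energy matrices, computes TRAP
#' affinities for every region, assigns regions to genes under the chosen
#' regime and summarizes per gene and condition.
#'
#' Region assignment: in `"window"` mode every candidate in the scoring
#' window; in `"abc"`/`"gabc"` mode the called interactions of the gene
#' (score at or above `config$cutoff`) plus all TSS-proximal regions
#' (`distance <= config$tss_proximal_bp`) regardless of score,
#' deduplicated.
#'
#' @param scored interaction table from [score_all()].
#' @param enhancers the scored `EnhancerSet`.
#' @param genes gene table.
#' @param genome a `DNAStringSet` keyed by chromosome (or path to a FASTA
#'   file).
#' @param pfms list of `"MotifPFM"` from [read_pfms()].
#' @param mode `"gabc"` (default), `"abc"` or `"window"`.
#' @param config a [scoring_config()].
#' @param params a [trap_params()].
#' @return named list (one element per condition) of data.frames with a
#'   `gene_id` column, the three feature columns and one affinity column
#'   per TF.
#' @export
gene_tf_matrix <- function(scored, enhancers, genes, genome, pfms,
                           mode = c("gabc", "abc", "window"),
                           config = scoring_config(),
                           params = trap_params()) {
  mode <- match.arg(mode)
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  regions <- enhancers$regions
  seqs <- region_sequences(regions, genome)
  bg <- background_composition(seqs)
  energies <- lapply(pfms, pfm_to_energy, background = bg, params = params)
  aff <- trap_affinities(energies, seqs)
  widths <- attr(aff, "motif_widths")
  names(widths) <- colnames(aff)
  score_col <- if (mode == "abc") "score_ABC" else "score_gABC"
  c_max <- if (mode == "abc") {
    cm <- suppressWarnings(max(scored$C_rg, na.rm = TRUE))
    if (!is.finite(cm)) 0 else cm
  } else NULL
  lens <- setNames(regions$end - regions$start, regions$region_id)
  conds <- unique(scored$condition)
  out <- lapply(conds, function(cond) {
    sc <- scored[scored$condition == cond, , drop = FALSE]
    rows <- lapply(seq_len(nrow(genes)), function(gi) {
      g <- genes[gi, , drop = FALSE]
      gsc <- sc[sc$gene_id == g$gene_id, , drop = FALSE]
      if (mode == "window") {
        keep <- !is.na(gsc$score_gABC)
      } else {
        s <- gsc[[score_col]]
        keep <- (!is.na(s) & s >= config$cutoff) |
          gsc$distance <= config$tss_proximal_bp
      }
      assigned <- gsc[keep & !duplicated(gsc$region_id), , drop = FALSE]
      assigned$length <- lens[assigned$region_id]
      rec <- summarize_gene_tf(assigned, aff, widths, mode = mode,
                               config = config, c_max = c_max)
      cbind(data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE), rec)
    })
    do.call(rbind, rows)
  })
  names(out) <- conds
  out
}

#' Extract region sequences from a genome
#'
#' @param regions region data.frame (0-based half-open coordinates).
#' @param genome `DNAStringSet` keyed by chromosome.
#' @return named character vector of sequences (names = region ids).
#' @export
region_sequences <- function(regions, genome) {
  out <- vapply(seq_len(nrow(regions)), function(i) {
    chr <- genome[[regions$chrom[i]]]
    as.character(Biostrings::subseq(chr, regions$start[i] + 1L, regions$end[i]))
  }, character(1))
  setNames(out, regions$region_id)
}

#' Write gene x TF matrices to tab-separated files
#'
#' One file per condition, named `gene_tf_<condition>.tsv` (`.gz` when
#' `gzip = TRUE`).
#'
#' @param mats named list from [gene_tf_matrix()].
#' @param dir output directory.
#' @param gzip compress output (default FALSE).
#' @return character vector of the written paths, invisibly.
#' @export
write_gene_tf_matrices <- function(mats, dir, gzip = FALSE) {
  paths <- vapply(names(mats), function(cond) {
    path <- file.path(dir, sprintf("gene_tf_%s.tsv%s", cond,
                                   if (gzip) ".gz" else ""))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    utils::write.table(mats[[cond]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    path
  }, character(1))
  invisible(paths)
}
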