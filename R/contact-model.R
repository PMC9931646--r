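#' Construct a binned contact map
#'
#' Stores normalized chromatin contact frequencies between genomic bins of
#' fixed `resolution` on one chromosome as a sparse upper-triangular
#' matrix.  Lookups are symmetric and every lookup adds `pseudocount`, so
#' that all candidate enhancer-gene pairs in a window contribute to
#' scoring even when no contact was measured.
#'
#' @param chrom chromosome name.
#' @param resolution bin size in bp (> 0).
#' @param bin_i,bin_j 0-based bin indices of the stored entries.
#' @param value non-negative contact frequencies.
#' @param pseudocount non-negative constant added to every lookup.
#'   Defaults to the inverse-distance contact estimate at a 1 Mb reference
#'   distance, `1e-6`.
#' @return object of class `"ContactMap"`.
#' @export
contact_map <- function(chrom, resolution, bin_i = integer(), bin_j = integer(),
                        value = numeric(), pseudocount = 1e-6) {
  if (resolution <= 0) stop_gabc("resolution must be > 0", "gabc_invalid_input")
  if (pseudocount < 0) stop_gabc("pseudocount must be >= 0", "gabc_invalid_input")
  if (any(value < 0)) stop_gabc("negative contact frequency", "gabc_invalid_input")
  ii <- pmin(bin_i, bin_j)
  jj <- pmax(bin_i, bin_j)
  n <- if (length(jj)) max(jj) + 1L else 1L
  # duplicates (after symmetrizing) are summed by sparseMatrix
  mat <- Matrix::sparseMatrix(i = ii + 1L, j = jj + 1L, x = value,
                              dims = c(n, n))
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 mat = mat, pseudocount = pseudocount),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %s, %g bp bins, %d stored entries, pseudocount %g\n",
              x$chrom, x$resolution, length(x$mat@x), x$pseudocount))
  invisible(x)
}

#' Read a contact map from sparse triplet text
#'
#' Each line holds `a b value` where `a`/`b` are bp positions (or pre-binned
#' indices with `positions = "bin"`) and `value` is an already-normalized
#' contact frequency.  Entries are symmetrized (stored with `i <= j`) and
#' duplicate pairs are summed.  A five-column variant
#' `chrom1 a chrom2 b value` is accepted; inter-chromosomal pairs are
#' skipped with a warning, since scoring windows never cross chromosomes.
#'
#' @param path path to the triplet file (whitespace-separated).
#' @param resolution bin size in bp.
#' @param chrom chromosome name of the map (required for the 3-column
#'   format; for the 5-column format rows on other chromosomes are dropped).
#' @param positions `"bp"` (positions, binned as `floor(pos/resolution)`)
#'   or `"bin"` (already bin indices).
#' @param pseudocount passed to [contact_map()].
#' @return a `"ContactMap"`.
#' @export
read_contact_triples <- function(path, resolution, chrom = "chr1",
                                 positions = c("bp", "bin"),
                                 pseudocount = 1e-6) {
  positions <- match.arg(positions)
  if (!file.exists(path)) stop_gabc(paste0("file not found: ", path), "gabc_io_error")
  tab <- if (file.size(path) == 0) NULL else
    data.table::fread(path, header = FALSE, data.table = FALSE)
  if (is.null(tab) || nrow(tab) == 0L)
    return(contact_map(chrom, resolution, pseudocount = pseudocount))
  if (ncol(tab) == 5L) {
    inter <- tab[[1L]] != tab[[3L]]
    if (any(inter))
      warn_gabc(sprintf("%d inter-chromosomal pair(s) skipped", sum(inter)),
                "gabc_interchromosomal")
    tab <- tab[!inter & tab[[1L]] == chrom, c(2L, 4L, 5L), drop = FALSE]
  } else if (ncol(tab) != 3L) {
    stop_gabc("contact triplets must have 3 or 5 columns", "gabc_parse_error")
  }
  a <- as.numeric(tab[[1L]]); b <- as.numeric(tab[[2L]]); v <- as.numeric(tab[[3L]])
  if (any(v < 0)) stop_gabc("negative contact frequency", "gabc_parse_error")
  if (positions == "bp") {
    a <- floor(a / resolution)
    b <- floor(b / resolution)
  }
  contact_map(chrom, resolution, as.integer(a), as.integer(b), v, pseudocount)
}

#' Look up contact frequency between two positions
#'
#' Maps each bp position to its bin (`floor(pos/resolution)`) and returns
#' the stored frequency plus the map's pseudocount; pairs without a stored
#' entry return the pseudocount alone.  Lookup is symmetric in its two
#' position arguments.
#'
#' @param map a `"ContactMap"`.
#' @param pos_a,pos_b bp positions (vectors are recycled to equal length).
#' @return numeric vector of contact frequencies (>= pseudocount).
#' @export
lookup_contact <- function(map, pos_a, pos_b) {
  if (any(pos_a < 0) || any(pos_b < 0))
    stop_gabc("negative genomic position", "gabc_invalid_input")
  ba <- floor(pos_a / map$resolution)
  bb <- floor(pos_b / map$resolution)
  ii <- pmin(ba, bb) + 1
  jj <- pmax(ba, bb) + 1
  n <- nrow(map$mat)
  val <- numeric(length(ii))
  inside <- jj <= n
  if (any(inside))
    val[inside] <- map$mat[cbind(ii[inside], jj[inside])]
  val + map$pseudocount
}

#' Distance-decay contact model
#'
#' Closed-form contact estimate `1 / max(d, min_distance)` as a function of
#' the linear enhancer-TSS distance `d`, following the fractal-globule
#' expectation that contact frequency decays roughly as the inverse of
#' genomic distance.  Used when no measured contact matrix is available.
#'
#' @param min_distance bp clamp below which the estimate saturates
#'   (default 5000, one typical Hi-C bin).
#' @return object of class `"DistanceContactModel"`.
#' @export
distance_contact_model <- function(min_distance = 5000) {
  if (min_distance <= 0) stop_gabc("min_distance must be > 0", "gabc_invalid_input")
  structure(list(min_distance = as.numeric(min_distance)),
            class = "DistanceContactModel")
}

#' Inverse-distance contact estimate
#'
#' @param model a `"DistanceContactModel"`.
#' @param d non-negative bp distance(s).
#' @return `1 / pmax(d, min_distance)`.
#' @export
distance_contact_estimate <- function(model, d) {
  if (any(d < 0)) stop_gabc("distance must be >= 0", "gabc_invalid_input")
  1 / pmax(d, model$min_distance)
}

#' Contact frequency between two genomic positions
#'
#' Generic dispatcher used by the scoring engine: a `"ContactMap"` performs
#' a binned symmetric lookup (pseudocount included), a
#' `"DistanceContactModel"` returns the inverse-distance estimate for
#' `|pos_a - pos_b|`.
#'
#' @param contacts a `"ContactMap"` or `"DistanceContactModel"`.
#' @param pos_a,pos_b bp positions.
#' @return numeric vector of contact frequencies.
#' @export
contact_between <- function(contacts, pos_a, pos_b) {
  UseMethod("contact_between")
}

#' @export
contact_between.ContactMap <- function(contacts, pos_a, pos_b) {
  lookup_contact(contacts, pos_a, pos_b)
}

#' @export
contact_between.DistanceContactModel <- function(contacts, pos_a, pos_b) {
  distance_contact_estimate(contacts, abs(pos_a - pos_b))
}

#' Average several contact maps entrywise
#'
#' Arithmetic mean over maps of identical chromosome and resolution,
#' treating entries missing from a map as 0 — the construction behind an
#' "average Hi-C" matrix shared across cell types.  The pseudocount of the
#' first map is retained.
#'
#' @param maps list of `"ContactMap"` objects.
#' @return a `"ContactMap"`.
#' @export
average_contact_maps <- function(maps) {
  if (length(maps) == 0L) stop_gabc("no maps given", "gabc_invalid_input")
  res <- unique(vapply(maps, function(m) m$resolution, numeric(1)))
  chr <- unique(vapply(maps, function(m) m$chrom, character(1)))
  if (length(res) > 1L) stop_gabc("resolution mismatch", "gabc_invalid_input")
  if (length(chr) > 1L) stop_gabc("chromosome mismatch", "gabc_invalid_input")
  trip <- lapply(maps, function(m) {
    t <- methods::as(m$mat, "TsparseMatrix")
    data.frame(i = t@i, j = t@j, x = t@x)
  })
  all <- do.call(rbind, trip)
  contact_map(chr, res, all$i, all$j, all$x / length(maps),
              pseudocount = maps[[1L]]$pseudocount)
}
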