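#' Read candidate regions from a BED file
#'
#' Parses a BED file (0-based, half-open coordinates) into a region table.
#' Lines starting with `#`, `track` or `browser` are skipped.  The fourth
#' column, when present, supplies the region identifier; otherwise the id
#' defaults to `"chrom:start-end"`.
#'
#' @param path path to a BED file with at least three tab-separated columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `region_id`,
#'   in file order.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_gabc(paste0("file not found: ", path), "gabc_io_error")
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      region_id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_one <- function(f, lineno) {
    if (length(f) < 3L)
      stop_gabc(sprintf("line %d: fewer than 3 columns", lineno), "gabc_parse_error")
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop_gabc(sprintf("line %d: non-integer coordinate", lineno), "gabc_parse_error")
    if (start < 0L || start >= end)
      stop_gabc(sprintf("line %d: invalid interval [%d, %d)", lineno, start, end),
                "gabc_parse_error")
    id <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else
      sprintf("%s:%d-%d", f[1L], start, end)
    list(chrom = f[1L], start = start, end = end, region_id = id)
  }
  parsed <- Map(parse_one, fields, idx)
  out <- data.frame(
    chrom = vapply(parsed, `[[`, character(1), "chrom"),
    start = vapply(parsed, `[[`, integer(1), "start"),
    end = vapply(parsed, `[[`, integer(1), "end"),
    region_id = vapply(parsed, `[[`, character(1), "region_id"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$region_id))
    stop_gabc("duplicate region ids in BED file", "gabc_parse_error")
  out
}

#' Write regions to a BED file
#'
#' Inverse of [read_regions()]: writing then re-reading reproduces
#' coordinates and ids exactly.
#'
#' @param regions region data.frame (`chrom`, `start`, `end`, `region_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                   regions$end, regions$region_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models with all annotated TSSs from a GTF file
#'
#' Builds one gene model per `gene_id` from the transcript records of a GTF
#' annotation.  The TSS of a transcript is its 5' end: the record start on
#' the `+` strand and the record end on the `-` strand, converted from
#' 1-based inclusive GTF coordinates to 0-based positions.  Exact duplicate
#' TSS positions are collapsed; distinct TSSs are all retained so that
#' scoring can sum over every annotated start site.
#'
#' @param path path to a GTF file.
#' @param feature GTF feature type carrying transcript extents
#'   (default `"transcript"`).
#' @return data.frame with columns `gene_id`, `chrom`, `strand` and a list
#'   column `tss` of sorted 0-based TSS positions.
#' @export
read_gene_annotation <- function(path, feature = "transcript") {
  if (!file.exists(path)) stop_gabc(paste0("file not found: ", path), "gabc_io_error")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == feature]
  if (length(gr) == 0L)
    stop_gabc(sprintf("no '%s' records in %s", feature, path), "gabc_parse_error")
  gid <- as.character(gr$gene_id)
  missing_gid <- is.na(gid) | !nzchar(gid)
  if (any(missing_gid)) {
    warn_gabc(sprintf("%d transcript record(s) without gene_id skipped",
                      sum(missing_gid)), "gabc_missing_gene_id")
    gr <- gr[!missing_gid]
    gid <- gid[!missing_gid]
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  # 1-based GTF -> 0-based: '+' TSS = start - 1; '-' TSS = end - 1.
  tss0 <- ifelse(strand == "-", GenomicRanges::end(gr) - 1L,
                 GenomicRanges::start(gr) - 1L)
  ord <- unique(gid)
  genes <- lapply(ord, function(g) {
    sel <- gid == g
    if (length(unique(chrom[sel])) > 1L)
      stop_gabc(sprintf("gene %s spans multiple chromosomes", g),
                "gabc_parse_error")
    list(gene_id = g, chrom = chrom[sel][1L], strand = strand[sel][1L],
         tss = sort(unique(tss0[sel])))
  })
  out <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  out$tss <- lapply(genes, `[[`, "tss")
  out
}

#' Load per-region activity values
#'
#' Reads a tab-separated activity table (first column: region id; remaining
#' columns: one activity value per condition, e.g. per cell-type cluster)
#' and attaches it to a region set.  With `normalize = "rpkm"` raw read
#' counts are converted to reads per kilobase per million:
#' `v * 1e9 / (L * T)` for a region of length `L` bp in a column with total
#' count `T`.
#'
#' @param path path to the activity table (header row names the conditions).
#' @param regions region data.frame from [read_regions()].
#' @param normalize `"none"` (values passed through) or `"rpkm"`.
#' @return an enhancer set: list with `regions` (the region table) and
#'   `activity` (numeric matrix, rows = regions, columns = conditions),
#'   class `"EnhancerSet"`.
#' @export
load_activity <- function(path, regions, normalize = c("none", "rpkm")) {
  normalize <- match.arg(normalize)
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE)
  if (ncol(tab) < 2L)
    stop_gabc("activity table needs an id column and >=1 value column",
              "gabc_parse_error")
  ids <- as.character(tab[[1L]])
  hit <- match(regions$region_id, ids)
  if (anyNA(hit)) {
    miss <- regions$region_id[is.na(hit)]
    stop_gabc(paste0("regions missing from activity table: ",
                     paste(head(miss, 10L), collapse = ", ")),
              "gabc_missing_region")
  }
  act <- as.matrix(tab[hit, -1L, drop = FALSE])
  storage.mode(act) <- "double"
  rownames(act) <- regions$region_id
  if (anyNA(act)) stop_gabc("non-numeric activity value", "gabc_parse_error")
  if (any(act < 0)) stop_gabc("negative activity value", "gabc_parse_error")
  if (normalize == "rpkm") {
    len <- regions$end - regions$start
    totals <- colSums(act)
    if (any(totals == 0))
      stop_gabc(paste0("zero library size in column(s): ",
                       paste(colnames(act)[totals == 0], collapse = ", ")),
                "gabc_zero_library")
    act <- sweep(act * 1e9 / len, 2L, totals, "/")
  }
  enhancer_set(regions, act)
}

#' Construct an enhancer set
#'
#' @param regions region data.frame (`chrom`, `start`, `end`, `region_id`).
#' @param activity non-negative numeric matrix, one row per region, one
#'   column per condition.
#' @return object of class `"EnhancerSet"`.
#' @export
enhancer_set <- function(regions, activity) {
  activity <- as.matrix(activity)
  if (nrow(activity) != nrow(regions))
    stop_gabc("activity rows must match regions", "gabc_invalid_input")
  if (any(activity < 0))
    stop_gabc("activity must be non-negative", "gabc_invalid_input")
  if (is.null(colnames(activity)))
    colnames(activity) <- paste0("condition_", seq_len(ncol(activity)))
  rownames(activity) <- regions$region_id
  structure(list(regions = regions, activity = activity),
            class = "EnhancerSet")
}

#' @export
print.EnhancerSet <- function(x, ...) {
  cat(sprintf("EnhancerSet: %d regions x %d condition(s) [%s]\n",
              nrow(x$regions), ncol(x$activity),
              paste(colnames(x$activity), collapse = ", ")))
  invisible(x)
}

#' Combine two activity assays by their geometric mean
#'
#' Per-region `sqrt(a1 * a2)`, the standard way of merging two activity
#' readouts (e.g. DNase-seq and H3K27ac ChIP-seq) into one enhancer
#' activity.  A zero in either assay yields zero.
#'
#' @param a1,a2 non-negative numeric vectors (or matrices) over the same
#'   regions in the same order; names/dimnames must agree when present.
#' @return the element-wise geometric mean, same shape as the inputs.
#' @export
combine_activity_assays <- function(a1, a2) {
  if (length(a1) != length(a2))
    stop_gabc("activity assays cover different region sets", "gabc_invalid_input")
  n1 <- if (is.matrix(a1)) rownames(a1) else names(a1)
  n2 <- if (is.matrix(a2)) rownames(a2) else names(a2)
  if (!is.null(n1) && !is.null(n2) && !identical(n1, n2))
    stop_gabc("activity assays cover different region sets", "gabc_invalid_input")
  if (any(a1 < 0) || any(a2 < 0))
    stop_gabc("activity must be non-negative", "gabc_invalid_input")
  sqrt(a1 * a2)
}

#' Remove enhancers overlapping exclusion regions
#'
#' Drops every enhancer that overlaps (by at least 1 bp, half-open
#' semantics) any interval of an exclusion list, e.g. signal-artifact
#' blacklist regions that accumulate anomalous read counts.
#'
#' @param enhancers an `EnhancerSet` or a plain region data.frame.
#' @param exclusion path to an exclusion BED file, or a region data.frame.
#' @return the filtered object, with attribute `n_removed` giving the
#'   number of enhancers dropped.
#' @export
filter_excluded_regions <- function(enhancers, exclusion) {
  excl <- if (is.character(exclusion)) read_regions(exclusion) else exclusion
  regions <- if (inherits(enhancers, "EnhancerSet")) enhancers$regions else enhancers
  if (nrow(excl) == 0L) {
    attr(enhancers, "n_removed") <- 0L
    return(enhancers)
  }
  # Half-open BED intervals -> 1-based closed IRanges: [start+1, end].
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  s <- GenomicRanges::GRanges(excl$chrom,
                              IRanges::IRanges(excl$start + 1L, excl$end))
  hit <- GenomicRanges::countOverlaps(q, s) > 0L
  out <- if (inherits(enhancers, "EnhancerSet")) {
    enhancer_set(regions[!hit, , drop = FALSE],
                 enhancers$activity[!hit, , drop = FALSE])
  } else {
    regions[!hit, , drop = FALSE]
  }
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Read TF motifs as position frequency matrices
#'
#' Parses a JASPAR-style motif text file: a `>name` header per motif
#' followed by four base rows (`A`, `C`, `G`, `T`, optionally bracketed).
#'
#' @param path path to the motif file.
#' @return named list of `"MotifPFM"` objects, each a list with `tf_name`,
#'   `counts` (W x 4 matrix, columns `A C G T`) and `width`.
#' @export
read_pfms <- function(path) {
  if (!file.exists(path)) stop_gabc(paste0("file not found: ", path), "gabc_io_error")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L)
    stop_gabc("no motif headers ('>') found", "gabc_parse_error")
  ends <- c(hdr[-1L] - 1L, length(lines))
  pfms <- Map(function(from, to) {
    name <- sub("^>\\s*", "", lines[from])
    name <- strsplit(name, "\\s+")[[1L]]
    name <- name[length(name)]   # JASPAR: ">ID NAME" -> keep NAME
    rows <- lines[(from + 1L):to]
    if (length(rows) != 4L)
      stop_gabc(sprintf("motif %s: expected 4 base rows, got %d", name,
                        length(rows)), "gabc_parse_error")
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*|\\[|\\]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    w <- lengths(vals)
    if (length(unique(w)) != 1L)
      stop_gabc(sprintf("motif %s: rows of unequal length", name),
                "gabc_parse_error")
    counts <- matrix(unlist(vals), ncol = 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    motif_pfm(name, counts)
  }, hdr, ends)
  names(pfms) <- vapply(pfms, `[[`, character(1), "tf_name")
  pfms
}

#' Construct a position frequency matrix object
#'
#' @param tf_name motif/TF name.
#' @param counts W x 4 non-negative count matrix over `A C G T`
#'   (rows = motif positions).
#' @return object of class `"MotifPFM"`.
#' @export
motif_pfm <- function(tf_name, counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop_gabc("PFM must have 4 base columns", "gabc_invalid_input")
  colnames(counts) <- c("A", "C", "G", "T")
  if (nrow(counts) < 1L || any(counts < 0))
    stop_gabc("PFM counts must be non-negative with width >= 1",
              "gabc_invalid_input")
  if (any(rowSums(counts) <= 0))
    stop_gabc(sprintf("motif %s: position with zero total count", tf_name),
              "gabc_invalid_input")
  structure(list(tf_name = tf_name, counts = counts, width = nrow(counts)),
            class = "MotifPFM")
}
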