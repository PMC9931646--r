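#' @importFrom stats rnorm runif rgamma setNames complete.cases pnorm sd cor
#' @importFrom utils head tail
NULL

# Abort with a classed condition so callers can test on condition class.
stop_gabc <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gabc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_gabc <- function(msg, class, ...) {
  warning(structure(
    class = c(class, "gabc_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Midpoints of genomic regions
#'
#' Integer midpoint `floor((start + end) / 2)` of 0-based half-open regions.
#' The midpoint anchors a region to a contact-map bin and is the reference
#' point for all enhancer-TSS distances.
#'
#' @param regions data.frame with `start` and `end` columns.
#' @return numeric vector of midpoints.
#' @export
region_midpoints <- function(regions) {
  floor((regions$start + regions$end) / 2)
}

# 5'-most TSS of a gene: minimum position on '+', maximum on '-'.
tss_five_prime <- function(tss, strand) {
  if (identical(strand, "-")) max(tss) else min(tss)
}

# TSS anchor set used to define scoring windows.
tss_anchor <- function(gene, use_all_tss) {
  tss <- gene$tss[[1]]
  if (use_all_tss) tss else tss_five_prime(tss, gene$strand)
}

# Distance from each position in `pos` to its nearest value in `targets`.
nearest_distance <- function(pos, targets) {
  vapply(pos, function(p) min(abs(p - targets)), numeric(1))
}
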