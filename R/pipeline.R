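#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines are ignored.  Values are kept as strings; [run_pipeline()]
#' coerces the ones it knows about.
#'
#' @param path path to the config file.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop_gabc(sprintf("malformed config line: '%s'", lines[bad][1L]),
              "gabc_parse_error")
  out <- lapply(kv, function(m) trimws(m[3L]))
  names(out) <- vapply(kv, function(m) trimws(m[2L]), character(1))
  out
}

config_num <- function(config, key, default) {
  if (is.null(config[[key]])) default else as.numeric(config[[key]])
}

#' Run the full scoring and affinity pipeline
#'
#' Orchestrates: read inputs, exclusion-filter enhancers, score all
#' enhancer-gene pairs batched over activity columns, call interactions at
#' the cutoff and — when motifs and a genome are configured — summarize TF
#' affinities per gene.  Writes per-condition interaction tables and
#' gene x TF matrices plus a JSON run manifest with input checksums, so a
#' run is reproducible from its output directory alone.  Results are
#' deterministic and independent of `n_workers` (parallelism is over
#' genes, with an ordered merge).
#'
#' @param config named list (or path to a `key = value` file) with keys:
#'   `regions`, `annotation`, `activity`, `contacts` (path, or
#'   `"distance-model"` for the inverse-distance fallback), optional
#'   `motifs`, `genome`, `exclusion`; numeric `window`, `cutoff`,
#'   `resolution`, `pseudocount`, `min_distance`; `summarize` regime
#'   (`window`/`abc`/`gabc`), `normalize` (`none`/`rpkm`), `chrom`,
#'   `output_dir`, `n_workers`.
#' @param existence_check when TRUE, validate paths and exit without
#'   computing.
#' @return invisibly, a list with the scored table, called interactions,
#'   affinity matrices (or NULL) and the manifest.
#' @export
run_pipeline <- function(config, existence_check = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  required <- c("regions", "annotation", "activity", "contacts", "output_dir")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop_gabc(paste0("missing config keys: ", paste(miss, collapse = ", ")),
              "gabc_invalid_input")
  in_paths <- unlist(config[intersect(names(config),
                                      c("regions", "annotation", "activity",
                                        "contacts", "motifs", "genome",
                                        "exclusion"))])
  in_paths <- in_paths[in_paths != "distance-model"]
  absent <- in_paths[!file.exists(in_paths)]
  if (length(absent))
    stop_gabc(paste0("input path(s) not found: ", paste(absent, collapse = ", ")),
              "gabc_io_error")
  if (existence_check) {
    message("[gabc] existence check passed (", length(in_paths), " inputs)")
    return(invisible(NULL))
  }

  sc_config <- scoring_config(
    window = config_num(config, "window", 5e6),
    cutoff = config_num(config, "cutoff", 0.02),
    tss_proximal_bp = config_num(config, "tss_proximal_bp", 2500),
    decay_d0 = config_num(config, "decay_d0", 5000)
  )
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  regions <- read_regions(config$regions)
  message(sprintf("[gabc] stage=read regions=%d", nrow(regions)))
  genes <- read_gene_annotation(config$annotation)
  message(sprintf("[gabc] stage=read genes=%d", nrow(genes)))
  normalize <- if (is.null(config$normalize)) "none" else config$normalize
  enhancers <- load_activity(config$activity, regions, normalize = normalize)
  n_excluded <- 0L
  if (!is.null(config$exclusion)) {
    enhancers <- filter_excluded_regions(enhancers, config$exclusion)
    n_excluded <- attr(enhancers, "n_removed")
  }
  message(sprintf("[gabc] stage=filter excluded=%d kept=%d", n_excluded,
                  nrow(enhancers$regions)))

  contacts <- if (identical(config$contacts, "distance-model")) {
    distance_contact_model(config_num(config, "min_distance", 5000))
  } else {
    read_contact_triples(config$contacts,
                         resolution = config_num(config, "resolution", 5000),
                         chrom = if (is.null(config$chrom))
                           regions$chrom[1L] else config$chrom,
                         pseudocount = config_num(config, "pseudocount", 1e-6))
  }

  n_workers <- as.integer(config_num(config, "n_workers", 1))
  scored <- score_all_parallel(enhancers, genes, contacts, sc_config,
                               n_workers)
  message(sprintf("[gabc] stage=score pairs=%d conditions=%d",
                  nrow(scored), length(unique(scored$condition))))
  called <- call_interactions(scored, sc_config$cutoff)
  for (cond in unique(scored$condition)) {
    write_interactions(scored[scored$condition == cond, , drop = FALSE],
                       file.path(out_dir, sprintf("interactions_%s.tsv", cond)))
    message(sprintf("[gabc] stage=call condition=%s called=%d", cond,
                    sum(called$condition == cond)))
  }

  mats <- NULL
  if (!is.null(config$motifs) && !is.null(config$genome)) {
    pfms <- read_pfms(config$motifs)
    mode <- if (is.null(config$summarize)) "gabc" else config$summarize
    mats <- gene_tf_matrix(scored, enhancers, genes, config$genome, pfms,
                           mode = mode, config = sc_config)
    write_gene_tf_matrices(mats, out_dir)
    message(sprintf("[gabc] stage=affinity tfs=%d mode=%s", length(pfms), mode))
  } else {
    message("[gabc] stage=affinity skipped (no motifs/genome configured)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gabc")),
    config = config[order(names(config))],
    config_hash = unname(tools::md5sum(write_temp_config(config))),
    input_md5 = as.list(tools::md5sum(unname(in_paths))),
    n_regions = nrow(enhancers$regions),
    n_excluded = n_excluded,
    n_genes = nrow(genes),
    n_called = nrow(called)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scored = scored, called = called, affinities = mats,
                 manifest = manifest))
}

write_temp_config <- function(config) {
  path <- tempfile(fileext = ".cfg")
  writeLines(sprintf("%s = %s", names(config)[order(names(config))],
                     unlist(config[order(names(config))])), path)
  path
}

# score_all with gene-level parallelism and ordered merge; results are
# identical for any worker count.
score_all_parallel <- function(enhancers, genes, contacts, config, n_workers) {
  if (n_workers <= 1L || nrow(genes) < 2L ||
      .Platform$OS.type == "windows")
    return(score_all(enhancers, genes, contacts, config))
  chunks <- split(seq_len(nrow(genes)),
                  cut(seq_len(nrow(genes)), min(n_workers, nrow(genes)),
                      labels = FALSE))
  parts <- parallel::mclapply(chunks, function(ix) {
    score_all(enhancers, genes[ix, , drop = FALSE], contacts, config,
              gene_universe = genes)
  }, mc.cores = n_workers)
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}
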