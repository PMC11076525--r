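#' Load a screen manifest
#'
#' A manifest describes one multi-replicate screen: where the per-replicate
#' inputs live and the analysis options. As YAML:
#'
#' ```yaml
#' library: lib.tsv            # optional, enables annotation + shift analysis
#' options: {mode: per_guide, fdr: 0.01, min_w: 4}
#' replicates:
#'   - {id: IN1, reporter: DUAL_IN, counts: in1.tsv}
#'   - {id: EX1, reporter: DUAL_EX,
#'      fastq: {unsorted: u.fastq, top: t.fastq, bottom: b.fastq}}
#' ```
#'
#' @param manifest Path to a YAML file, or an equivalent list.
#' @return Validated manifest list.
#' @export
read_screen_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  if (is.null(manifest$replicates) || length(manifest$replicates) == 0) {
    stop("manifest must list at least one replicate (field 'replicates')",
         call. = FALSE)
  }
  for (i in seq_along(manifest$replicates)) {
    r <- manifest$replicates[[i]]
    if (is.null(r$id)) {
      stop("replicates[", i, "]: missing 'id'", call. = FALSE)
    }
    if (is.null(r$reporter) || !r$reporter %in% c("DUAL_IN", "DUAL_EX")) {
      stop("replicates[", i, "]: 'reporter' must be DUAL_IN or DUAL_EX",
           call. = FALSE)
    }
    if (is.null(r$counts) && is.null(r$fastq)) {
      stop("replicates[", i, "]: need either 'counts' or 'fastq' paths",
           call. = FALSE)
    }
    paths <- c(r$counts, unlist(r$fastq))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("replicates[", i, "]: missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  manifest
}

#' Run the full screen analysis pipeline
#'
#' Counts spacers where FASTQ inputs are given, computes per-replicate
#' statistics, combines replicates, calls hits, and (when the manifest
#' names a guide library) runs the spacer-length shift analysis. All tables
#' are written as TSV (missing values as `.`) together with a run-metadata
#' JSON recording the options in effect; the run is deterministic given
#' identical inputs.
#'
#' @param manifest Manifest path or list, see [read_screen_manifest()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `screen_results` object (with a `shift` element
#'   when the shift analysis ran).
#' @export
run_screen_pipeline <- function(manifest, out_dir) {
  manifest <- read_screen_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- manifest$options
  mode <- opts$mode %||% "per_guide"
  fdr <- opts$fdr %||% 0.01
  min_w <- opts$min_w %||% 4L
  library <- if (!is.null(manifest$library)) {
    read_guide_library(manifest$library)
  } else NULL

  tables <- purrr::map(manifest$replicates, function(r) {
    if (!is.null(r$counts)) {
      tab <- read_bin_counts(r$counts)
      attr(tab, "replicate_id") <- r$id
      attr(tab, "reporter") <- r$reporter
      tab
    } else {
      if (is.null(library)) {
        stop("FASTQ inputs require a 'library' entry in the manifest",
             call. = FALSE)
      }
      count_replicate(r$fastq$unsorted, r$fastq$top, r$fastq$bottom,
                      library, replicate_id = r$id, reporter = r$reporter)
    }
  })

  res <- analyze_screen(tables, mode = mode, fdr_threshold = fdr,
                        min_w = min_w, library = library)
  for (st in res$replicates) {
    readr::write_tsv(tibble::as_tibble(st),
                     file.path(out_dir, paste0("stats_",
                                               attr(st, "replicate_id"),
                                               ".tsv")), na = ".")
  }
  write_screen_results(res, file.path(out_dir, "combined.tsv"))

  if (!is.null(library) && all(c(22L, 25L) %in% library$length)) {
    pairs <- pair_by_shift(library)
    if (nrow(pairs) > 0) {
      sc <- shift_correlation(pairs, res)
      readr::write_tsv(sc$summary, file.path(out_dir, "shift_summary.tsv"),
                       na = ".")
      readr::write_tsv(sc$pairs, file.path(out_dir, "shift_pairs.tsv"),
                       na = ".")
      res$shift <- sc$summary
    }
  }

  meta <- list(
    package = "splicescreen",
    version = as.character(utils::packageVersion("splicescreen")),
    options = list(mode = mode, fdr = fdr, min_w = min_w),
    replicates = purrr::map(manifest$replicates,
                            ~ list(id = .x$id, reporter = .x$reporter)),
    znorm = purrr::map(res$replicates, ~ attr(.x, "znorm"))
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
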