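#' Assemble a per-replicate bin count table
#'
#' Holds per-guide read counts for the unsorted, top and bottom bins of one
#' replicate screen, alongside bin totals and unassigned-read counts. The
#' invariant `total_x == sum(counts_x) + unassigned_x` is enforced.
#'
#' @param counts Tibble with columns `guide_id`, `n_unsorted`, `n_top`,
#'   `n_bottom` (non-negative integers).
#' @param unassigned Named numeric vector `c(unsorted=, top=, bottom=)` of
#'   reads not assigned to any guide.
#' @param totals Optional named totals; computed from counts + unassigned
#'   when `NULL`.
#' @param replicate_id,reporter Metadata: replicate label and reporter
#'   orientation (`"DUAL_IN"` or `"DUAL_EX"`).
#' @return A `bin_count_table` tibble with `totals`, `unassigned`,
#'   `replicate_id` and `reporter` attributes.
#' @export
bin_count_table <- function(counts, unassigned = c(unsorted = 0, top = 0, bottom = 0),
                            totals = NULL, replicate_id = "rep1",
                            reporter = c("DUAL_IN", "DUAL_EX")) {
  reporter <- match.arg(reporter)
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("guide_id", "n_unsorted", "n_top", "n_bottom") %in% names(counts)))
  bins <- c("unsorted", "top", "bottom")
  stopifnot(all(bins %in% names(unassigned)))
  if (any(counts$n_unsorted < 0 | counts$n_top < 0 | counts$n_bottom < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  sums <- c(unsorted = sum(counts$n_unsorted), top = sum(counts$n_top),
            bottom = sum(counts$n_bottom))
  if (is.null(totals)) {
    totals <- sums + unassigned[bins]
  } else {
    stopifnot(all(bins %in% names(totals)))
    if (any(abs(totals[bins] - (sums + unassigned[bins])) > 0)) {
      stop("totals must equal assigned + unassigned reads per bin", call. = FALSE)
    }
  }
  structure(counts, class = c("bin_count_table", class(counts)),
            totals = totals[bins], unassigned = unassigned[bins],
            replicate_id = replicate_id, reporter = reporter)
}

#' @export
print.bin_count_table <- function(x, ...) {
  cat("<bin_count_table> replicate ", attr(x, "replicate_id"), " (",
      attr(x, "reporter"), "), totals u/t/b = ",
      paste(attr(x, "totals"), collapse = "/"), "\n", sep = "")
  NextMethod()
}

#' Count spacer-matching reads in one sequenced bin
#'
#' Assigns each read to at most one guide by exact spacer match.
#'
#' In `anchored` mode (default) the spacer is extracted as the subsequence
#' between the 3' end of the direct repeat and the 3' backbone anchor, and
#' must equal a library spacer exactly; reads missing either anchor, or
#' whose extracted sequence is not in the library, are unassigned. This
#' tolerates untrimmed reads because the DR is located by search.
#'
#' In `substring` mode a read is assigned to a guide whose spacer occurs as
#' an exact substring, with longest-match tie-breaking so a read carrying a
#' 25-nt spacer is never credited to a nested 22-nt spacer; a read matching
#' several distinct spacers of the same (longest) length is ambiguous and
#' left unassigned.
#'
#' @param reads Path to a FASTQ file (gzip-transparent) or a character
#'   vector of read sequences.
#' @param library A guide library tibble (with `id` and `spacer`).
#' @param mode `"anchored"` or `"substring"`.
#' @param dr_seq,three_prime Anchor sequences for `anchored` mode; default
#'   to the library's attached DR / 3' adapter.
#' @return Tibble `guide_id`, `count` covering every library guide, with
#'   attributes `unassigned` and `total`.
#' @export
count_spacers <- function(reads, library, mode = c("anchored", "substring"),
                          dr_seq = attr(library, "dr_seq"),
                          three_prime = attr(library, "adapters")$three_prime) {
  mode <- match.arg(mode)
  if (nrow(library) == 0) stop("empty guide library", call. = FALSE)
  if (anyDuplicated(library$spacer)) {
    stop("library spacers must be unique for exact-match counting", call. = FALSE)
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(reads, format = "fastq"),
      error = function(e) stop("malformed FASTQ (", conditionMessage(e), ")",
                               call. = FALSE))
    reads <- as.character(seqs)
  }
  n_reads <- length(reads)
  assigned <- rep(NA_character_, n_reads)
  if (n_reads > 0) {
    if (mode == "anchored") {
      if (is.null(dr_seq) || is.null(three_prime)) {
        stop("anchored mode needs dr_seq and a 3' anchor sequence", call. = FALSE)
      }
      dr_loc <- stringr::str_locate(reads, stringr::fixed(dr_seq))
      after_dr <- ifelse(is.na(dr_loc[, "end"]), NA_character_,
                         stringr::str_sub(reads, dr_loc[, "end"] + 1L))
      anchor_loc <- stringr::str_locate(after_dr, stringr::fixed(three_prime))
      spacer <- ifelse(is.na(anchor_loc[, "start"]), NA_character_,
                       stringr::str_sub(after_dr, 1L, anchor_loc[, "start"] - 1L))
      idx <- match(spacer, library$spacer)
      assigned <- library$id[idx]
    } else {
      subject <- Biostrings::DNAStringSet(reads)
      match_count <- integer(n_reads)
      for (L in sort(unique(nchar(library$spacer)), decreasing = TRUE)) {
        sel <- which(nchar(library$spacer) == L)
        pd <- Biostrings::PDict(library$spacer[sel])
        hits <- Biostrings::vwhichPDict(pd, subject)
        n_hits <- lengths(hits)
        todo <- is.na(assigned) & match_count == 0L
        uniq <- todo & n_hits == 1L
        assigned[uniq] <- library$id[sel][vapply(hits[uniq], `[`, integer(1), 1L)]
        # ambiguous at the longest matching length -> stays unassigned
        match_count[todo] <- n_hits[todo]
      }
    }
  }
  tab <- table(factor(assigned, levels = library$id))
  out <- tibble::tibble(guide_id = library$id, count = as.integer(tab))
  structure(out, unassigned = n_reads - sum(out$count), total = n_reads)
}

#' Count all three bins of a replicate from FASTQ files
#'
#' @param fastq_unsorted,fastq_top,fastq_bottom FASTQ paths.
#' @inheritParams count_spacers
#' @inheritParams bin_count_table
#' @return A [bin_count_table()].
#' @export
count_replicate <- function(fastq_unsorted, fastq_top, fastq_bottom, library,
                            mode = c("anchored", "substring"),
                            replicate_id = "rep1",
                            reporter = c("DUAL_IN", "DUAL_EX")) {
  mode <- match.arg(mode)
  cols <- purrr::map(list(unsorted = fastq_unsorted, top = fastq_top,
                          bottom = fastq_bottom),
                     count_spacers, library = library, mode = mode)
  counts <- tibble::tibble(
    guide_id = cols$unsorted$guide_id,
    n_unsorted = cols$unsorted$count,
    n_top = cols$top$count,
    n_bottom = cols$bottom$count
  )
  bin_count_table(
    counts,
    unassigned = c(unsorted = attr(cols$unsorted, "unassigned"),
                   top = attr(cols$top, "unassigned"),
                   bottom = attr(cols$bottom, "unassigned")),
    replicate_id = replicate_id, reporter = reporter
  )
}

#' Reads-per-million normalization
#'
#' `rpm_{x,g} = n_{x,g} / N_x * 1e6`, where `N_x` is the bin's total read
#' count (assigned + unassigned).
#'
#' @param table A [bin_count_table()].
#' @return Tibble `guide_id`, `rpm_unsorted`, `rpm_top`, `rpm_bottom`.
#' @export
rpm_normalize <- function(table) {
  totals <- attr(table, "totals")
  if (any(totals == 0)) {
    stop("cannot RPM-normalize bin(s) with zero total reads: ",
         paste(names(totals)[totals == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    guide_id = table$guide_id,
    rpm_unsorted = table$n_unsorted / totals[["unsorted"]] * 1e6,
    rpm_top = table$n_top / totals[["top"]] * 1e6,
    rpm_bottom = table$n_bottom / totals[["bottom"]] * 1e6
  )
}

#' Mini-library style log2 enrichment ratios
#'
#' For each guide, the top and bottom RPM are divided by the unsorted RPM
#' and log2-transformed; the top-vs-bottom contrast is their difference.
#' With `pseudo = 0` a ratio whose numerator or denominator is zero is
#' undefined and returned as `NaN`/`Inf` (flagged in the `undefined`
#' column), never silently dropped.
#'
#' @param rpm Tibble from [rpm_normalize()].
#' @param pseudo Non-negative pseudocount added to every RPM.
#' @return Tibble `guide_id`, `log2_top`, `log2_bottom`, `top_vs_bottom`,
#'   `undefined`.
#' @export
mini_library_enrichment <- function(rpm, pseudo = 0) {
  stopifnot(pseudo >= 0)
  log2_top <- log2((rpm$rpm_top + pseudo) / (rpm$rpm_unsorted + pseudo))
  log2_bottom <- log2((rpm$rpm_bottom + pseudo) / (rpm$rpm_unsorted + pseudo))
  tibble::tibble(
    guide_id = rpm$guide_id,
    log2_top = log2_top,
    log2_bottom = log2_bottom,
    top_vs_bottom = log2_top - log2_bottom,
    undefined = !is.finite(log2_top) | !is.finite(log2_bottom)
  )
}

#' Write / read a bin count table (TSV + JSON sidecar)
#'
#' The TSV is long format (`guide_id`, `bin`, `count`); totals, unassigned
#' reads, replicate id and reporter go into `<path>.json`.
#'
#' @param table A [bin_count_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_bin_counts <- function(table, path) {
  long <- tidyr::pivot_longer(tibble::as_tibble(table),
                              cols = c("n_unsorted", "n_top", "n_bottom"),
                              names_to = "bin", names_prefix = "n_",
                              values_to = "count")
  readr::write_tsv(long, path, na = ".")
  jsonlite::write_json(
    list(totals = as.list(attr(table, "totals")),
         unassigned = as.list(attr(table, "unassigned")),
         replicate_id = attr(table, "replicate_id"),
         reporter = attr(table, "reporter")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path) {
  long <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                          progress = FALSE)
  wide <- tidyr::pivot_wider(long, names_from = "bin", values_from = "count",
                             names_prefix = "n_")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bin_count_table(wide,
                  unassigned = unlist(meta$unassigned),
                  totals = unlist(meta$totals),
                  replicate_id = meta$replicate_id,
                  reporter = meta$reporter)
}
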