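#' Quantifiability filter for a bin-vs-unsorted comparison
#'
#' A guide is quantifiable in a comparison when its read count is at least 5
#' in both compared samples and its RPM is at least 20 in at least one of
#' them. Guides failing the filter keep their Z-score out of the Stouffer
#' combination (weight 0).
#'
#' @param n_bin,n_ref Read counts in the sorted bin and the unsorted
#'   reference.
#' @param rpm_bin,rpm_ref The corresponding RPM values.
#' @param min_count,min_rpm The thresholds (inclusive).
#' @return Logical vector.
#' @export
quantifiable <- function(n_bin, n_ref, rpm_bin, rpm_ref,
                         min_count = 5, min_rpm = 20) {
  n_bin >= min_count & n_ref >= min_count &
    (rpm_bin >= min_rpm | rpm_ref >= min_rpm)
}

#' Binomial enrichment score for one bin-vs-reference comparison
#'
#' Measures how far a guide's share of reads in the sorted bin departs from
#' the share expected from the bin totals, standardized by a binomial
#' standard deviation: `e = (r - r0) / s`.
#'
#' Two readings of the statistic are provided. The default, `per_guide`,
#' treats the guide's reads as a two-sample binomial:
#' `r = n_bin / (n_bin + n_ref)`, `r0 = N_bin / (N_bin + N_ref)`,
#' `s = sqrt(r (1 - r) / (n_bin + n_ref))`. The `as_printed` variant uses
#' the library-wide denominator throughout:
#' `r = n_bin / (N_bin + N_ref)`, `s = sqrt(r (1 - r) / (N_bin + N_ref))`;
#' it carries a large guide-independent offset that the subsequent
#' median/MAD centering removes, and is retained for fidelity audits.
#'
#' A degenerate proportion (`r` of 0 or 1, so `s = 0`) yields `NA`: the
#' guide is unquantifiable in that comparison.
#'
#' @param n_bin,n_ref Per-guide read counts (vectors).
#' @param N_bin,N_ref Total reads in the two samples (scalars).
#' @param mode `"per_guide"` (default) or `"as_printed"`.
#' @return Numeric vector of enrichment scores (`NA` where undefined).
#' @export
enrichment_score <- function(n_bin, n_ref, N_bin, N_ref,
                             mode = c("per_guide", "as_printed")) {
  mode <- match.arg(mode)
  if (mode == "per_guide") {
    tot <- n_bin + n_ref
    r <- ifelse(tot > 0, n_bin / tot, NA_real_)
    r0 <- N_bin / (N_bin + N_ref)
    s <- sqrt(r * (1 - r) / tot)
  } else {
    N <- N_bin + N_ref
    r <- n_bin / N
    r0 <- N_bin / N
    s <- sqrt(r * (1 - r) / N)
  }
  e <- (r - r0) / s
  e[!is.finite(e)] <- NA_real_
  e
}

#' Robust Z-normalization by median and scaled MAD
#'
#' `z = (e - m) / sigma` with `m` the median and `sigma = MAD(e) / 0.6745`
#' computed across all guides with a defined enrichment score (controls
#' included). A zero MAD indicates a degenerate score distribution and is an
#' error rather than a silent epsilon.
#'
#' @param e Numeric vector of enrichment scores (may contain `NA`).
#' @return List with `z` (vector, `NA` propagated) and `stats`
#'   (list `m`, `sigma`).
#' @export
robust_z <- function(e) {
  ok <- is.finite(e)
  if (sum(ok) < 2) {
    stop("robust Z-normalization needs at least 2 defined enrichment scores",
         call. = FALSE)
  }
  m <- stats::median(e[ok])
  sigma <- stats::mad(e[ok], constant = 1 / 0.6745)
  if (sigma == 0) {
    stop("MAD of enrichment scores is zero; the score distribution is ",
         "degenerate (try a larger library or the other enrichment mode)",
         call. = FALSE)
  }
  list(z = (e - m) / sigma, stats = list(m = m, sigma = sigma))
}

#' Per-replicate Stouffer combination of the two sorted bins
#'
#' `z_rep = (z_top w_top - z_bottom w_bottom) / sqrt(w_top + w_bottom)`;
#' missing when neither bin is quantifiable. The minus sign encodes that
#' enrichment in the top and depletion in the bottom bin are concordant
#' evidence.
#'
#' @param z_top,z_bottom Robust Z-scores (may be `NA` where `w` is 0).
#' @param w_top,w_bottom 0/1 quantifiability weights.
#' @return Numeric vector (`NA` where `w_top + w_bottom == 0`).
#' @export
replicate_z <- function(z_top, z_bottom, w_top, w_bottom) {
  zt <- ifelse(w_top == 1, z_top, 0)
  zb <- ifelse(w_bottom == 1, z_bottom, 0)
  w <- w_top + w_bottom
  ifelse(w >= 1, (zt - zb) / sqrt(w), NA_real_)
}

#' Per-replicate enrichment statistics
#'
#' Runs the full per-replicate chain on a bin count table: RPM, the
#' quantifiability filter, enrichment scores for top-vs-unsorted and
#' bottom-vs-unsorted, robust Z-normalization across all guides with a
#' defined score, and the per-replicate Stouffer combination. Weights are
#' zeroed where the score itself is undefined, and the median/MAD pool
#' excludes undefined scores; the filter is applied after Z computation.
#'
#' @param table A [bin_count_table()].
#' @param mode Enrichment mode, see [enrichment_score()].
#' @param min_count,min_rpm Quantifiability thresholds.
#' @return Tibble with per-guide columns `guide_id`, counts, RPM, `e_top`,
#'   `e_bottom`, `z_top`, `z_bottom`, `w_top`, `w_bottom`, `z_rep`;
#'   attributes `znorm` (normalization constants per comparison),
#'   `replicate_id`, `reporter`, `mode`.
#' @export
replicate_stats <- function(table, mode = c("per_guide", "as_printed"),
                            min_count = 5, min_rpm = 20) {
  mode <- match.arg(mode)
  totals <- attr(table, "totals")
  rpm <- rpm_normalize(table)
  e_top <- enrichment_score(table$n_top, table$n_unsorted,
                            totals[["top"]], totals[["unsorted"]], mode)
  e_bottom <- enrichment_score(table$n_bottom, table$n_unsorted,
                               totals[["bottom"]], totals[["unsorted"]], mode)
  zt <- robust_z(e_top)
  zb <- robust_z(e_bottom)
  w_top <- as.integer(
    quantifiable(table$n_top, table$n_unsorted, rpm$rpm_top, rpm$rpm_unsorted,
                 min_count, min_rpm) & is.finite(zt$z))
  w_bottom <- as.integer(
    quantifiable(table$n_bottom, table$n_unsorted, rpm$rpm_bottom,
                 rpm$rpm_unsorted, min_count, min_rpm) & is.finite(zb$z))
  out <- tibble::tibble(
    guide_id = table$guide_id,
    n_unsorted = table$n_unsorted, n_top = table$n_top,
    n_bottom = table$n_bottom,
    rpm_unsorted = rpm$rpm_unsorted, rpm_top = rpm$rpm_top,
    rpm_bottom = rpm$rpm_bottom,
    e_top = e_top, e_bottom = e_bottom,
    z_top = zt$z, z_bottom = zb$z,
    w_top = w_top, w_bottom = w_bottom,
    z_rep = replicate_z(zt$z, zb$z, w_top, w_bottom)
  )
  structure(out, znorm = list(top = zt$stats, bottom = zb$stats),
            replicate_id = attr(table, "replicate_id"),
            reporter = attr(table, "reporter"), mode = mode)
}

# Sign of a sorted bin's contribution to the combined Z. With the Dual-IN
# reporter, top-bin enrichment means more exon inclusion (activation, +);
# the Dual-EX reporter inverts the readout.
.bin_sign <- function(bin, reporter) {
  s <- ifelse(bin == "top", 1, -1)
  if (identical(reporter, "DUAL_IN")) s else -s
}

#' Combine replicate screens into a final per-guide Z-score
#'
#' Generalizes the canonical four-replicate combination to any number of
#' replicates: `Z = sum(sign * z * w) / sqrt(W)` over every sorted bin of
#' every replicate, with `sign(top, DUAL_IN) = +1`,
#' `sign(bottom, DUAL_IN) = -1` and both signs flipped for `DUAL_EX`, and
#' `W` the number of quantifiable bins. A positive Z reflects splicing
#' activation.
#'
#' @param replicates List of [replicate_stats()] tibbles (each carrying a
#'   `reporter` attribute), or a single such tibble.
#' @return Tibble `guide_id`, `Z`, `W` (`Z` is `NA` where `W == 0`).
#' @export
combine_replicates <- function(replicates) {
  if (!is.list(replicates) || is.data.frame(replicates)) {
    replicates <- list(replicates)
  }
  long <- purrr::imap_dfr(replicates, function(st, i) {
    rep_id <- attr(st, "replicate_id")
    if (is.null(rep_id)) rep_id <- as.character(i)
    reporter <- attr(st, "reporter")
    stopifnot(reporter %in% c("DUAL_IN", "DUAL_EX"))
    bin <- rep(c("top", "bottom"), each = nrow(st))
    tibble::tibble(
      guide_id = rep(st$guide_id, 2L),
      bin = bin,
      z = c(st$z_top, st$z_bottom),
      w = c(st$w_top, st$w_bottom),
      sign = .bin_sign(bin, reporter)
    )
  })
  long |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::summarise(
      W = sum(.data$w),
      Z = ifelse(W == 0, NA_real_,
                 sum(.data$sign * ifelse(.data$w == 1, .data$z, 0)) / sqrt(W)),
      .groups = "drop"
    ) |>
    dplyr::select("guide_id", "Z", "W")
}

#' Call hits from combined Z-scores
#'
#' Keeps guides with at least `min_w` quantifiable bins, converts their
#' combined Z into two-sided normal p-values, adjusts by Benjamini-Hochberg
#' over exactly that filtered set, and classifies hits by sign: activator
#' (`fdr <= fdr_threshold`, `Z > 0`) or inhibitor (`Z < 0`). Guides below
#' the `W` filter carry no p, FDR or class.
#'
#' @param combined Tibble from [combine_replicates()].
#' @param fdr_threshold FDR cutoff in (0, 1); the comparison is `<=`.
#' @param min_w Minimum number of quantifiable bins (default 4).
#' @return The input with `p`, `fdr`, `hit_class` columns added.
#' @export
call_hits <- function(combined, fdr_threshold = 0.01, min_w = 4L) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  keep <- !is.na(combined$Z) & combined$W >= min_w
  if (!any(keep)) {
    warning("no guides pass the W >= ", min_w, " filter", call. = FALSE)
  }
  p <- rep(NA_real_, nrow(combined))
  p[keep] <- 2 * stats::pnorm(-abs(combined$Z[keep]))
  fdr <- rep(NA_real_, nrow(combined))
  fdr[keep] <- stats::p.adjust(p[keep], method = "BH")
  hit_class <- rep(NA_character_, nrow(combined))
  hit_class[keep] <- dplyr::case_when(
    fdr[keep] <= fdr_threshold & combined$Z[keep] > 0 ~ "activator",
    fdr[keep] <= fdr_threshold & combined$Z[keep] < 0 ~ "inhibitor",
    .default = "none"
  )
  dplyr::mutate(combined, p = p, fdr = fdr, hit_class = hit_class)
}

#' Analyze a full screen: replicates in, annotated hit table out
#'
#' Convenience driver chaining [replicate_stats()], [combine_replicates()]
#' and [call_hits()].
#'
#' @param tables List of [bin_count_table()]s (one per replicate, each
#'   tagged with its reporter orientation).
#' @param mode Enrichment mode, see [enrichment_score()].
#' @param fdr_threshold,min_w Hit-calling parameters, see [call_hits()].
#' @param min_count,min_rpm Quantifiability thresholds.
#' @param library Optional guide library; when given, guide names, lengths,
#'   anchor positions and control status are joined onto the result.
#' @return A `screen_results` object: list with `combined` (annotated hit
#'   tibble), `replicates` (list of per-replicate stats) and `params`.
#' @export
analyze_screen <- function(tables, mode = c("per_guide", "as_printed"),
                           fdr_threshold = 0.01, min_w = 4L,
                           min_count = 5, min_rpm = 20, library = NULL) {
  mode <- match.arg(mode)
  stats_list <- purrr::map(tables, replicate_stats, mode = mode,
                           min_count = min_count, min_rpm = min_rpm)
  names(stats_list) <- purrr::map_chr(stats_list, ~ attr(.x, "replicate_id"))
  combined <- call_hits(combine_replicates(stats_list),
                        fdr_threshold = fdr_threshold, min_w = min_w)
  if (!is.null(library)) {
    ann <- tibble::tibble(
      guide_id = library$id, name = library$name, length = library$length,
      position = guide_anchor(library), is_control = library$is_control
    )
    combined <- dplyr::left_join(combined, ann, by = "guide_id")
    combined <- dplyr::relocate(combined, "name", "length", "position",
                                "is_control", .after = "guide_id")
  }
  structure(
    list(combined = combined, replicates = stats_list,
         params = list(mode = mode, fdr_threshold = fdr_threshold,
                       min_w = min_w, min_count = min_count,
                       min_rpm = min_rpm)),
    class = "screen_results"
  )
}

#' @export
print.screen_results <- function(x, ...) {
  g <- glance(x)
  cat("<screen_results> ", g$n_guides, " guides, ", g$n_replicates,
      " replicates, mode=", x$params$mode, "\n", sep = "")
  cat("  tested (W >= ", x$params$min_w, "): ", g$n_tested,
      "; hits at FDR <= ", x$params$fdr_threshold, ": ", g$n_hits,
      " (", g$n_activators, " activators, ", g$n_inhibitors,
      " inhibitors)\n", sep = "")
  invisible(x)
}

#' Tidy the combined hit table of a screen analysis
#'
#' @param x A `screen_results` object.
#' @param ... Unused.
#' @return The combined per-guide tibble (`guide_id`, `Z`, `W`, `p`, `fdr`,
#'   `hit_class`, plus library annotation when available).
#' @method tidy screen_results
#' @export
tidy.screen_results <- function(x, ...) {
  x$combined
}

#' One-row summary of a screen analysis
#'
#' @param x A `screen_results` object.
#' @param ... Unused.
#' @return One-row tibble with guide, replicate and hit counts.
#' @method glance screen_results
#' @export
glance.screen_results <- function(x, ...) {
  cm <- x$combined
  tibble::tibble(
    n_guides = nrow(cm),
    n_replicates = length(x$replicates),
    n_tested = sum(!is.na(cm$p)),
    n_hits = sum(cm$hit_class %in% c("activator", "inhibitor")),
    n_activators = sum(cm$hit_class %in% "activator"),
    n_inhibitors = sum(cm$hit_class %in% "inhibitor"),
    fdr_threshold = x$params$fdr_threshold,
    mode = x$params$mode
  )
}

#' Write the combined results table as TSV
#'
#' @param results A `screen_results` object or its combined tibble.
#' @param path Output path. Missing values are written as `.`.
#' @return Invisibly, `path`.
#' @export
write_screen_results <- function(results, path) {
  tab <- if (inherits(results, "screen_results")) results$combined else results
  readr::write_tsv(tab, path, na = ".")
  invisible(path)
}
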