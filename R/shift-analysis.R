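#' Pair each 25-nt guide with the four 22-nt guides it covers
#'
#' A 25-mer target footprint `[s, s+25)` fully covers four 22-mer
#' footprints. Shift is defined on the spacer: shift 0 when the two spacers
#' share their 5' end (which, for antisense spacers, is the target
#' interval's 3' end), and shift k when the 22-nt spacer is moved k nt
#' toward the spacer 3' direction, so the shift-k partner footprint is
#' `[s+3-k, s+25-k)`. Shift 3 means the spacers coincide at their 3' ends
#' (matching target 5' ends). 25-mers missing a partner at a region edge
#' contribute no row for that shift.
#'
#' @param library A guide library tibble containing both 22- and 25-nt
#'   on-target guides tiled at step 1.
#' @param long_length,short_length Spacer length classes to pair.
#' @return Tibble `guide_long_id`, `guide_short_id`, `shift`,
#'   `start_long`, `end_long`, `start_short`, `end_short`.
#' @export
pair_by_shift <- function(library, long_length = 25L, short_length = 22L) {
  d <- long_length - short_length
  long <- dplyr::filter(tibble::as_tibble(library),
                        !.data$is_control, .data$length == long_length)
  short <- dplyr::filter(tibble::as_tibble(library),
                         !.data$is_control, .data$length == short_length)
  if (nrow(long) == 0 || nrow(short) == 0) {
    return(tibble::tibble(guide_long_id = character(),
                          guide_short_id = character(), shift = integer(),
                          start_long = integer(), end_long = integer(),
                          start_short = integer(), end_short = integer()))
  }
  grid <- tidyr::expand_grid(
    dplyr::select(long, guide_long_id = "id", start_long = "target_start",
                  end_long = "target_end"),
    shift = 0:d
  )
  grid <- dplyr::mutate(grid,
    start_short = .data$start_long + d - .data$shift,
    end_short = .data$start_long + long_length - .data$shift
  )
  short_key <- dplyr::select(short, guide_short_id = "id",
                             start_short = "target_start")
  out <- dplyr::inner_join(grid, short_key, by = "start_short")
  dplyr::select(out, "guide_long_id", "guide_short_id", "shift",
                "start_long", "end_long", "start_short", "end_short")
}

#' Per-shift concordance of combined Z-scores
#'
#' Joins the combined Z-scores of both members of every 25/22 pair and
#' computes, independently per shift, the squared Pearson correlation over
#' pairs where both Z are present. Pairs with a missing Z (filtered guides)
#' are dropped, not imputed; fewer than `min_pairs` complete pairs yields a
#' missing R2.
#'
#' @param pairs Tibble from [pair_by_shift()].
#' @param results Combined results: a `screen_results` object or a tibble
#'   with `guide_id` and `Z`.
#' @param min_pairs Minimum complete pairs per shift.
#' @return List with `summary` (tibble `shift`, `n`, `r2`) and `pairs`
#'   (the pair table with `z_long`, `z_short` columns).
#' @export
shift_correlation <- function(pairs, results, min_pairs = 3L) {
  if (inherits(results, "screen_results")) results <- results$combined
  z <- dplyr::select(tibble::as_tibble(results), "guide_id", "Z")
  tab <- pairs |>
    dplyr::left_join(dplyr::rename(z, guide_long_id = "guide_id",
                                   z_long = "Z"), by = "guide_long_id") |>
    dplyr::left_join(dplyr::rename(z, guide_short_id = "guide_id",
                                   z_short = "Z"), by = "guide_short_id")
  summary <- tab |>
    dplyr::filter(!is.na(.data$z_long), !is.na(.data$z_short)) |>
    dplyr::group_by(.data$shift) |>
    dplyr::summarise(
      n = dplyr::n(),
      r2 = if (dplyr::n() >= min_pairs) {
        stats::cor(.data$z_long, .data$z_short)^2
      } else NA_real_,
      .groups = "drop"
    )
  all_shifts <- tibble::tibble(shift = sort(unique(pairs$shift)))
  summary <- dplyr::left_join(all_shifts, summary, by = "shift")
  summary$n[is.na(summary$n)] <- 0L
  list(summary = summary, pairs = tab)
}
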