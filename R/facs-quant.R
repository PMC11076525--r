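#' Gate flow-cytometry events
#'
#' Retains viable events with BFP intensity at or above the threshold
#' (high BFP marks cells expressing the dCas13d effector). Retained/total
#' counts are recorded as attributes.
#'
#' @param events Data frame with columns `egfp`, `tdtomato`, `bfp` and,
#'   when `require_viable`, a logical `viable` column.
#' @param bfp_threshold Intensity cutoff (inclusive).
#' @param require_viable Drop non-viable events first.
#' @return The gated tibble with attributes `n_total` and `n_retained`.
#' @export
gate_events <- function(events, bfp_threshold = 0, require_viable = TRUE) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("egfp", "tdtomato", "bfp") %in% names(events)))
  keep <- events$bfp >= bfp_threshold
  if (require_viable) {
    stopifnot("viable" %in% names(events))
    keep <- keep & events$viable
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no events retained by the gate", call. = FALSE)
  }
  structure(out, n_total = nrow(events), n_retained = nrow(out))
}

#' Per-event log-ratio PSI proxy (M/A values)
#'
#' On the dual-fluorescence reporter, `log2(PSI) = log2(tdTomato) -
#' log2(eGFP) + c` for an unknown constant `c`, so the per-event log-ratio
#' `M = log2(tdtomato) - log2(egfp)` is a relative inclusion readout;
#' `A = (log2(tdtomato) + log2(egfp)) / 2` is the mean log-intensity used
#' for MA plots. Events with non-positive intensities are dropped and
#' counted. Summaries are median-based (robust to the heavy-tailed event
#' distribution); absolute PSI is not identifiable and never reported.
#'
#' @param events A gated event table (see [gate_events()]).
#' @return List with `events` (tibble plus `M`, `A` columns), `summary`
#'   (one-row tibble: `median_m`, `mad_m`, `n`) and `n_dropped`.
#' @export
psi_log_ratio <- function(events) {
  events <- tibble::as_tibble(events)
  ok <- events$egfp > 0 & events$tdtomato > 0
  dropped <- sum(!ok)
  events <- events[ok, , drop = FALSE]
  if (nrow(events) == 0) stop("no events with positive intensities", call. = FALSE)
  events <- dplyr::mutate(events,
    M = log2(.data$tdtomato) - log2(.data$egfp),
    A = (log2(.data$tdtomato) + log2(.data$egfp)) / 2
  )
  list(
    events = events,
    summary = tibble::tibble(
      median_m = stats::median(events$M),
      mad_m = stats::mad(events$M, constant = 1 / 0.6745),
      n = nrow(events)
    ),
    n_dropped = dropped
  )
}

#' Relative exon-inclusion change versus a non-targeting control
#'
#' `delta = median M(sample) - median M(control)`: the unknown offset `c`
#' of the fluorescence PSI proxy cancels, making the fold change directly
#' comparable to RT-PCR-based estimates. Samples below the minimum event
#' count are annotated with a warning flag but still returned.
#'
#' @param sample,control Summary tibbles from [psi_log_ratio()] (or lists
#'   containing one).
#' @param min_events Minimum events per summary for a trusted estimate.
#' @return One-row tibble `delta_log2_psi`, `n_sample`, `n_control`,
#'   `low_event_warning`.
#' @export
delta_psi_vs_control <- function(sample, control, min_events = 2400L) {
  pick <- function(x) if (is.list(x) && !is.data.frame(x)) x$summary else x
  s <- pick(sample)
  k <- pick(control)
  low <- s$n < min_events || k$n < min_events
  if (low) {
    warning("fewer than ", min_events, " events in sample or control; ",
            "estimate may be unstable", call. = FALSE)
  }
  tibble::tibble(
    delta_log2_psi = s$median_m - k$median_m,
    n_sample = s$n, n_control = k$n,
    low_event_warning = low
  )
}

#' Read a flow-cytometry event table from CSV
#'
#' Expects named columns `egfp`, `tdtomato`, `bfp` and optionally `viable`
#' (native FCS parsing is out of scope; export events upstream).
#'
#' @param path CSV path.
#' @return Tibble of events.
#' @export
read_facs_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(ev) <- tolower(names(ev))
  stopifnot(all(c("egfp", "tdtomato", "bfp") %in% names(ev)))
  ev
}
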