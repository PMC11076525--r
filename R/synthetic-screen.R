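#' Ground truth for a synthetic tiling screen
#'
#' Describes the splicing-regulatory elements (SREs) planted in the
#' simulated reporter, the baseline inclusion level and how a bound
#' dCas13d/gRNA perturbs it. Blocking an element shifts the logit of PSI by
#' `-effect * overlap_frac * potency(length)`, where `overlap_frac` is the
#' fraction of the SRE covered by the guide's effective footprint. Silencer
#' elements carry negative `effect` (blocking them raises inclusion),
#' enhancers positive `effect`.
#'
#' The effective footprint is anchored at the spacer 5' end: only the
#' `anchor_width` target bases adjacent to the target interval's 3' end
#' count (the spacer 5' end pairs the footprint's 3'-most target base, and
#' together with the upstream stem-loop defines where the protein sits).
#' Set `footprint_anchor = "full"` to use the whole target interval.
#'
#' @param region_length Reporter length in nt.
#' @param sres Tibble with columns `start`, `end` (0-based half-open),
#'   `effect` (signed, logit-PSI units per unit overlap), `kind`
#'   (`"enhancer"` or `"silencer"`).
#' @param baseline_psi Baseline inclusion level in (0, 1).
#' @param potency Named numeric, spacer length -> effect multiplier.
#' @param footprint_anchor `"spacer5"` (default) or `"full"`.
#' @param anchor_width Width of the effective footprint under `"spacer5"`.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(region_length = 835L,
                      sres = default_sres(),
                      baseline_psi = 0.4,
                      potency = c("22" = 0.7, "25" = 1),
                      footprint_anchor = c("spacer5", "full"),
                      anchor_width = 22L) {
  footprint_anchor <- match.arg(footprint_anchor)
  sres <- tibble::as_tibble(sres)
  if (nrow(sres) > 0) {
    stopifnot(all(c("start", "end", "effect", "kind") %in% names(sres)),
              all(sres$start >= 0), all(sres$end <= region_length),
              all(sres$end > sres$start))
  }
  stopifnot(baseline_psi > 0, baseline_psi < 1, all(potency > 0))
  structure(list(region_length = region_length, sres = sres,
                 baseline_psi = baseline_psi, potency = potency,
                 footprint_anchor = footprint_anchor,
                 anchor_width = anchor_width),
            class = "sim_truth")
}

#' Default demo SREs
#'
#' One proximal intronic silencer (emulating ISS-N1: downstream-intron
#' positions 10-34 of the demo layout) and one distal intronic enhancer
#' (emulating ISE-D1: positions 333-357), each 25 nt, with logit-scale
#' effects of -2.5 and +2.5. Coordinates are absolute on the demo 835-nt
#' region whose downstream intron starts at position 335.
#'
#' @return Tibble `start`, `end`, `effect`, `kind`.
#' @export
default_sres <- function() {
  tibble::tibble(
    start = c(335L + 9L, 335L + 332L),
    end   = c(335L + 34L, 335L + 357L),
    effect = c(-2.5, 2.5),
    kind = c("silencer", "enhancer")
  )
}

#' Simulation configuration
#'
#' @param cells_per_guide Cells transduced per library guide (single
#'   integration: each cell carries exactly one guide).
#' @param bfp_positive_frac Fraction of cells remaining BFP-positive
#'   (expressing dCas13d) at sort time.
#' @param fluor_noise_sd Log2-scale Gaussian noise on the tdTomato/eGFP
#'   ratio per cell.
#' @param sort_fraction Fraction collected into each of the top and bottom
#'   bins (strict empirical quantiles of the log-ratio M).
#' @param reads_per_bin Sequencing reads per bin (multinomial over the
#'   bin's guide composition).
#' @param egfp_mean_log2,egfp_sd_log2 Log2-scale location/spread of the
#'   constitutive eGFP channel.
#' @param bfp_threshold Gate threshold on the BFP channel.
#' @param viable_frac Fraction of events passing the viability stain.
#' @param seed Default seed for [simulate_screen()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(cells_per_guide = 1000L, bfp_positive_frac = 0.4,
                       fluor_noise_sd = 0.5, sort_fraction = 0.05,
                       reads_per_bin = 1e6, egfp_mean_log2 = 10,
                       egfp_sd_log2 = 0.8, bfp_threshold = 512,
                       viable_frac = 0.95, seed = 1L) {
  stopifnot(sort_fraction > 0, sort_fraction < 0.5, cells_per_guide > 0,
            reads_per_bin > 0, bfp_positive_frac > 0, bfp_positive_frac <= 1)
  structure(list(cells_per_guide = as.integer(cells_per_guide),
                 bfp_positive_frac = bfp_positive_frac,
                 fluor_noise_sd = fluor_noise_sd,
                 sort_fraction = sort_fraction,
                 reads_per_bin = reads_per_bin,
                 egfp_mean_log2 = egfp_mean_log2,
                 egfp_sd_log2 = egfp_sd_log2,
                 bfp_threshold = bfp_threshold,
                 viable_frac = viable_frac, seed = as.integer(seed)),
            class = "sim_config")
}

# Effective footprint of a guide under the truth's anchor rule.
.effective_footprint <- function(start, end, truth) {
  if (truth$footprint_anchor == "spacer5") {
    w <- pmin(end - start, truth$anchor_width)
    list(start = end - w, end = end)
  } else {
    list(start = start, end = end)
  }
}

#' Per-guide overlap with the planted SREs
#'
#' For every on-target guide, the maximum `overlap_frac` over SREs
#' (`|footprint .intersect. sre| / |sre|`, using the truth's effective
#' footprint) and the Z sign expected if the guide is a hit (+1 when the
#' best-overlapped SRE is a silencer, -1 for an enhancer).
#'
#' @param library A guide library tibble.
#' @param truth A [sim_truth()].
#' @return Tibble `guide_id`, `overlap`, `expected_sign` (0 for controls
#'   and guides overlapping no SRE).
#' @export
guide_truth_overlap <- function(library, truth) {
  fp <- .effective_footprint(library$target_start, library$target_end, truth)
  overlap <- rep(0, nrow(library))
  expected_sign <- rep(0, nrow(library))
  if (nrow(truth$sres) > 0) {
    per_sre <- vapply(seq_len(nrow(truth$sres)), function(i) {
      sre <- truth$sres[i, ]
      ov <- pmax(0, pmin(fp$end, sre$end) - pmax(fp$start, sre$start))
      ov / (sre$end - sre$start)
    }, numeric(nrow(library)))
    per_sre <- matrix(per_sre, nrow = nrow(library))
    per_sre[is.na(per_sre)] <- 0
    best <- max.col(per_sre, ties.method = "first")
    overlap <- per_sre[cbind(seq_len(nrow(library)), best)]
    expected_sign <- ifelse(overlap > 0,
                            ifelse(truth$sres$kind[best] == "silencer", 1, -1),
                            0)
  }
  tibble::tibble(guide_id = library$id, overlap = overlap,
                 expected_sign = expected_sign)
}

#' Ground-truth PSI for every guide
#'
#' `logit(psi_g) = logit(baseline) - sum_sre effect * overlap_frac *
#' potency(length_g)`; controls (and guides overlapping nothing) sit at the
#' baseline.
#'
#' @param library A guide library tibble.
#' @param truth A [sim_truth()].
#' @return Tibble `guide_id`, `psi`.
#' @export
guide_effects <- function(library, truth) {
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  shift <- rep(0, nrow(library))
  on <- !library$is_control
  if (any(on) && nrow(truth$sres) > 0) {
    fp <- .effective_footprint(library$target_start[on],
                               library$target_end[on], truth)
    pot <- unname(truth$potency[as.character(library$length[on])])
    pot[is.na(pot)] <- 1
    for (i in seq_len(nrow(truth$sres))) {
      sre <- truth$sres[i, ]
      ov <- pmax(0, pmin(fp$end, sre$end) - pmax(fp$start, sre$start)) /
        (sre$end - sre$start)
      shift[on] <- shift[on] + sre$effect * ov * pot
    }
  }
  tibble::tibble(guide_id = library$id,
                 psi = inv_logit(logit(truth$baseline_psi) - shift))
}

#' Simulate flow-cytometry events for a transduced cell pool
#'
#' Each cell carries exactly one guide (single-integration model). The
#' constitutive eGFP channel is lognormal; tdTomato scales with the guide's
#' PSI (`DUAL_IN`) or `1 - PSI` (`DUAL_EX`) times eGFP, with additional
#' log2-scale Gaussian noise; BFP is bimodal with `bfp_positive_frac` of
#' cells in the high mode. Reproducible for a fixed seed.
#'
#' @param psis Tibble `guide_id`, `psi` from [guide_effects()].
#' @param config A [sim_config()].
#' @param reporter `"DUAL_IN"` or `"DUAL_EX"`.
#' @param seed Integer seed.
#' @return Event tibble: `event`, `guide_id` (factor), `egfp`, `tdtomato`,
#'   `bfp`, `viable`.
#' @export
simulate_cells <- function(psis, config, reporter = c("DUAL_IN", "DUAL_EX"),
                           seed = config$seed) {
  reporter <- match.arg(reporter)
  if (any(psis$psi <= 0 | psis$psi >= 1)) {
    stop("all PSI values must lie strictly inside (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  n_guides <- nrow(psis)
  n <- n_guides * config$cells_per_guide
  guide <- rep.int(seq_len(n_guides), config$cells_per_guide)
  psi <- psis$psi[guide]
  egfp <- 2^stats::rnorm(n, config$egfp_mean_log2, config$egfp_sd_log2)
  frac <- if (reporter == "DUAL_IN") psi else 1 - psi
  tdtomato <- egfp * frac * 2^stats::rnorm(n, 0, config$fluor_noise_sd)
  bfp_pos <- stats::runif(n) < config$bfp_positive_frac
  bfp <- 2^ifelse(bfp_pos, stats::rnorm(n, 12, 1), stats::rnorm(n, 6, 1))
  viable <- stats::runif(n) < config$viable_frac
  tibble::tibble(
    event = seq_len(n),
    guide_id = factor(psis$guide_id[guide], levels = psis$guide_id),
    egfp = egfp, tdtomato = tdtomato, bfp = bfp, viable = viable
  )
}

#' Sort simulated cells and sequence the bins
#'
#' Gates BFP-positive viable cells, ranks them by the log-ratio
#' `M = log2(tdtomato) - log2(egfp)` with deterministic tie-breaking by
#' event index, collects the strict top and bottom `sort_fraction`
#' quantiles, and draws `reads_per_bin` sequencing reads per bin from a
#' multinomial over each bin's guide composition (the unsorted sample is
#' the whole gated population).
#'
#' @param cells Event tibble from [simulate_cells()] (needs `guide_id`).
#' @param config A [sim_config()].
#' @param replicate_id,reporter Metadata for the resulting count table.
#' @param seed Integer seed for the read sampling.
#' @return A [bin_count_table()] whose totals are `reads_per_bin` per bin
#'   (unassigned 0). The per-bin cell compositions are attached as the
#'   `bin_cells` attribute.
#' @export
sort_and_sequence <- function(cells, config, replicate_id = "rep1",
                              reporter = c("DUAL_IN", "DUAL_EX"),
                              seed = config$seed) {
  reporter <- match.arg(reporter)
  gated <- cells[cells$viable & cells$bfp >= config$bfp_threshold, ]
  if (nrow(gated) == 0) stop("no BFP-positive viable cells to sort", call. = FALSE)
  m <- log2(gated$tdtomato) - log2(gated$egfp)
  ord <- order(m, gated$event)
  k <- floor(config$sort_fraction * nrow(gated))
  if (k < 1) stop("sort fraction yields an empty bin", call. = FALSE)
  bottom_idx <- ord[seq_len(k)]
  top_idx <- ord[seq.int(nrow(gated) - k + 1L, nrow(gated))]
  levels_g <- levels(gated$guide_id)
  comp <- function(idx) tabulate(as.integer(gated$guide_id[idx]),
                                 nbins = length(levels_g))
  cells_u <- comp(seq_len(nrow(gated)))
  cells_t <- comp(top_idx)
  cells_b <- comp(bottom_idx)
  set.seed(seed)
  draw <- function(cells_x) {
    as.integer(stats::rmultinom(1, size = config$reads_per_bin,
                                prob = cells_x / sum(cells_x)))
  }
  counts <- tibble::tibble(
    guide_id = levels_g,
    n_unsorted = draw(cells_u),
    n_top = draw(cells_t),
    n_bottom = draw(cells_b)
  )
  out <- bin_count_table(counts, replicate_id = replicate_id,
                         reporter = reporter)
  attr(out, "bin_cells") <- tibble::tibble(
    guide_id = levels_g, cells_unsorted = cells_u,
    cells_top = cells_t, cells_bottom = cells_b)
  out
}

#' Write a bin count table out as synthetic FASTQ files
#'
#' Embeds each counted guide's spacer in the sequencing cassette
#' (`5' adapter + DR + spacer + 3' adapter`), one read per counted read, so
#' that [count_spacers()] on the files reproduces the table exactly.
#'
#' @param table A [bin_count_table()].
#' @param library The guide library the counts refer to.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of the three FASTQ paths.
#' @export
write_bin_fastq <- function(table, library, dir, prefix = "bin") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adapters <- attr(library, "adapters")
  dr <- attr(library, "dr_seq")
  spacer <- library$spacer[match(table$guide_id, library$id)]
  paths <- c(unsorted = file.path(dir, paste0(prefix, "_unsorted.fastq")),
             top = file.path(dir, paste0(prefix, "_top.fastq")),
             bottom = file.path(dir, paste0(prefix, "_bottom.fastq")))
  cols <- list(unsorted = table$n_unsorted, top = table$n_top,
               bottom = table$n_bottom)
  for (bin in names(paths)) {
    n <- cols[[bin]]
    reads <- paste0(adapters$five_prime, dr, rep(spacer, n),
                    adapters$three_prime)
    seqs <- Biostrings::DNAStringSet(reads)
    names(seqs) <- sprintf("read%07d", seq_along(seqs))
    Biostrings::writeXStringSet(
      seqs, paths[[bin]], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  }
  paths
}

#' Simulate a complete multi-replicate screen
#'
#' Runs [guide_effects()], [simulate_cells()] and [sort_and_sequence()] for
#' each replicate of the canonical design (two Dual-IN and two Dual-EX
#' transductions by default), with per-replicate seeds derived from `seed`.
#'
#' @param library A guide library tibble.
#' @param truth A [sim_truth()].
#' @param config A [sim_config()].
#' @param reporters Named character vector: replicate id -> reporter.
#' @param seed Base seed.
#' @return Named list of [bin_count_table()]s.
#' @export
simulate_screen <- function(library, truth, config = sim_config(),
                            reporters = c(IN1 = "DUAL_IN", IN2 = "DUAL_IN",
                                          EX1 = "DUAL_EX", EX2 = "DUAL_EX"),
                            seed = config$seed) {
  psis <- guide_effects(library, truth)
  purrr::imap(reporters, function(reporter, rep_id) {
    rep_seed <- seed + 1000L * match(rep_id, names(reporters))
    cells <- simulate_cells(psis, config, reporter = reporter,
                            seed = rep_seed)
    sort_and_sequence(cells, config, replicate_id = rep_id,
                      reporter = reporter, seed = rep_seed + 1L)
  })
}

#' Hit recovery against the simulation ground truth
#'
#' Sensitivity is computed over on-target guides whose effective-footprint
#' overlap with some SRE is at least `overlap_min`; the control false
#' positive rate over control guides; sign accuracy over the called true
#' guides (a silencer-blocking hit must have Z > 0, an enhancer-blocking
#' hit Z < 0).
#'
#' @param results A `screen_results` object or combined hit tibble with
#'   `guide_id`, `Z`, `hit_class`.
#' @param library The guide library used for the screen.
#' @param truth The [sim_truth()] that generated the data.
#' @param overlap_min Minimum SRE overlap fraction defining a true guide.
#' @return One-row tibble `sensitivity`, `fpr_controls`, `sign_accuracy`,
#'   `n_true`, `n_controls` (`sensitivity`/`sign_accuracy` are `NA` when no
#'   guide qualifies).
#' @export
evaluate_recovery <- function(results, library, truth, overlap_min = 0.8) {
  if (inherits(results, "screen_results")) results <- results$combined
  ov <- guide_truth_overlap(library, truth)
  tab <- dplyr::left_join(ov,
                          dplyr::select(tibble::as_tibble(results),
                                        "guide_id", "Z", "hit_class"),
                          by = "guide_id")
  tab$called <- tab$hit_class %in% c("activator", "inhibitor")
  is_ctrl <- library$is_control[match(tab$guide_id, library$id)]
  true_set <- !is_ctrl & tab$overlap >= overlap_min
  sens <- if (any(true_set)) mean(tab$called[true_set]) else NA_real_
  called_true <- true_set & tab$called
  sign_acc <- if (any(called_true)) {
    mean(sign(tab$Z[called_true]) == tab$expected_sign[called_true])
  } else NA_real_
  tibble::tibble(
    sensitivity = sens,
    fpr_controls = if (any(is_ctrl)) mean(tab$called[is_ctrl]) else NA_real_,
    sign_accuracy = sign_acc,
    n_true = sum(true_set),
    n_controls = sum(is_ctrl)
  )
}
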