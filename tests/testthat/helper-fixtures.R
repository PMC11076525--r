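# Shared fixtures, all built in code.

# Small annotation with the canonical exon/intron labels:
# exon6 [0,10) intron6 [10,40) exon7 [40,60) intron7 [60,100) exon8 [100,110)
tiny_annotation <- function(seed = 42L) {
  reporter_annotation(
    random_dna(110L, seed = seed),
    data.frame(label = c("exon6", "intron6", "exon7", "intron7", "exon8"),
               start = c(0L, 10L, 40L, 60L, 100L),
               end = c(10L, 40L, 60L, 100L, 110L))
  )
}

tiny_library <- function(seed = 42L, n_controls = 5L) {
  design_guide_library(tiny_annotation(seed), lengths = c(22L, 25L),
                       step = 1L, n_controls = n_controls, seed = seed)
}

# Random count table with plausible totals for statistics tests.
random_count_table <- function(n_guides = 50L, seed = 7L,
                               reporter = "DUAL_IN", replicate_id = "rep1") {
  set.seed(seed)
  counts <- tibble::tibble(
    guide_id = sprintf("g%03d", seq_len(n_guides)),
    n_unsorted = rpois(n_guides, 400),
    n_top = rpois(n_guides, 400),
    n_bottom = rpois(n_guides, 400)
  )
  bin_count_table(counts, replicate_id = replicate_id, reporter = reporter)
}

# Event table with exact intensities for FACS tests.
facs_events <- function(tdtomato, egfp, bfp = 1000, viable = TRUE) {
  tibble::tibble(egfp = egfp, tdtomato = tdtomato,
                 bfp = rep_len(bfp, length(egfp)),
                 viable = rep_len(viable, length(egfp)))
}

# Small simulation setup used by several integration tests.
small_sim_setup <- function(seed = 3L, n_controls = 40L) {
  ann <- demo_annotation(seed = seed)
  lib <- design_guide_library(ann, n_controls = n_controls, seed = seed)
  truth <- sim_truth()
  list(annotation = ann, library = lib, truth = truth)
}

# Reduced-scale config for fast integration tests (full-scale defaults are
# exercised in the acceptance suite).
small_sim_config <- function(...) {
  sim_config(cells_per_guide = 200L, reads_per_bin = 2e5, ...)
}
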