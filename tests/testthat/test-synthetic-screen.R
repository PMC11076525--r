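test_that("ground-truth PSI follows the logit overlap model", {
  ann <- tiny_annotation()
  lib <- design_guide_library(ann, n_controls = 2L)
  # one silencer exactly under the effective footprint of some guide
  truth <- sim_truth(region_length = 110L,
                     sres = tibble::tibble(start = 63L, end = 85L,
                                           effect = -2, kind = "silencer"),
                     baseline_psi = 0.4, potency = c("22" = 1, "25" = 1),
                     anchor_width = 22L)
  psis <- guide_effects(lib, truth)
  # controls sit at baseline
  expect_equal(psis$psi[lib$is_control], rep(0.4, 2))
  # a guide with zero overlap sits at baseline
  far <- lib$id[!lib$is_control & lib$target_end <= 60][1]
  expect_equal(psis$psi[psis$guide_id == far], 0.4)
  # a 22-nt guide whose footprint covers the whole silencer: logit shift +2
  full_cov <- lib$id[!lib$is_control & lib$length == 22 &
                       lib$target_start == 63][1]
  expect_equal(psis$psi[psis$guide_id == full_cov],
               1 / (1 + exp(-(log(0.4 / 0.6) + 2))), tolerance = 1e-12)
  expect_equal(psis$psi[psis$guide_id == full_cov], 0.8312, tolerance = 1e-4)
})

test_that("higher potency gives at least as large a PSI shift", {
  ann <- tiny_annotation()
  lib <- design_guide_library(ann, n_controls = 0L)
  truth <- sim_truth(region_length = 110L,
                     sres = tibble::tibble(start = 63L, end = 85L,
                                           effect = -2, kind = "silencer"),
                     potency = c("22" = 0.7, "25" = 1))
  psis <- guide_effects(lib, truth)
  tab <- dplyr::inner_join(tibble::as_tibble(lib), psis,
                           by = c(id = "guide_id"))
  # 25-nt and 22-nt guides sharing the same effective footprint (same end)
  g22 <- dplyr::filter(tab, length == 22, target_end == 85)
  g25 <- dplyr::filter(tab, length == 25, target_end == 85)
  expect_gt(abs(g25$psi - 0.4), abs(g22$psi - 0.4))
})

test_that("noiseless cells separate perfectly and flip with the reporter", {
  psis <- tibble::tibble(guide_id = c("hi", "lo"), psi = c(0.8, 0.2))
  config <- sim_config(cells_per_guide = 100L, fluor_noise_sd = 0,
                       viable_frac = 1)
  cells_in <- simulate_cells(psis, config, "DUAL_IN", seed = 4L)
  m <- log2(cells_in$tdtomato) - log2(cells_in$egfp)
  expect_gt(min(m[cells_in$guide_id == "hi"]), max(m[cells_in$guide_id == "lo"]))
  cells_ex <- simulate_cells(psis, config, "DUAL_EX", seed = 4L)
  m_ex <- log2(cells_ex$tdtomato) - log2(cells_ex$egfp)
  expect_lt(max(m_ex[cells_ex$guide_id == "hi"]),
            min(m_ex[cells_ex$guide_id == "lo"]))
  # determinism under a fixed seed
  again <- simulate_cells(psis, config, "DUAL_IN", seed = 4L)
  expect_identical(cells_in, again)
  # invalid PSI rejected
  expect_error(simulate_cells(tibble::tibble(guide_id = "g", psi = 1),
                              config, "DUAL_IN"), "inside")
})

test_that("sorting collects the extreme quantiles and sequencing conserves reads", {
  setup <- small_sim_setup()
  psis <- guide_effects(setup$library, setup$truth)
  config <- small_sim_config()
  cells <- simulate_cells(psis, config, "DUAL_IN", seed = 5L)
  tab <- sort_and_sequence(cells, config, replicate_id = "IN1",
                           reporter = "DUAL_IN", seed = 6L)
  totals <- attr(tab, "totals")
  expect_equal(unname(totals), rep(config$reads_per_bin, 3))
  expect_equal(sum(tab$n_top) + attr(tab, "unassigned")[["top"]],
               totals[["top"]])
  bc <- attr(tab, "bin_cells")
  gated <- sum(cells$viable & cells$bfp >= config$bfp_threshold)
  expect_equal(sum(bc$cells_top), floor(config$sort_fraction * gated))
  expect_equal(sum(bc$cells_bottom), floor(config$sort_fraction * gated))
  expect_equal(sum(bc$cells_unsorted), gated)
  # a guide with PSI far above baseline is overrepresented in the top bin
  strong <- psis$guide_id[which.max(psis$psi)]
  i <- match(strong, bc$guide_id)
  expect_gt(bc$cells_top[i] / sum(bc$cells_top),
            bc$cells_unsorted[i] / sum(bc$cells_unsorted))
})

test_that("null composition: top-bin shares stay within multinomial bounds", {
  setup <- small_sim_setup()
  truth0 <- sim_truth(sres = setup$truth$sres[0, ])
  psis <- guide_effects(setup$library, truth0)
  config <- small_sim_config()
  cells <- simulate_cells(psis, config, "DUAL_IN", seed = 12L)
  tab <- sort_and_sequence(cells, config, seed = 13L)
  n_g <- nrow(setup$library)
  p0 <- 1 / n_g
  # cell-level sampling widens the spread beyond pure multinomial read
  # noise, so use a crude extreme-value bound rather than per-guide 4-sigma
  share <- tab$n_top / sum(tab$n_top)
  expect_lt(abs(mean(share) - p0), 1e-12)
  expect_lt(max(share) / p0, 8)
  expect_gt(cor(tab$n_top, tab$n_unsorted), -0.2)
})

test_that("the full simulated screen is deterministic under a fixed seed", {
  setup <- small_sim_setup()
  config <- small_sim_config()
  s1 <- simulate_screen(setup$library, setup$truth, config, seed = 21L)
  s2 <- simulate_screen(setup$library, setup$truth, config, seed = 21L)
  expect_identical(purrr::map(s1, tibble::as_tibble),
                   purrr::map(s2, tibble::as_tibble))
})

test_that("simulator FASTQ -> count_spacers reproduces the count table exactly", {
  ann <- tiny_annotation()
  lib <- design_guide_library(ann, n_controls = 4L, seed = 2L)
  truth <- sim_truth(region_length = 110L,
                     sres = tibble::tibble(start = 63L, end = 85L,
                                           effect = -2, kind = "silencer"))
  config <- sim_config(cells_per_guide = 50L, reads_per_bin = 3000)
  psis <- guide_effects(lib, truth)
  cells <- simulate_cells(psis, config, "DUAL_IN", seed = 31L)
  tab <- sort_and_sequence(cells, config, seed = 32L)
  dir <- withr::local_tempdir()
  paths <- write_bin_fastq(tab, lib, dir)
  counted <- count_replicate(paths[["unsorted"]], paths[["top"]],
                             paths[["bottom"]], lib)
  expect_equal(tibble::as_tibble(counted), tibble::as_tibble(tab),
               ignore_attr = TRUE)
  expect_equal(unname(attr(counted, "unassigned")), rep(0L, 3))
})

test_that("recovery evaluation on injected perfect and null results", {
  setup <- small_sim_setup()
  lib <- setup$library
  truth <- setup$truth
  ov <- guide_truth_overlap(lib, truth)
  # perfect results: huge |Z| of the expected sign on true guides
  res <- tibble::tibble(
    guide_id = lib$id,
    Z = ifelse(ov$overlap >= 0.8, ov$expected_sign * 50, 0),
    hit_class = ifelse(ov$overlap >= 0.8,
                       ifelse(ov$expected_sign > 0, "activator", "inhibitor"),
                       "none")
  )
  ev <- evaluate_recovery(res, lib, truth, overlap_min = 0.8)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$sign_accuracy, 1)
  expect_equal(ev$fpr_controls, 0)
  expect_gt(ev$n_true, 0)
  # no-SRE truth: sensitivity undefined
  truth0 <- sim_truth(sres = truth$sres[0, ])
  ev0 <- evaluate_recovery(res, lib, truth0, overlap_min = 0.8)
  expect_true(is.na(ev0$sensitivity))
})

test_that("stronger effects raise the median |Z| of overlapping guides", {
  ann <- demo_annotation(seed = 3L)
  lib <- design_guide_library(ann, n_controls = 40L, seed = 3L)
  config <- small_sim_config()
  med_z <- purrr::map_dbl(c(0.8, 1.6, 3.2), function(eff) {
    truth <- sim_truth(sres = tibble::tibble(start = 344L, end = 369L,
                                             effect = -eff, kind = "silencer"))
    tabs <- simulate_screen(lib, truth, config, seed = 77L)
    res <- analyze_screen(tabs, library = lib)
    ov <- guide_truth_overlap(lib, truth)
    zz <- res$combined$Z[match(ov$guide_id[ov$overlap >= 0.8],
                               res$combined$guide_id)]
    median(abs(zz), na.rm = TRUE)
  })
  expect_true(all(diff(med_z) > 0))
})
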