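test_that("quantifiability filter applies both thresholds inclusively", {
  expect_true(quantifiable(5, 5, 20, 1))
  expect_false(quantifiable(4, 1000, 19, 5000))  # count threshold is a conjunct
  expect_false(quantifiable(1000, 4, 5000, 19))
  expect_false(quantifiable(5, 5, 19, 19.9))     # RPM needed in at least one
  expect_true(quantifiable(5, 5, 19, 20))
  expect_false(quantifiable(0, 0, 0, 0))
})

test_that("enrichment score matches hand arithmetic in both modes", {
  # per_guide: r = 30/40 = 0.75, r0 = 0.5, s = sqrt(.75*.25/40)
  e <- enrichment_score(30, 10, 1e6, 1e6, mode = "per_guide")
  expect_equal(e, (0.75 - 0.5) / sqrt(0.75 * 0.25 / 40), tolerance = 1e-12)
  expect_equal(e, 3.6515, tolerance = 1e-4)
  # independent check: e is the one-sample proportion z-statistic with the
  # estimated (not null) variance
  expect_equal(e, (0.75 - 0.5) / sqrt(0.75 * (1 - 0.75) / 40))
  # null case: counts in exact proportion to totals
  expect_equal(enrichment_score(50, 100, 1e6, 2e6), 0)
  # as_printed: r = 30/2000, r0 = 0.5
  ep <- enrichment_score(30, NA, 1000, 1000, mode = "as_printed")
  r <- 30 / 2000
  expect_equal(ep, (r - 0.5) / sqrt(r * (1 - r) / 2000), tolerance = 1e-12)
  expect_equal(ep, -178.44, tolerance = 1e-3)
  # degenerate proportions are missing, with zero-count guides undefined
  expect_true(is.na(enrichment_score(0, 0, 1e6, 1e6)))
  expect_true(is.na(enrichment_score(10, 0, 1e6, 1e6)))  # r = 1 -> s = 0
})

test_that("per_guide enrichment is monotone in the bin count", {
  e <- enrichment_score(1:200, 50, 1e6, 1e6)
  expect_true(all(diff(e) > 0))
})

test_that("robust Z uses median and MAD/0.6745", {
  out <- robust_z(c(1, 2, 3, 4, 100))
  expect_equal(out$stats$m, 3)
  expect_equal(out$stats$sigma, 1 / 0.6745, tolerance = 1e-12)
  expect_equal(out$z[5], 97 * 0.6745, tolerance = 1e-12)
  expect_equal(out$z[5], 65.4265, tolerance = 1e-4)
  # location invariance
  e <- rnorm(20)
  expect_equal(robust_z(e + 7)$z, robust_z(e)$z, tolerance = 1e-12)
  # antisymmetry for a distribution symmetric about its median
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(robust_z(sym)$z, -rev(robust_z(rev(-sym))$z))
  # degenerate cases error
  expect_error(robust_z(c(1, NA)), "at least 2")
  expect_error(robust_z(rep(1, 10)), "MAD")
})

test_that("per-replicate Stouffer combination", {
  expect_equal(replicate_z(2, -2, 1, 1), 4 / sqrt(2))
  expect_equal(replicate_z(2, NA, 1, 0), 2)
  expect_equal(replicate_z(NA, 3, 0, 1), -3)
  expect_true(is.na(replicate_z(NA, NA, 0, 0)))
})

test_that("cross-replicate combination follows the signed Stouffer sum", {
  mk <- function(z_t, z_b, reporter, id) {
    structure(tibble::tibble(guide_id = "g", z_top = z_t, z_bottom = z_b,
                             w_top = 1L, w_bottom = 1L),
              reporter = reporter, replicate_id = id)
  }
  reps <- list(mk(3, -3, "DUAL_IN", "IN1"), mk(3, -3, "DUAL_IN", "IN2"),
               mk(-3, 3, "DUAL_EX", "EX1"), mk(-3, 3, "DUAL_EX", "EX2"))
  comb <- combine_replicates(reps)
  expect_equal(comb$W, 8L)
  expect_equal(comb$Z, 24 / sqrt(8))
  # single quantifiable bin passes through
  one <- combine_replicates(list(
    structure(tibble::tibble(guide_id = "g", z_top = 2, z_bottom = NA,
                             w_top = 1L, w_bottom = 0L),
              reporter = "DUAL_IN", replicate_id = "IN1")))
  expect_equal(one$Z, 2)
  expect_equal(one$W, 1L)
  # all-zero z with full W
  zero <- combine_replicates(purrr::map(
    c("IN1", "IN2", "EX1", "EX2"),
    ~ structure(tibble::tibble(guide_id = "g", z_top = 0, z_bottom = 0,
                               w_top = 1L, w_bottom = 1L),
                reporter = if (grepl("IN", .x)) "DUAL_IN" else "DUAL_EX",
                replicate_id = .x)))
  expect_equal(zero$Z, 0)
  expect_equal(zero$W, 8L)
})

test_that("hit calling: p-values, BH over the W-filtered set, classes", {
  comb <- tibble::tibble(
    guide_id = c("a", "b", "c", "d", "e"),
    Z = c(0, 1.959964, 8, -8, 5),
    W = c(8L, 8L, 8L, 8L, 2L)
  )
  hits <- call_hits(comb, fdr_threshold = 0.01)
  expect_equal(hits$p[1], 1)
  expect_equal(hits$p[2], 0.05, tolerance = 1e-6)
  # the W < 4 guide carries no p/fdr/class
  expect_true(is.na(hits$p[5]) && is.na(hits$fdr[5]) && is.na(hits$hit_class[5]))
  # BH computed over exactly the filtered set (4 guides, not 5)
  expect_equal(hits$fdr[1:4],
               p.adjust(hits$p[1:4], method = "BH"))
  expect_equal(hits$hit_class[3], "activator")
  expect_equal(hits$hit_class[4], "inhibitor")
  expect_equal(hits$hit_class[1], "none")
  # textbook BH example
  expect_equal(p.adjust(c(0.001, 0.02, 0.03, 0.5), method = "BH"),
               c(0.004, 0.04, 0.04, 0.5))
  expect_warning(call_hits(tibble::tibble(guide_id = "a", Z = 1, W = 1L)),
                 "no guides")
})

test_that("swapping top and bottom counts negates Z exactly", {
  tabs <- purrr::imap(c(IN1 = "DUAL_IN", IN2 = "DUAL_IN",
                        EX1 = "DUAL_EX", EX2 = "DUAL_EX"),
                      function(rep_, id) {
                        random_count_table(40L, seed = match(id, c("IN1", "IN2", "EX1", "EX2")),
                                           reporter = rep_, replicate_id = id)
                      })
  res <- analyze_screen(tabs)
  swapped <- purrr::map(tabs, function(tab) {
    bin_count_table(
      dplyr::mutate(tibble::as_tibble(tab), tmp = n_top, n_top = n_bottom,
                    n_bottom = tmp, tmp = NULL),
      replicate_id = attr(tab, "replicate_id"),
      reporter = attr(tab, "reporter"))
  })
  res_sw <- analyze_screen(swapped)
  expect_equal(res_sw$combined$Z, -res$combined$Z, tolerance = 1e-12)
  expect_equal(res_sw$combined$W, res$combined$W)
})

test_that("relabeling a replicate's reporter while swapping its bins leaves Z unchanged", {
  tabs <- purrr::imap(c(IN1 = "DUAL_IN", IN2 = "DUAL_IN",
                        EX1 = "DUAL_EX", EX2 = "DUAL_EX"),
                      function(rep_, id) {
                        random_count_table(40L, seed = 10 + match(id, c("IN1", "IN2", "EX1", "EX2")),
                                           reporter = rep_, replicate_id = id)
                      })
  res <- analyze_screen(tabs)
  flipped <- tabs
  flipped$IN1 <- bin_count_table(
    dplyr::mutate(tibble::as_tibble(tabs$IN1), tmp = n_top, n_top = n_bottom,
                  n_bottom = tmp, tmp = NULL),
    replicate_id = "IN1", reporter = "DUAL_EX")
  res_fl <- analyze_screen(flipped)
  expect_equal(res_fl$combined$Z, res$combined$Z, tolerance = 1e-12)
  expect_equal(res_fl$combined$W, res$combined$W)
})

test_that("tidy and glance summarize a screen analysis", {
  tabs <- purrr::imap(c(IN1 = "DUAL_IN", EX1 = "DUAL_EX"),
                      function(rep_, id) {
                        random_count_table(30L, seed = match(id, c("IN1", "EX1")),
                                           reporter = rep_, replicate_id = id)
                      })
  res <- analyze_screen(tabs)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("guide_id", "Z", "W", "p", "fdr", "hit_class") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_guides, 30L)
  expect_equal(gl$n_replicates, 2L)
  expect_equal(gl$n_hits, gl$n_activators + gl$n_inhibitors)
})
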