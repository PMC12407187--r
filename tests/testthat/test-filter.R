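# Independently coded statement of the published filtering rules, used as a
# truth-table oracle against the implementation.
oracle_pass <- function(cd, cc, dd, gap_mode = "both") {
  on_ok <- cd$rmsd < 2.0 && cd$pae_interaction < 10 && cd$plddt > 90
  off <- function(r) r$rmsd < 2.0 && r$pae_interaction < 10 && r$plddt > 95
  gap_cc <- cc$pae_interaction - cd$pae_interaction > 10
  gap_dd <- dd$pae_interaction - cd$pae_interaction > 10
  gap_ok <- if (gap_mode == "both") gap_cc && gap_dd else gap_cc || gap_dd
  on_ok && !off(cc) && !off(dd) && gap_ok
}

test_that("worked examples evaluate as expected", {
  v <- evaluate_design(metric_record("d", "CD", 1.0, 5, 95),
                       metric_record("d", "CC", 5.0, 25, 70),
                       metric_record("d", "DD", 6.0, 28, 60))
  expect_true(v$passed)
  expect_length(v$reasons[[1]], 0)

  v2 <- evaluate_design(metric_record("d", "CD", 1.0, 5, 95),
                        metric_record("d", "CC", 1.5, 8, 96),
                        metric_record("d", "DD", 6.0, 28, 60))
  expect_false(v2$passed)
  expect_setequal(v2$reasons[[1]], c("off_target_CC_predicted", "gap_fail"))

  # boundary values fail under the strict inequalities
  v3 <- evaluate_design(metric_record("d", "CD", 2.0, 5, 95),
                        metric_record("d", "CC", 5.0, 25, 70),
                        metric_record("d", "DD", 6.0, 28, 60))
  expect_false(v3$passed)
  expect_true("on_target_fail" %in% v3$reasons[[1]])

  expect_error(evaluate_design(metric_record("a", "CD", 1, 5, 95),
                               metric_record("b", "CC", 5, 25, 70),
                               metric_record("a", "DD", 6, 28, 60)),
               "different designs")
  expect_error(evaluate_design(metric_record("a", "CC", 1, 5, 95),
                               metric_record("a", "CC", 5, 25, 70),
                               metric_record("a", "DD", 6, 28, 60)),
               "mislabeled")
})

test_that("the filter equals the truth-table oracle on boundary-straddling records", {
  # six binary axes: three on-target conditions, the two off-target
  # predictions and the gap configuration
  cd_rmsd <- c(1.5, 2.0); cd_pae <- c(5, 10); cd_plddt <- c(95, 90)
  cc_opts <- list(ok = c(1.0, 8, 96), no = c(3.0, 25, 70))
  dd_opts <- cc_opts
  for (r in cd_rmsd) for (p in cd_pae) for (l in cd_plddt)
    for (cc_i in names(cc_opts)) for (dd_i in names(dd_opts))
      for (gm in c("both", "any")) {
        cd <- metric_record("x", "CD", r, p, l)
        cc <- metric_record("x", "CC", cc_opts[[cc_i]][1],
                            cc_opts[[cc_i]][2], cc_opts[[cc_i]][3])
        dd <- metric_record("x", "DD", dd_opts[[dd_i]][1],
                            dd_opts[[dd_i]][2], dd_opts[[dd_i]][3])
        v <- evaluate_design(cd, cc, dd, gap_mode = gm)
        expect_identical(v$passed, oracle_pass(cd, cc, dd, gm))
        expect_identical(v$passed, length(v$reasons[[1]]) == 0)
        # pure function: re-evaluation is identical
        expect_identical(v, evaluate_design(cd, cc, dd, gap_mode = gm))
      }
})

test_that("relaxing thresholds never shrinks the passing set", {
  withr::local_seed(21)
  n <- 40
  recs <- dplyr::bind_rows(
    tibble::tibble(design_id = sprintf("d%02d", 1:n), interface = "CD",
                   rmsd = runif(n, 0, 4), pae_interaction = runif(n, 0, 20),
                   plddt = runif(n, 70, 100)),
    tibble::tibble(design_id = sprintf("d%02d", 1:n), interface = "CC",
                   rmsd = runif(n, 0, 4), pae_interaction = runif(n, 0, 30),
                   plddt = runif(n, 70, 100)),
    tibble::tibble(design_id = sprintf("d%02d", 1:n), interface = "DD",
                   rmsd = runif(n, 0, 4), pae_interaction = runif(n, 0, 30),
                   plddt = runif(n, 70, 100)))
  strict <- filter_batch(recs)
  relaxed_th <- filter_thresholds(on_rmsd_max = 3, on_pae_max = 15,
                                  on_plddt_min = 80, off_rmsd_max = 1,
                                  off_pae_max = 5, off_plddt_min = 99,
                                  pae_gap_min = 5)
  relaxed <- filter_batch(recs, relaxed_th)
  passed_strict <- strict$design_id[which(strict$passed)]
  passed_relaxed <- relaxed$design_id[which(relaxed$passed)]
  expect_true(all(passed_strict %in% passed_relaxed))
})

test_that("batch filtering summarizes and isolates malformed designs", {
  good_cd <- function(id) metric_record(id, "CD", 1.0, 5, 95)
  bad_cd <- function(id) metric_record(id, "CD", 3.0, 5, 95)
  off_cc <- function(id) metric_record(id, "CC", 5.0, 25, 70)
  off_dd <- function(id) metric_record(id, "DD", 6.0, 28, 60)
  recs <- dplyr::bind_rows(
    lapply(sprintf("p%d", 1:3),
           function(id) dplyr::bind_rows(good_cd(id), off_cc(id), off_dd(id))),
    lapply(sprintf("f%d", 1:7),
           function(id) dplyr::bind_rows(bad_cd(id), off_cc(id), off_dd(id))))
  out <- filter_batch(recs)
  expect_equal(nrow(out), 10)
  expect_equal(out$design_id, sort(out$design_id))
  g <- glance(out)
  expect_equal(g$n_passed, 3)
  expect_equal(g$on_target_fail, 7)

  empty <- filter_batch(recs[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(glance(empty)$n_passed, 0)

  dup <- dplyr::bind_rows(good_cd("z"), good_cd("z"), off_cc("z"), off_dd("z"))
  out_dup <- filter_batch(dup)
  expect_true(is.na(out_dup$passed))
  expect_match(out_dup$error, "expected one row")

  missing <- dplyr::bind_rows(good_cd("m"), off_cc("m"))
  out_m <- filter_batch(missing)
  expect_true(is.na(out_m$passed))
})

test_that("0-1 scaled pLDDT tables are detected and rescaled", {
  recs <- dplyr::bind_rows(
    metric_record("s", "CD", 1.0, 5, 95),
    metric_record("s", "CC", 5.0, 25, 70),
    metric_record("s", "DD", 6.0, 28, 60))
  recs$plddt <- recs$plddt / 100
  expect_warning(out <- filter_batch(recs), "0-1 scaled")
  expect_true(out$passed)
})

test_that("extension designs pass only strictly inside both thresholds", {
  expect_true(evaluate_extension_design(95, 1.0))
  expect_false(evaluate_extension_design(90, 1.0))
  expect_false(evaluate_extension_design(95, 1.5))
  expect_equal(evaluate_extension_design(c(95, 90, 95), c(1.0, 1.0, 1.5)),
               c(TRUE, FALSE, FALSE))
  expect_error(evaluate_extension_design(NaN, 1), "finite")
})

test_that("metric tables and verdicts read and write", {
  recs <- dplyr::bind_rows(
    metric_record("t1", "CD", 1.0, 5, 95),
    metric_record("t1", "CC", 5.0, 25, 70),
    metric_record("t1", "DD", 6.0, 28, 60))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(recs, f)
  back <- read_metric_table(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(recs))
  out <- filter_batch(back)
  fv <- withr::local_tempfile(fileext = ".tsv")
  write_verdicts(out, fv)
  expect_match(readLines(fv)[2], "t1\tTRUE")
})
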