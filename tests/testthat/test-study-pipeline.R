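test_that("shipped fixtures carry the normative summaries verbatim", {
  fx <- cl_behavioral_fixture()
  expect_equal(unlist(fx$norm[c("mean_x", "sd_x", "mean_y", "sd_y", "r")]),
               c(mean_x = 5.5, sd_x = 1.5, mean_y = 13.4, sd_y = 8.4,
                 r = 0.8))
  expect_equal(fx$norm$n, 12L)
  expect_equal(fx$diff_sd, 6.8)
  expect_equal(fx$frequency$mean, 1.3)
  expect_equal(fx$cases[["MN+"]]$ll, 10.4)
  expect_equal(fx$cases[["MN-"]]$cl, 32.5)

  rois <- cl_roi_fixtures()
  expect_setequal(names(rois), c("pre-SMA", "left PPC", "right PPC"))
  expect_equal(rois[["pre-SMA"]]$mni, c(4, -2, 52), ignore_attr = TRUE)
  expect_equal(rois[["left PPC"]]$mni, c(-37, -50, 33), ignore_attr = TRUE)
  expect_equal(rois[["right PPC"]]$mni, c(26, -44, 36), ignore_attr = TRUE)
  lppc <- rois[["left PPC"]]
  expect_equal(unlist(lppc$norm[c("mean_x", "sd_x", "mean_y", "sd_y", "r")]),
               c(mean_x = 0.36, sd_x = 0.4, mean_y = 0.91, sd_y = 0.66,
                 r = 0.82))
  expect_equal(lppc$cases[["MN+"]]$ll, 1.59)
  # values printed in the source but not reconstructible from rounded
  # inputs are shipped as annotations, never recomputed against
  expect_equal(fx$annotations$printed_rsdt_mn_minus$T, 0.6)
  expect_equal(fx$annotations$printed_frequency_comparison$Z_PCC, 1.46)
  expect_equal(rois[["pre-SMA"]]$annotations$printed_comparison$Z_PCC, 2.35)
})

test_that("behavioral report has one row per case test", {
  fx <- cl_behavioral_fixture()
  rep <- run_behavioral_analysis(fx$cases, fx$norm, diff_sd = fx$diff_sd)
  expect_equal(nrow(rep), 3L)  # 2 RSDT + 1 comparison
  expect_identical(names(rep), c("analysis", "case", "measure", "method",
                                 "statistic", "df", "p_two_tailed",
                                 "inputs_digest"))
  expect_true(all(rep$df == 11))
  expect_true(all(rep$p_two_tailed >= 0 & rep$p_two_tailed <= 1))
  expect_true(all(nchar(rep$inputs_digest) == 8L))

  withfreq <- run_behavioral_analysis(fx$cases, fx$norm,
                                      diff_sd = fx$diff_sd,
                                      frequency_norm = fx$frequency)
  expect_equal(nrow(withfreq), 4L)
  expect_true("drawing frequency" %in% withfreq$measure)
})

test_that("identical cases give a zero two-case comparison", {
  fx <- cl_behavioral_fixture()
  twin <- list(a = list(ll = 9, cl = 12), b = list(ll = 4, cl = 7))
  rep <- run_behavioral_analysis(twin, fx$norm)
  cmp <- rep[grepl("difference", rep$measure), ]
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_two_tailed, 1)
})

test_that("missing conditions are reported by case and condition", {
  fx <- cl_behavioral_fixture()
  broken <- list("MN+" = list(ll = 10.4), "MN-" = list(ll = 8, cl = 32.5))
  err <- tryCatch(run_behavioral_analysis(broken, fx$norm),
                  error = function(e) e)
  expect_s3_class(err, "cl_missing_condition")
  expect_match(conditionMessage(err), "MN\\+")
  expect_match(conditionMessage(err), "CL")

  ses <- generate_session(session_spec(seed = 4), trajectory_params(),
                          trajectory_params(), seed = 4)
  err2 <- tryCatch(condition_scores(ses[ses$condition != "CL", ]),
                   error = function(e) e)
  expect_s3_class(err2, "cl_missing_condition")
  expect_match(conditionMessage(err2), "CL")
})

test_that("ROI report covers every ROI, case and comparison", {
  rep <- run_roi_analysis()
  expect_equal(sum(grepl("RSDT", rep$method)), 6L)
  expect_equal(sum(grepl("comparison", rep$method)), 3L)
  expect_setequal(unique(rep$analysis), c("pre-SMA", "left PPC", "right PPC"))
  # null case: betas equal to the normative means
  rois <- cl_roi_fixtures()
  null_fx <- rois["left PPC"]
  null_fx[["left PPC"]]$cases <- list(
    "MN+" = list(ll = 0.36, cl = 0.91),
    "MN-" = list(ll = 0.36, cl = 0.91))
  nulls <- run_roi_analysis(null_fx)
  expect_equal(nulls$statistic, rep(0, 3))
  expect_equal(nulls$p_two_tailed, rep(1, 3))

  bad <- rois["pre-SMA"]
  bad[["pre-SMA"]]$roi <- "cerebellum"
  expect_error(run_roi_analysis(bad), class = "cl_invalid_parameter")
})

test_that("end-to-end run writes a complete deterministic report", {
  cfg <- list(seed = 5, out_dir = file.path(tempdir(), "cl_report_a"))
  res <- end_to_end(cfg)
  files <- list.files(res$out_dir)
  expect_true(all(c("behavioral_report.tsv", "roi_report.tsv",
                    "condition_scores.tsv", "run_log.txt") %in% files))
  expect_equal(nrow(res$behavioral), 4L)  # 2 RSDT + OI diff + frequency
  expect_equal(nrow(res$roi), 9L)
  log <- readLines(file.path(res$out_dir, "run_log.txt"))
  expect_true(any(grepl("seed: 5", log)))
  expect_true(any(grepl("package version", log)))

  cfg2 <- list(seed = 5, out_dir = file.path(tempdir(), "cl_report_b"))
  end_to_end(cfg2)
  for (f in c("behavioral_report.tsv", "roi_report.tsv",
              "condition_scores.tsv"))
    expect_identical(readBin(file.path(cfg$out_dir, f), "raw", 1e6),
                     readBin(file.path(cfg2$out_dir, f), "raw", 1e6))
  unlink(c(cfg$out_dir, cfg2$out_dir), recursive = TRUE)
})

test_that("end-to-end accepts a YAML study configuration", {
  yml <- tempfile(fileext = ".yaml")
  out <- file.path(tempdir(), "cl_report_yaml")
  writeLines(c(
    paste0("out_dir: ", out),
    "seed: 3",
    "roi: false",
    "cases:",
    "  patient:",
    "    coupling: 0.0",
    "    ovalization_ratio: 0.1",
    "  control:",
    "    coupling: 0.25"), yml)
  res <- end_to_end(yml)
  expect_null(res$roi)
  expect_setequal(unique(res$condition_scores$case), c("patient", "control"))
  ctrl <- res$condition_scores[res$condition_scores$case == "control", ]
  d_ctrl <- ctrl$oi[ctrl$condition == "CL"] - ctrl$oi[ctrl$condition == "LL"]
  expect_gt(d_ctrl, 15)  # coupled case shows the interference effect
  unlink(out, recursive = TRUE)
})
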