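# Study orchestration: determinism, the bending/contrast equivalence at the
# baseline contrast, refinement pooling, and report export.

tiny_cfg <- function(seed = 5, refine = FALSE, levels = 8) {
  study_config(bending_levels = levels, contrast_levels = "30_1000",
               refine = refine,
               params = dir_params(iterations = c(20, 12, 6)),
               bend_args = list(spacing = c(2.5, 2.5, 2.5)),
               shrink_args = list(spacing = c(2.5, 2.5, 2.5)),
               seed = seed)
}

test_that("identical config and seed reproduce the study bit for bit", {
  r1 <- run_bending_study(tiny_cfg())
  r2 <- run_bending_study(tiny_cfg())
  expect_identical(r1$table, r2$table)
})

test_that("the baseline contrast level reproduces the bending study", {
  cfg <- tiny_cfg()
  cfg$contrast_bending_levels <- cfg$bending_levels
  bend <- run_bending_study(cfg)
  contrast <- run_contrast_study(cfg)
  expect_equal(bend$table[setdiff(names(bend$table), "study")],
               contrast$table[setdiff(names(contrast$table), "study")])
})

test_that("study tables carry one report per configured condition", {
  cfg <- tiny_cfg(refine = TRUE)
  res <- run_bending_study(cfg)
  expect_length(res$reports, 2)  # nRR + RR for the single level
  conds <- unique(res$table[c("level", "refine")])
  expect_equal(nrow(conds), 2)
  sa <- spider_areas(res)
  expect_equal(nrow(sa), 2)
  expect_true(all(is.finite(sa$area)))
})

test_that("refinement pooling produces one Wilcoxon row per index", {
  # synthetic paired table exercising the pooling rule without a DIR run
  mk <- function(refine, vals)
    data.frame(item = paste0("s", 1:6), index = "DSC", value = vals,
               study = "bending", level = 25, contrast = "c", refine = refine)
  res <- structure(list(study = "bending",
                        table = rbind(mk(FALSE, c(.90, .91, .88, .92, .89, .90)),
                                      mk(TRUE, c(.95, .96, .93, .97, .94, .85))),
                        reports = list(), config = tiny_cfg()),
                   class = "dirqa_study_result")
  out <- compare_refinement(res, indices = "DSC")
  expect_equal(out$n, 6)
  expect_equal(out$method, "exact")
  expect_equal(out$p_value, wilcoxon_paired(
    c(.90, .91, .88, .92, .89, .90), c(.95, .96, .93, .97, .94, .85))$p_value)
})

test_that("export writes the documented file set with sensitivity flags", {
  dir <- withr::local_tempdir()
  res <- run_bending_study(tiny_cfg(refine = TRUE))
  sens <- data.frame(phantom = "bending", RM = 0.1, HD = 0.2, DD = 0.4,
                     R = 0.05, one_minus_DSC = 0.02)
  class(sens) <- c("sensitivity_table", "data.frame")
  paths <- export_report(res, dir, sensitivity = sens)
  expect_true(file.exists(file.path(dir, "bending_indices.csv")))
  expect_true(file.exists(file.path(dir, "bending_long.csv")))
  expect_true(file.exists(file.path(dir, "bending.json")))
  expect_true(file.exists(file.path(dir, "run.log")))
  wide <- utils::read.csv(file.path(dir, "bending_indices.csv"))
  expect_true(all(c("nRR", "RR", "exceeds_sensitivity") %in% names(wide)))
  expect_true(all(is.finite(wide$nRR)))
  # flag logic: below-sensitivity differences are not flagged
  row <- wide[wide$index == "DSC", ][1, ]
  expect_identical(row$exceeds_sensitivity,
                   abs(row$nRR - row$RR) > 0.02)
  js <- jsonlite::read_json(file.path(dir, "bending.json"))
  expect_equal(js$study, "bending")
  expect_equal(length(js$conditions), 2)
})

test_that("empty study tables export header-only CSVs", {
  dir <- withr::local_tempdir()
  empty <- structure(list(study = "bending", reports = list(),
                          table = data.frame(item = character(0),
                                             index = character(0),
                                             value = numeric(0),
                                             study = character(0),
                                             level = numeric(0),
                                             contrast = character(0),
                                             refine = logical(0)),
                          config = tiny_cfg()),
                     class = "dirqa_study_result")
  suppressWarnings(export_report(empty, dir))
  wide <- utils::read.csv(file.path(dir, "bending_indices.csv"))
  expect_equal(nrow(wide), 0)
})
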