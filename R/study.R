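# Orchestration of the four accuracy experiments: variable bending,
# variable contrast, shrinking volume, and the refine-vs-no-refine
# comparison with the pooled paired Wilcoxon test.

#' Study configuration
#'
#' @param bending_levels bending angles (degrees) registered onto the 0
#'   degree reference; study defaults 8, 16, 25.
#' @param contrast_levels names of the contrast levels to run (subset of
#'   `names(study_contrast_levels())`); the first one doubles as the
#'   baseline contrast of the bending study.
#' @param contrast_bending_levels bending angles used in the variable
#'   contrast test (default: the largest bending level, the condition the
#'   contrast comparison is reported at).
#' @param fills named list of `c(ref, tgt)` fill volumes (ml) defining the
#'   shrinking registrations; defaults reg1: 50 on 25, reg2: 50 on 0.
#' @param refine run each registration both without (`nRR`) and with (`RR`)
#'   box-based refinement.
#' @param params [dir_params()] for the stand-in DIR.
#' @param noise_sigma Gaussian image noise added to the raw volumes, HU.
#' @param seed master seed; all per-volume noise seeds derive from it.
#' @param bend_args,shrink_args extra arguments forwarded to
#'   [bending_phantom_spec()] / [shrinking_phantom_spec()] (e.g. a coarser
#'   `spacing` for quick runs).
#' @return A list of class `study_config`.
#' @export
study_config <- function(bending_levels = c(8, 16, 25),
                         contrast_levels = c("30_1000", "-100_40", "10_50"),
                         contrast_bending_levels = NULL,
                         fills = list(reg1 = c(ref = 25, tgt = 50),
                                      reg2 = c(ref = 0, tgt = 50)),
                         refine = TRUE,
                         params = dir_params(),
                         noise_sigma = 10,
                         seed = 17,
                         bend_args = list(), shrink_args = list()) {
  if (!length(bending_levels))
    stop("parameter error: need at least one bending level", call. = FALSE)
  if (is.null(contrast_bending_levels))
    contrast_bending_levels <- max(bending_levels)
  structure(list(bending_levels = bending_levels,
                 contrast_levels = contrast_levels,
                 contrast_bending_levels = contrast_bending_levels,
                 fills = fills, refine = isTRUE(refine), params = params,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 bend_args = bend_args, shrink_args = shrink_args),
            class = "study_config")
}

# derived per-volume noise seed, kept below 2^31
noise_seed <- function(config, k) {
  (as.numeric(config$seed) * 7919 + k) %% 2147483647
}

new_study_result <- function(reports, config, study) {
  tab <- do.call(rbind, lapply(reports, report_long))
  rownames(tab) <- NULL
  structure(list(study = study, reports = reports, table = tab,
                 config = config),
            class = "dirqa_study_result")
}

#' @export
print.dirqa_study_result <- function(x, ...) {
  cat("<dirqa_study_result> '", x$study, "': ", length(x$reports),
      " registration report(s)\n", sep = "")
  print(utils::head(x$table, 20), digits = 4)
  if (nrow(x$table) > 20) cat("... (", nrow(x$table), " rows)\n", sep = "")
  invisible(x)
}

# shared bending pipeline: one (angle, contrast, refine) condition.
# Raw noisy volumes are remapped with the contrast spec before
# registration, so scanner-like noise is compressed together with the
# material contrast exactly as a post-hoc HU rescale would do.
run_bending_condition <- function(ref_bundle, ref_noisy_raw, angle, cspec,
                                  cname, config) {
  args <- c(list(angle_deg = angle), config$bend_args)
  tgt_bundle <- do.call(bending_phantom_spec, args)
  tgt_bundle <- build_bending_phantom(tgt_bundle)
  tgt_noisy_raw <- add_noise(tgt_bundle$volume, config$noise_sigma,
                             noise_seed(config, round(angle * 100) + 1))
  ref_vol <- remap_contrast(ref_noisy_raw, cspec)
  tgt_vol <- remap_contrast(tgt_noisy_raw, cspec)

  anchor_names <- c("sphere1", "sphere3")
  anchors <- list(ref_bundle$landmarks[match(anchor_names,
                                             ref_bundle$landmarks$name), ],
                  tgt_bundle$landmarks[match(anchor_names,
                                             tgt_bundle$landmarks$name), ])
  init <- rigid_align(mode = "landmark", anchors = anchors)
  field <- deform_register(ref_vol, tgt_vol, init, config$params)
  reg_vol <- resample(tgt_vol, field)
  meta <- list(study = "bending", level = angle, contrast = cname,
               refine = FALSE)
  reports <- list(score_registration(ref_vol, reg_vol, field, ref_bundle,
                                     tgt_bundle, metadata = meta))
  if (config$refine) {
    boxes <- default_bending_boxes(tgt_bundle$spec)
    field_rr <- reg_refine(ref_vol, tgt_vol, field, boxes, config$params)
    reg_rr <- resample(tgt_vol, field_rr)
    meta$refine <- TRUE
    reports[[2]] <- score_registration(ref_vol, reg_rr, field_rr, ref_bundle,
                                       tgt_bundle, metadata = meta)
  }
  reports
}

bending_reference <- function(config) {
  args <- c(list(angle_deg = 0), config$bend_args)
  ref_bundle <- build_bending_phantom(do.call(bending_phantom_spec, args))
  ref_noisy_raw <- add_noise(ref_bundle$volume, config$noise_sigma,
                             noise_seed(config, 0))
  list(bundle = ref_bundle, noisy_raw = ref_noisy_raw)
}

contrast_spec_for <- function(config, cname) {
  args <- c(list(angle_deg = 0), config$bend_args)
  spec0 <- do.call(bending_phantom_spec, args)
  levels <- study_contrast_levels(hu_clay = as.numeric(spec0$hu["clay"]),
                                  hu_glass = as.numeric(spec0$hu["glass"]))
  if (!cname %in% names(levels))
    stop("parameter error: unknown contrast level '", cname, "'", call. = FALSE)
  levels[[cname]]
}

#' Run the variable-bending study
#'
#' Generates the straight reference and each bent variant, rigid-aligns on
#' spheres 1 and 3 (landmark mode), runs the stand-in DIR with and (if
#' configured) without box refinement, segments the spheres at 50% of the
#' maximum, and evaluates DSC/HD/DD/R per sphere plus RM per marker. Images
#' are remapped to the baseline (first configured) contrast level before
#' registration.
#'
#' @param config [study_config()].
#' @return A `dirqa_study_result`.
#' @export
run_bending_study <- function(config = study_config()) {
  cname <- config$contrast_levels[1]
  cspec <- contrast_spec_for(config, cname)
  ref <- bending_reference(config)
  reports <- list()
  for (angle in config$bending_levels)
    reports <- c(reports, run_bending_condition(ref$bundle, ref$noisy_raw,
                                                angle, cspec, cname, config))
  new_study_result(reports, config, "bending")
}

#' Run the variable-contrast study
#'
#' Remaps the raw noisy bending-study volumes with each configured contrast
#' level before registration; the downstream chain is identical to
#' [run_bending_study()], so the first contrast level reproduces the bending
#' study bit for bit under the same seed.
#'
#' @param config [study_config()].
#' @return A `dirqa_study_result`.
#' @export
run_contrast_study <- function(config = study_config()) {
  ref <- bending_reference(config)
  reports <- list()
  for (cname in config$contrast_levels) {
    cspec <- contrast_spec_for(config, cname)
    for (angle in config$contrast_bending_levels)
      reports <- c(reports, run_bending_condition(ref$bundle, ref$noisy_raw,
                                                  angle, cspec, cname, config))
  }
  new_study_result(reports, config, "contrast")
}

#' Run the shrinking-volume study
#'
#' Builds the phantom at each configured fill level, rigid-aligns each pair
#' on the bony structures (intensity metric restricted to bone), runs the
#' stand-in DIR (with and without the 25-box refinement near the changing
#' volume), and evaluates DSC/HD on the external contour and mandible over
#' the analysis ROI plus RM over the 8 internal markers. The fill-volume
#' difference of each registration is recorded in the report metadata.
#'
#' @param config [study_config()].
#' @return A `dirqa_study_result`.
#' @export
run_shrinking_study <- function(config = study_config()) {
  fill_levels <- sort(unique(unlist(config$fills)))
  bundles <- list(); noisy <- list()
  for (f in fill_levels) {
    args <- c(list(fill_ml = f), config$shrink_args)
    b <- build_shrinking_phantom(do.call(shrinking_phantom_spec, args))
    bundles[[as.character(f)]] <- b
    noisy[[as.character(f)]] <- add_noise(b$volume, config$noise_sigma,
                                          noise_seed(config, 5000 + f))
  }
  reports <- list()
  for (rn in names(config$fills)) {
    fr <- config$fills[[rn]]
    ref_b <- bundles[[as.character(fr[["ref"]])]]
    tgt_b <- bundles[[as.character(fr[["tgt"]])]]
    ref_vol <- noisy[[as.character(fr[["ref"]])]]
    tgt_vol <- noisy[[as.character(fr[["tgt"]])]]
    init <- rigid_align(ref_vol, tgt_vol, mode = "intensity",
                        mask = ref_b$mandible_mask, maxit = 120)
    field <- deform_register(ref_vol, tgt_vol, init, config$params)
    reg_vol <- resample(tgt_vol, field)
    vd <- abs(fr[["tgt"]] - fr[["ref"]])
    meta <- list(study = "shrinking", level = rn, contrast = "native",
                 refine = FALSE, volume_difference_ml = vd)
    reports <- c(reports, list(
      score_registration(ref_vol, reg_vol, field, ref_b, tgt_b,
                         metadata = meta)))
    if (config$refine) {
      boxes <- default_shrinking_boxes(ref_b$spec)
      field_rr <- reg_refine(ref_vol, tgt_vol, field, boxes, config$params)
      reg_rr <- resample(tgt_vol, field_rr)
      meta$refine <- TRUE
      reports <- c(reports, list(
        score_registration(ref_vol, reg_rr, field_rr, ref_b, tgt_b,
                           metadata = meta)))
    }
  }
  new_study_result(reports, config, "shrinking")
}

#' Pooled refine-vs-no-refine comparison
#'
#' Pools, across one or more study results, one paired observation per
#' (structure-or-marker, condition) present in both the refined and the
#' unrefined run, and applies the paired two-sided Wilcoxon signed-rank
#' test ([wilcoxon_paired()]) separately to each similarity index common to
#' both phantoms (DSC, HD, RM).
#'
#' @param ... `dirqa_study_result` objects (or a single list of them).
#' @param indices indices to test.
#' @return Data frame with columns index, n, statistic, p_value, method.
#' @export
compare_refinement <- function(..., indices = c("DSC", "HD", "RM")) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1]], "dirqa_study_result"))
    results <- results[[1]]
  tab <- do.call(rbind, lapply(results, function(r) r$table))
  if (is.null(tab$refine))
    stop("parameter error: results carry no refine flag", call. = FALSE)
  key <- interaction(tab$study, tab$level, tab$contrast, tab$item, tab$index,
                     drop = TRUE)
  out <- list()
  for (ix in indices) {
    sel <- tab$index == ix
    nrr <- tab[sel & !tab$refine, ]
    rr <- tab[sel & tab$refine, ]
    k_n <- interaction(nrr$study, nrr$level, nrr$contrast, nrr$item, drop = TRUE)
    k_r <- interaction(rr$study, rr$level, rr$contrast, rr$item, drop = TRUE)
    shared <- intersect(as.character(k_n), as.character(k_r))
    if (!length(shared)) next
    a <- nrr$value[match(shared, as.character(k_n))]
    b <- rr$value[match(shared, as.character(k_r))]
    res <- tryCatch(wilcoxon_paired(a, b), error = function(e) NULL)
    out[[ix]] <- data.frame(
      index = ix, n = length(shared),
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      method = if (is.null(res)) "insufficient data" else res$method,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Spider-graph areas per registration condition
#'
#' Mean HD, DD, R (over structures) and RM (over markers) per condition,
#' placed on the four conventional spider axes; conditions missing DD/R
#' (shrinking phantom) use the available axes.
#'
#' @param result `dirqa_study_result`.
#' @return Data frame with one row per (level, contrast, refine) condition
#'   and columns for the axis means and `area`.
#' @export
spider_areas <- function(result) {
  tab <- result$table
  if (is.null(tab) || !nrow(tab))
    return(data.frame(study = character(0), level = character(0),
                      contrast = character(0), refine = logical(0),
                      HD = numeric(0), DD = numeric(0), R = numeric(0),
                      RM = numeric(0), area = numeric(0)))
  key <- unique(tab[c("study", "level", "contrast", "refine")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- tab$study == key$study[i] & tab$level == key$level[i] &
      tab$contrast == key$contrast[i] & tab$refine == key$refine[i]
    m <- vapply(c("HD", "DD", "R", "RM"), function(ix) {
      v <- tab$value[sel & tab$index == ix]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    ax <- m[!is.na(m)]
    area <- if (length(ax) >= 3) spider_area(ax) else NA_real_
    cbind(key[i, , drop = FALSE],
          data.frame(HD = m[["HD"]], DD = m[["DD"]], R = m[["R"]],
                     RM = m[["RM"]], area = area))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
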