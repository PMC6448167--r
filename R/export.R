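# Study-result export: per-structure index tables in the nRR/RR layout with
# sensitivity flagging, spider-graph figures, machine-readable JSON and a
# run log.

#' Export a study result to files
#'
#' Writes, under `dir`: `<study>_indices.csv` (one row per structure/marker
#' and index with nRR and RR columns and a flag marking differences larger
#' than the phantom-matched sensitivity), `<study>_long.csv` (flat table),
#' `<study>_spider.csv` and `<study>_spider.png` (axis means and polygon
#' areas per condition), `<study>.json`, and `run.log`.
#'
#' @param result `dirqa_study_result`.
#' @param dir output directory (created if needed).
#' @param sensitivity optional `sensitivity_table` from
#'   [sensitivity_protocol()] used for the flag column; without it the flag
#'   is `NA`.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(result, dir, sensitivity = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, result$study)
  paths <- character(0)

  tab <- result$table
  long_path <- paste0(stem, "_long.csv")
  utils::write.csv(tab, long_path, row.names = FALSE)
  paths <- c(paths, long_path)

  wide <- export_wide_table(tab, sensitivity)
  wide_path <- paste0(stem, "_indices.csv")
  utils::write.csv(wide, wide_path, row.names = FALSE)
  paths <- c(paths, wide_path)

  sp <- spider_areas(result)
  sp_path <- paste0(stem, "_spider.csv")
  utils::write.csv(sp, sp_path, row.names = FALSE)
  paths <- c(paths, sp_path)
  fig <- paste0(stem, "_spider.png")
  ok <- tryCatch({ plot_spider(sp, fig); TRUE },
                 error = function(e) {
                   warning("spider figure skipped: ", conditionMessage(e),
                           call. = FALSE)
                   FALSE
                 })
  if (ok) paths <- c(paths, fig)

  js <- paste0(stem, ".json")
  jsonlite::write_json(
    list(study = result$study,
         seed = result$config$seed,
         conditions = lapply(result$reports, function(r)
           list(metadata = r$metadata, structures = r$structures,
                markers = r$markers, summary = r$summary)),
         spider = sp),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, js)

  log_path <- file.path(dir, "run.log")
  cat(sprintf("%s dirqa %s study: %d report(s), seed %d\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), result$study,
              length(result$reports), result$config$seed),
      file = log_path, append = TRUE)
  paths <- c(paths, log_path)
  invisible(paths)
}

# one row per (condition, item, index) with nRR/RR columns and the
# larger-than-sensitivity flag of the printed-table convention
export_wide_table <- function(tab, sensitivity = NULL) {
  if (!nrow(tab))
    return(data.frame(study = character(0), level = character(0),
                      contrast = character(0), item = character(0),
                      index = character(0), nRR = numeric(0), RR = numeric(0),
                      exceeds_sensitivity = logical(0)))
  key <- unique(tab[c("study", "level", "contrast", "item", "index")])
  rownames(key) <- NULL
  pick <- function(i, refine) {
    v <- tab$value[tab$study == key$study[i] & tab$level == key$level[i] &
                     tab$contrast == key$contrast[i] &
                     tab$item == key$item[i] & tab$index == key$index[i] &
                     tab$refine == refine]
    if (length(v)) v[1] else NA_real_
  }
  key$nRR <- vapply(seq_len(nrow(key)), pick, numeric(1), refine = FALSE)
  key$RR <- vapply(seq_len(nrow(key)), pick, numeric(1), refine = TRUE)
  key$exceeds_sensitivity <- NA
  if (!is.null(sensitivity)) {
    sens_of <- function(study, index) {
      row <- sensitivity[match(
        if (study %in% c("bending", "contrast")) "bending" else "shrinking",
        sensitivity$phantom), , drop = FALSE]
      if (!nrow(row) || all(is.na(row))) return(NA_real_)
      switch(index,
             DSC = row$one_minus_DSC, HD = row$HD, DD = row$DD, R = row$R,
             RM = row$RM, NA_real_)
    }
    s <- mapply(sens_of, key$study, key$index)
    key$exceeds_sensitivity <- abs(key$nRR - key$RR) > s
  }
  key
}

# radar plot of the per-condition axis means, one polygon per condition
plot_spider <- function(sp, path) {
  axes <- c("HD", "DD", "R", "RM")
  have <- axes[vapply(axes, function(a) any(is.finite(sp[[a]])), logical(1))]
  if (length(have) < 3)
    stop("need at least 3 finite axes for a spider figure")
  k <- length(have)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  rmax <- max(unlist(sp[have]), na.rm = TRUE) * 1.1 + 1e-9
  grDevices::png(path, width = 720, height = 720, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = "Similarity-index spider graph (mm)")
  for (fr in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(fr * rmax * cos(ang), fr * rmax * sin(ang),
                      border = "grey80")
  for (i in seq_len(k)) {
    graphics::segments(0, 0, rmax * cos(ang[i]), rmax * sin(ang[i]),
                       col = "grey60")
    graphics::text(1.05 * rmax * cos(ang[i]), 1.05 * rmax * sin(ang[i]),
                   have[i], xpd = NA)
  }
  cols <- grDevices::hcl.colors(max(nrow(sp), 2), "Dark 2")
  for (i in seq_len(nrow(sp))) {
    v <- unlist(sp[i, have])
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[i], lwd = 2)
  }
  lab <- apply(sp[c("level", "contrast", "refine")], 1, function(r)
    paste0(r[["level"]], "/", r[["contrast"]],
           if (as.logical(r[["refine"]])) "/RR" else "/nRR"))
  graphics::legend("topright", legend = lab, col = cols[seq_len(nrow(sp))],
                   lwd = 2, bty = "n", cex = 0.9)
  invisible(path)
}
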