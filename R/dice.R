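#' 2D Dice score between two binary masks
#'
#' \eqn{2|A\cap B| / (|A| + |B|)}. When both masks are empty the score is
#' defined as 1.0 (the structure is correctly absent); callers that need to
#' audit this convention can detect it via the `flagged_empty` column of
#' [evaluate_segmenter()] reports.
#'
#' @param pred_mask,gt_mask Logical/0-1 rasters on one grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(pred_mask, gt_mask) {
  assert_same_grid(pred_mask, gt_mask, "masks")
  a <- sum(pred_mask != 0)
  b <- sum(gt_mask != 0)
  if (a + b == 0) return(1.0)
  2 * sum(pred_mask != 0 & gt_mask != 0) / (a + b)
}

#' Extract a named structure mask from a label map
#'
#' `lv_endo`, `lv_myo`, `la` and `sector` are the raw classes; `lv_epi` is
#' the filled epicardial region, i.e. the union of the LV cavity and the
#' myocardial ring (the epicardial contour encloses both).
#'
#' @param label_map A `label_map`.
#' @param name Structure name.
#' @return Logical mask.
#' @export
structure_mask <- function(label_map, name) {
  cls <- echo_classes()
  lm <- unclass(label_map)
  switch(name,
         lv_endo = lm == cls[["lv_endo"]],
         lv_myo = lm == cls[["lv_myo"]],
         lv_epi = lm == cls[["lv_endo"]] | lm == cls[["lv_myo"]],
         la = lm == cls[["la"]],
         sector = lm == cls[["sector"]],
         abort(sprintf("unknown structure '%s'.", name)))
}

#' Evaluate a segmenter with per-case, per-label Dice scores
#'
#' Produces a Dice report in the usual results-table shape: one row per
#' (case, label) plus per-label mean and standard deviation and a per-case
#' mean. The headline labels default to LV endocardium, LV epicardium
#' (cavity + myocardium union) and left atrium; the sector class is part of
#' the training targets but excluded from the headline summary. If both a
#' training and a test manifest are supplied, they must be disjoint in
#' `source_id`/`case_id` — evaluating on training cases is an error.
#'
#' @param model A `seg_net` or `seg_fit`.
#' @param test List of entries with `image`, `label_map` and `meta`.
#' @param label_names Structures to score (see [structure_mask()]).
#' @param train_manifest,test_manifest Optional manifests for the
#'   disjointness check.
#' @return A `dice_report`: `rows` and `summary` tibbles plus metadata.
#' @export
evaluate_segmenter <- function(model, test,
                               label_names = c("lv_endo", "lv_epi", "la"),
                               train_manifest = NULL, test_manifest = NULL) {
  fit <- NULL
  if (inherits(model, "seg_fit")) {
    fit <- model
    model <- model$model
  }
  if (!is.null(train_manifest) && !is.null(test_manifest)) {
    idcol <- intersect(c("case_id", "source_id"), names(train_manifest))[1]
    shared <- intersect(unique(train_manifest[[idcol]]),
                        unique(test_manifest[[idcol]]))
    if (length(shared)) {
      abort(sprintf("evaluate_segmenter: test cases overlap training set: %s",
                    paste(head(shared, 10), collapse = ", ")))
    }
  }
  rows <- list()
  for (i in seq_along(test)) {
    e <- test[[i]]
    case <- e$meta$case_id %||% i
    pred <- if (is.function(model)) model(e$image) else seg_predict(model, e$image)
    for (nm in label_names) {
      pm <- structure_mask(pred, nm)
      gm <- structure_mask(e$label_map, nm)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        case_id = case, label_name = nm, dice = dice(pm, gm),
        flagged_empty = sum(pm) + sum(gm) == 0)
    }
  }
  rows <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(dplyr::group_by(rows, .data$label_name),
                              mean_dice = mean(.data$dice),
                              sd_dice = stats::sd(.data$dice),
                              n = dplyr::n(), .groups = "drop")
  per_case <- dplyr::summarise(dplyr::group_by(rows, .data$case_id),
                               case_mean = mean(.data$dice), .groups = "drop")
  structure(list(rows = rows, summary = summary, per_case = per_case,
                 label_names = label_names,
                 train_manifest_hash = if (!is.null(fit)) fit$train_manifest_hash
                 else NA_character_,
                 lv_epi_convention = "union of LV cavity and myocardial ring"),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("Dice report (per-label mean ± sd, %):\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-8s %5.1f ± %.2f  (n = %d)\n",
                x$summary$label_name[i], 100 * x$summary$mean_dice[i],
                100 * x$summary$sd_dice[i], x$summary$n[i]))
  }
  if (!is.na(x$train_manifest_hash)) {
    cat("  training manifest:", x$train_manifest_hash, "\n")
  }
  invisible(x)
}

#' Write a Dice report as CSV plus a rendered text table
#' @param report A `dice_report`.
#' @param path CSV path for the rows; a `*_table.txt` companion renders the
#'   per-label mean±std layout.
#' @export
write_dice_report <- function(report, path) {
  readr::write_csv(report$rows, path)
  tab <- paste0(
    "Label\tDice (%)\n",
    paste(sprintf("%s\t%.1f ± %.2f", report$summary$label_name,
                  100 * report$summary$mean_dice, 100 * report$summary$sd_dice),
          collapse = "\n"), "\n")
  writeLines(tab, sub("\\.csv$", "_table.txt", path))
  invisible(path)
}
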