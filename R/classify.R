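#' Classify a spirometry report end to end
#'
#' Orchestrates the full workflow: rasterize the first page, parse the
#' demographics (text layer or sidecar CSV), build the graphical construct,
#' compute the risk that the manoeuvre is unacceptable, apply the decision
#' threshold (risk at or above the threshold is labelled
#' `"Unacceptable Test"`), and optionally write a Grad-CAM overlay. Stage
#' failures are re-raised with the stage name attached.
#'
#' @param report Path to the report file (PNG/TIFF/JPEG).
#' @param classifier A fitted `spiro_classifier` or a checkpoint path.
#' @param threshold Decision threshold in `[0, 1]` (e.g. the output of
#'   [select_threshold()] on validation predictions).
#' @param sidecar Optional demographics sidecar CSV (`path,sex,age,bmi`);
#'   used when the report has no text layer.
#' @param explain Write a Grad-CAM overlay PNG next to the record?
#' @param out_dir Directory for the record JSON and overlay PNG; `NULL`
#'   writes nothing.
#' @return A `classification_record` list: `report`, `risk`, `threshold`,
#'   `label` (`"Acceptable Test"` / `"Unacceptable Test"`), `construct_png`,
#'   `overlay_png`, `timestamp`.
#' @export
classify_report <- function(report, classifier, threshold, sidecar = NULL,
                            explain = FALSE, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(classifier))
    classifier <- stage("load-model", load_classifier(classifier))
  stopifnot(threshold >= 0, threshold <= 1)
  page <- stage("ingest", rasterize_first_page(report))
  demo <- stage("demographics", {
    if (!is.na(page$text)) parse_demographics(page)
    else if (!is.null(sidecar)) read_sidecar(sidecar, report)
    else stop("missing-field error: no text layer and no sidecar given",
              call. = FALSE)
  })
  construct <- stage("construct", build_construct(page, demo))
  risk <- stage("predict", predict_risk(classifier, construct))
  label <- if (risk >= threshold) "Unacceptable Test" else "Acceptable Test"

  construct_png <- overlay_png <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(basename(report))
    construct_png <- file.path(out_dir, paste0(stem, "_construct.png"))
    png::writePNG(construct$network_input[, , 1] / 255, construct_png)
  }
  if (explain) {
    hm <- stage("explain", grad_cam(classifier, construct))
    if (!is.null(out_dir)) {
      overlay_png <- file.path(out_dir,
                               paste0(tools::file_path_sans_ext(
                                 basename(report)), "_gradcam.png"))
      png::writePNG(overlay_heatmap(construct, hm), overlay_png)
    }
  }
  record <- list(report = report, risk = unname(risk), threshold = threshold,
                 label = label, construct_png = construct_png,
                 overlay_png = overlay_png,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(record) <- "classification_record"
  if (!is.null(out_dir)) {
    json <- file.path(out_dir, paste0(tools::file_path_sans_ext(
      basename(report)), "_record.json"))
    jsonlite::write_json(unclass(record), json, auto_unbox = TRUE,
                         digits = NA)
  }
  record
}

#' @export
print.classification_record <- function(x, ...) {
  cat("<classification_record> ", basename(x$report), "\n",
      "  risk = ", sprintf("%.3f", x$risk), " (threshold ",
      format(x$threshold), ") -> ", x$label, "\n", sep = "")
  invisible(x)
}
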