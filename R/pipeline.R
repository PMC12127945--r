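#' Default pipeline configuration
#'
#' Every tunable named by the stages, in one nested list. Values can be
#' overridden programmatically or loaded from YAML with [read_config].
#'
#' @param ... top-level overrides (replace whole sections).
#' @return nested configuration list of class `autoqc_config`.
#' @export
autoqc_config <- function(...) {
  cfg <- list(
    intensity = list(auto_window_probs = c(0.01, 0.99)),
    geometry = list(aspect_lower = 0.85, aspect_upper = 1.48,
                    pad_tol = 1 / 1024, collim_quantile = 0.05,
                    rotation_enabled = TRUE),
    annotation = list(intensity_thresh = 0.95, tophat_soft = 0.10,
                      tophat_hard = 0.25, tophat_brush = 7L,
                      min_height_frac = 0.01, max_height_frac = 0.10,
                      max_fill_ratio = 0.82, max_width_frac = 0.30,
                      dilate_px = 2L, max_mask_frac = 0.5),
    projection = list(threshold = 0.5, model_path = NULL),
    quality = list(thresholds = quality_thresholds()),
    evaluation = list(n_boot = 1000L)
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  structure(cfg, class = "autoqc_config")
}

#' @keywords internal
validate_config <- function(cfg) {
  need <- c("intensity", "geometry", "annotation", "projection", "quality",
            "evaluation")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) stop("config is missing sections: ",
                            paste(missing, collapse = ", "))
  g <- cfg$geometry
  if (!is.numeric(g$aspect_lower) || !is.numeric(g$aspect_upper) ||
      g$aspect_lower <= 0 || g$aspect_lower >= g$aspect_upper) {
    stop("geometry aspect bounds must satisfy 0 < lower < upper")
  }
  if (!is.numeric(cfg$evaluation$n_boot) || cfg$evaluation$n_boot < 1) {
    stop("evaluation.n_boot must be a positive integer")
  }
  invisible(cfg)
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file whose keys override [autoqc_config] defaults
#'   section-wise.
#' @return an `autoqc_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(autoqc_config())
  for (section in names(user)) {
    if (is.list(user[[section]]) && is.list(cfg[[section]])) {
      cfg[[section]][names(user[[section]])] <- user[[section]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "autoqc_config")
}

# Run all stages on one ingested record; returns list of qc_result plus the
# per-stage evidence used by the report.
#' @keywords internal
process_record <- function(rec, cfg, mode, model = NULL) {
  results <- list()
  evidence <- list()
  excluded <- FALSE
  img <- rec$image

  add <- function(res) results[[length(results) + 1L]] <<- res

  # stage 1: intensity standardisation
  window <- attr(rec, "window")
  img <- if (!is.null(window)) {
    apply_windowing(img, window$center, window$width)
  } else {
    apply_windowing(img, probs = cfg$intensity$auto_window_probs)
  }
  st <- intensity_stats(img)
  evidence$intensity <- st
  add(qc_result("intensity", "pass",
                evidence = list(mean = st$mean, sd = st$sd, cv = st$cv,
                                entropy = st$entropy)))

  # stage 2: geometry
  box <- detect_border_crop(img, pad_tol = cfg$geometry$pad_tol,
                            collim_quantile = cfg$geometry$collim_quantile)
  if (is.null(box)) {
    add(qc_result("geometry", "exclude", reasons = "empty_content"))
    excluded <- TRUE
  } else {
    cropped_frac <- 1 - ((box$row_end - box$row_start) *
                           (box$col_end - box$col_start)) /
      (nrow(img) * ncol(img))
    img <- crop_image(img, box)
    rotation <- 0L
    if (isTRUE(cfg$geometry$rotation_enabled)) {
      rc <- correct_rotation(img)
      img <- rc$image
      rotation <- rc$rotation
    }
    add(qc_result("geometry", "pass",
                  evidence = list(cropped_fraction = cropped_frac,
                                  rotation = rotation)))
    ar <- aspect_ratio_check(img, cfg$geometry$aspect_lower,
                             cfg$geometry$aspect_upper)
    add(ar)
  }

  if (!excluded || mode == "review") {
    if (!excluded) {
      # stage 3: annotation removal
      an <- cfg$annotation
      mask <- detect_annotations(img, intensity_thresh = an$intensity_thresh,
                                 tophat_soft = an$tophat_soft,
                                 tophat_hard = an$tophat_hard,
                                 tophat_brush = an$tophat_brush,
                                 min_height_frac = an$min_height_frac,
                                 max_height_frac = an$max_height_frac,
                                 max_fill_ratio = an$max_fill_ratio,
                                 max_width_frac = an$max_width_frac,
                                 dilate_px = an$dilate_px)
      mask_frac <- mean(mask$mask)
      inp <- tryCatch({
        img <- inpaint(img, mask, max_mask_frac = an$max_mask_frac)
        qc_result("annotation", "pass",
                  evidence = list(mask_fraction = mask_frac,
                                  n_components = nrow(mask$components)))
      }, radqc_inpaint_refused = function(e) {
        qc_result("annotation", "flag_for_review", reasons = "inpaint_refused",
                  evidence = list(mask_fraction = mask_frac))
      })
      add(inp)

      # stage 4: projection + consistency, quality
      declared <- parse_series_description(rec$metadata$series_description)
      predicted <- if (!is.null(model)) {
        predict_projection(model, img, threshold = cfg$projection$threshold)
      } else NULL
      cons <- consistency_check(declared, predicted)
      cons$evidence$declared <- declared$declared
      if (!is.null(predicted)) cons$evidence$predicted <- predicted$label
      add(cons)

      qm <- quality_metrics(img)
      add(quality_flag(qm, cfg$quality$thresholds))
    }
  }
  list(results = results, image = img)
}

#' Run the QC pipeline over a directory of radiographs
#'
#' Executes the fixed stage order — ingest, intensity standardisation,
#' geometry (crop, rotation, aspect ratio), annotation removal, projection +
#' header consistency, quality scoring — over every `.dcm`/`.png` file in a
#' directory. In `review` mode nothing is dropped and every verdict is
#' recorded; in `exclude` mode an excluded image skips later stages.
#' Per-image failures are isolated: a corrupt file yields one
#' `decode_error` exclusion and the rest of the batch proceeds.
#'
#' @param input_dir directory of radiographs.
#' @param config an [autoqc_config].
#' @param mode `"review"` or `"exclude"`.
#' @param model optional `projection_model` for stage 4 prediction; without
#'   it the projection stage records the declared header projection only.
#' @param seed integer seed recorded in the report.
#' @return a `batch_report` list: `qc_table` (long data frame: image_id,
#'   stage, action, reasons, evidence JSON), `stage_summary`,
#'   `metadata_profile`, `flagged`, `config`, `seed`, `mode`.
#' @export
run_pipeline <- function(input_dir, config = autoqc_config(),
                         mode = c("review", "exclude"), model = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  validate_config(config)
  files <- sort(list.files(input_dir, pattern = "\\.(dcm|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  files <- files[!grepl("_text\\.png$", files)]
  if (!length(files)) {
    return(.empty_batch_report(config, mode, seed))
  }
  if (!is.null(config$projection$model_path) && is.null(model)) {
    model <- load_projection_model(config$projection$model_path)
  }

  rows <- list()
  meta_rows <- list()
  for (f in files) {
    image_id <- tools::file_path_sans_ext(basename(f))
    rec <- read_radiograph(f)
    if (inherits(rec, "ingest_failure")) {
      rows[[length(rows) + 1L]] <- .qc_row(image_id, rec$result)
      next
    }
    rows[[length(rows) + 1L]] <- .qc_row(image_id, qc_result("ingest", "pass"))
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      image_id = image_id,
      patient_id = rec$metadata$patient_id,
      manufacturer = rec$metadata$manufacturer %||% NA_character_,
      series_description = rec$metadata$series_description %||% NA_character_,
      declared_projection = parse_series_description(
        rec$metadata$series_description)$declared,
      stringsAsFactors = FALSE)
    out <- tryCatch(
      process_record(rec, config, mode, model),
      error = function(e) NULL
    )
    if (is.null(out)) {
      rows[[length(rows) + 1L]] <- .qc_row(
        image_id, qc_result("pipeline", "exclude", reasons = "processing_error"))
      next
    }
    for (res in out$results) {
      rows[[length(rows) + 1L]] <- .qc_row(image_id, res)
    }
  }
  qc_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  metadata_table <- if (length(meta_rows)) {
    do.call(rbind, c(meta_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(image_id = character(), patient_id = character(),
               manufacturer = character(), series_description = character(),
               declared_projection = character(), stringsAsFactors = FALSE)
  }
  .assemble_batch_report(qc_table, metadata_table, config, mode, seed,
                         n_files = length(files))
}

.qc_row <- function(image_id, res) {
  data.frame(image_id = image_id, stage = res$stage, action = res$action,
             reasons = paste(res$reasons, collapse = ";"),
             evidence = as.character(jsonlite::toJSON(res$evidence,
                                                      auto_unbox = TRUE,
                                                      digits = 10, na = "null")),
             stringsAsFactors = FALSE)
}

.empty_batch_report <- function(config, mode, seed) {
  qc_table <- data.frame(image_id = character(), stage = character(),
                         action = character(), reasons = character(),
                         evidence = character(), stringsAsFactors = FALSE)
  meta <- data.frame(image_id = character(), patient_id = character(),
                     manufacturer = character(),
                     series_description = character(),
                     declared_projection = character(),
                     stringsAsFactors = FALSE)
  .assemble_batch_report(qc_table, meta, config, mode, seed, n_files = 0L)
}

.assemble_batch_report <- function(qc_table, metadata_table, config, mode,
                                   seed, n_files) {
  stage_summary <- if (nrow(qc_table)) {
    as.data.frame(table(stage = qc_table$stage, action = qc_table$action),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(stage = character(), action = character(), Freq = integer(),
               stringsAsFactors = FALSE)
  }
  token_coverage <- if (nrow(metadata_table)) {
    mean(metadata_table$declared_projection != "absent")
  } else NA_real_
  flagged <- recommend_review_subset(qc_table)
  structure(
    list(qc_table = qc_table,
         metadata_table = metadata_table,
         stage_summary = stage_summary,
         header_token_coverage = token_coverage,
         flagged = flagged,
         n_files = n_files,
         mode = mode,
         seed = seed,
         config = unclass(config)),
    class = "batch_report")
}

#' Recommend a review subset
#'
#' Orders all images with at least one `flag_for_review` verdict by number
#' of flagging stages (descending), total number of reason codes
#' (descending) and image id (ascending, for a deterministic tie-break);
#' optionally truncated to a budget.
#'
#' @param qc_table the long QC table of a `batch_report`.
#' @param budget optional maximum number of images.
#' @return character vector of image ids.
#' @export
recommend_review_subset <- function(qc_table, budget = NULL) {
  if (!nrow(qc_table)) return(character())
  fl <- qc_table[qc_table$action == "flag_for_review", , drop = FALSE]
  if (!nrow(fl)) return(character())
  n_stages <- tapply(fl$stage, fl$image_id, function(s) length(unique(s)))
  n_reasons <- tapply(fl$reasons, fl$image_id,
                      function(r) sum(lengths(strsplit(r, ";"))))
  ids <- names(n_stages)
  ord <- order(-n_stages, -n_reasons[ids], ids)
  out <- ids[ord]
  if (!is.null(budget)) out <- utils::head(out, budget)
  out
}

#' Write the batch report as JSON and HTML
#'
#' The JSON file is the canonical machine-readable output and is
#' byte-reproducible: rerunning the pipeline on the same files with the same
#' config and seed yields an identical file. The HTML is a static rendering
#' of the summary tables, the metadata completeness profile and the
#' declared-projection coverage.
#'
#' @param report a `batch_report` from [run_pipeline].
#' @param out_dir output directory (created if needed).
#' @return invisible list with the two file paths.
#' @export
build_report <- function(report, out_dir) {
  stopifnot(inherits(report, "batch_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "report.json")
  payload <- list(
    n_files = report$n_files,
    mode = report$mode,
    seed = report$seed,
    header_token_coverage = report$header_token_coverage,
    stage_summary = report$stage_summary,
    flagged = report$flagged,
    qc_table = report$qc_table,
    metadata_table = report$metadata_table,
    config = report$config
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  html_path <- file.path(out_dir, "report.html")
  html_table <- function(df) {
    if (!nrow(df)) return("<p><em>empty</em></p>")
    head_row <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                       "</tr>")
    body <- apply(df, 1L, function(r) {
      paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
    })
    paste0("<table border='1'>", head_row, paste(body, collapse = ""),
           "</table>")
  }
  cross <- if (nrow(report$metadata_table)) {
    as.data.frame(table(declared = report$metadata_table$declared_projection),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(declared = character(), Freq = integer())
  }
  html <- paste0(
    "<html><head><title>radqc batch report</title></head><body>",
    "<h1>radqc batch report</h1>",
    sprintf("<p>%d files, mode=%s, seed=%d</p>", report$n_files, report$mode,
            report$seed),
    sprintf("<p>Series Description projection-token coverage: %s</p>",
            format(report$header_token_coverage)),
    "<h2>Per-stage actions</h2>", html_table(report$stage_summary),
    "<h2>Declared projection counts</h2>", html_table(cross),
    "<h2>Flagged for review</h2>",
    html_table(data.frame(image_id = report$flagged)),
    "<h2>QC table</h2>", html_table(report$qc_table),
    "</body></html>")
  writeLines(html, html_path)
  invisible(list(json = json_path, html = html_path))
}
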