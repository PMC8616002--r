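# Result serialization: summary CSV, per-sequence profile CSVs, a single
# JSON document, optional plots, optional ZIP. All floats are written with
# 6 decimal places and fixed field order so re-runs are byte-identical
# (apart from the optional timestamp, which can be disabled).

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a scan's result bundle to a directory
#'
#' Emits `summary.csv` (one row per sequence), `profiles/<id>.csv` (pH,
#' mean hydrophobicity, NCPR, DispH score, state), `results.json` (a single
#' document mirroring both, headed by the full run configuration),
#' `skipped.tsv` when records were rejected, and optional score-vs-pH plot
#' files (per-residue profile plots in single-pH mode). In single-pH mode
#' `summary.csv` instead reports the overall score, mean hydrophobicity and
#' NCPR per sequence.
#'
#' @param x a [disph_scan()] object.
#' @param outdir output directory (created if needed).
#' @param plots also write one plot file per sequence (SVG when cairo is
#'   available, PDF otherwise).
#' @param timestamp include a timestamp field in the JSON header; disable
#'   for byte-identical re-runs.
#' @param zip additionally pack the bundle into `results.zip` (requires a
#'   `zip` binary on the PATH; degrades to a warning without one).
#' @return invisibly, the paths written.
#' @export
write_results <- function(x, outdir, plots = FALSE, timestamp = TRUE,
                          zip = FALSE) {
  stopifnot(inherits(x, "disph_scan"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  paths <- character()

  single <- isTRUE(x$config$single_ph)
  if (single) {
    sum_df <- do.call(rbind, lapply(names(x$profiles), function(id) {
      p <- x$profiles[[id]]
      data.frame(id = id,
                 ph = fmt6(p$ph[1]),
                 score = fmt6(p$score[1]),
                 mean_h = fmt6(p$mean_h[1]),
                 ncpr = fmt6(p$ncpr[1]),
                 state = p$state[1],
                 stringsAsFactors = FALSE)
    }))
  } else {
    sum_df <- as.data.frame(x)
    for (col in c("max_score", "max_score_ph", "min_score", "min_score_ph")) {
      sum_df[[col]] <- fmt6(sum_df[[col]])
    }
  }
  sum_path <- file.path(outdir, "summary.csv")
  utils::write.csv(sum_df, sum_path, row.names = FALSE, quote = TRUE)
  paths <- c(paths, sum_path)

  prof_dir <- file.path(outdir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (id in names(x$profiles)) {
    p <- x$profiles[[id]]
    df <- data.frame(ph = fmt6(p$ph), mean_h = fmt6(p$mean_h),
                     ncpr = fmt6(p$ncpr), score = fmt6(p$score),
                     state = p$state, stringsAsFactors = FALSE)
    fp <- file.path(prof_dir, paste0(sanitize_filename(id), ".csv"))
    utils::write.csv(df, fp, row.names = FALSE, quote = TRUE)
    paths <- c(paths, fp)
  }

  header <- x$config
  if (timestamp) header$timestamp <- format(Sys.time(), tz = "UTC")
  json_doc <- list(
    header = header,
    summary = lapply(names(x$reports), function(id) {
      r <- x$reports[[id]]
      list(id = id, verdict = r$verdict,
           transitions = if (nrow(r$transitions)) lapply(
             seq_len(nrow(r$transitions)), function(i) list(
               ph = as.numeric(fmt6(r$transitions$ph[i])),
               direction = r$transitions$direction[i],
               ph_class = r$transitions$ph_class[i])) else list(),
           max_score = as.numeric(fmt6(r$max_score)),
           max_score_ph = as.numeric(fmt6(r$max_score_ph)),
           min_score = as.numeric(fmt6(r$min_score)),
           min_score_ph = as.numeric(fmt6(r$min_score_ph)))
    }),
    profiles = lapply(names(x$profiles), function(id) {
      p <- x$profiles[[id]]
      list(id = id,
           ph = as.numeric(fmt6(p$ph)),
           mean_h = as.numeric(fmt6(p$mean_h)),
           ncpr = as.numeric(fmt6(p$ncpr)),
           score = as.numeric(fmt6(p$score)),
           state = p$state)
    })
  )
  json_path <- file.path(outdir, "results.json")
  jsonlite::write_json(json_doc, json_path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE)
  paths <- c(paths, json_path)

  if (nrow(x$skipped)) {
    skip_path <- file.path(outdir, "skipped.tsv")
    utils::write.table(x$skipped, skip_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, skip_path)
  }

  if (plots) {
    plot_dir <- file.path(outdir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    use_svg <- isTRUE(capabilities("cairo"))
    for (id in names(x$profiles)) {
      fp <- file.path(plot_dir,
                      paste0(sanitize_filename(id),
                             if (use_svg) ".svg" else ".pdf"))
      if (use_svg) grDevices::svg(fp, width = 7, height = 5)
      else grDevices::pdf(fp, width = 7, height = 5)
      tryCatch(plot(x, ids = id, main = id),
               finally = grDevices::dev.off())
      paths <- c(paths, fp)
    }
  }

  if (zip) {
    zip_path <- file.path(outdir, "results.zip")
    old <- getwd()
    status <- tryCatch({
      setwd(outdir)
      utils::zip(basename(zip_path),
                 files = setdiff(list.files("."), basename(zip_path)))
    }, error = function(e) -1L, warning = function(w) -1L,
    finally = setwd(old))
    if (!identical(status, 0L)) {
      warning("could not create ZIP bundle (no 'zip' binary?); ",
              "the plain directory holds all outputs", call. = FALSE)
    } else {
      paths <- c(paths, zip_path)
    }
  }
  invisible(paths)
}

sanitize_filename <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)
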