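# The user-facing entry point: scan a FASTA batch over a pH grid and return
# a single classed object bundling profiles, per-sequence verdicts and the
# dataset summary.

#' pH-dependent disorder scan of one or many protein sequences
#'
#' For every input sequence, computes mean hydrophobicity and NCPR at each
#' pH of the grid, combines them into the DispH score through the linear
#' charge-hydrophobicity boundary, and detects order-disorder transitions
#' outside the confidence band. This is the grid-mode pipeline; set
#' `ph` to a single value (or `ph_min == ph_max`) for single-pH mode.
#'
#' @param x input sequences: a FASTA file path, FASTA text, a
#'   [protein_record()], a plain sequence string (no '>' and no newline is
#'   treated as a bare sequence), or a list of records.
#' @param ph_min,ph_max,step pH grid (defaults 0 to 14, step 0.5).
#' @param ph optional single pH; overrides the grid with the degenerate
#'   one-point grid at this pH.
#' @param window odd sliding-window size in residues (default 51).
#' @param ci confidence band half-width on the DispH score (default 0.02).
#' @param scale a [lipophilicity_scale()] (default: bundled stand-in).
#' @param pkas a [pka_set()] (default: EMBOSS values).
#' @param boundary a [boundary_params()] (default 2.785, 1.151).
#' @param include_termini include terminal group charges in NCPR.
#' @param progress emit a heartbeat message every 1000 sequences.
#' @return an object of class `disph_scan`: list with `profiles` (named list
#'   of [ph_profile][scan_sequence()] data.frames), `reports` (named list of
#'   [transition_report][detect_transitions()]), `summary` (a
#'   [scan_summary][summarize_scan()]), `skipped` (data.frame of rejected
#'   records), and `config` (all run parameters).
#' @examples
#' sc <- disph_scan(">vk\nVKVKVKVKVKVKVKVKVKVK\n>gg\nGGGGGGGGGG\n",
#'                  step = 1, window = 5)
#' sc
#' summary(sc)
#' @export
disph_scan <- function(x, ph_min = 0, ph_max = 14, step = 0.5, ph = NULL,
                       window = 51, ci = 0.02,
                       scale = lipophilicity_scale(), pkas = pka_set(),
                       boundary = boundary_params(),
                       include_termini = FALSE, progress = FALSE) {
  if (!is.null(ph)) {
    check_ph(ph)
    ph_min <- ph_max <- ph
  }
  grid <- build_ph_grid(ph_min, ph_max, step)
  window <- check_window(window)

  if (inherits(x, "protein_record")) {
    records <- list(x)
    skipped <- data.frame(id = character(), reason = character())
  } else if (is.list(x)) {
    records <- lapply(x, as_protein_record)
    skipped <- data.frame(id = character(), reason = character())
  } else if (is.character(x) && length(x) == 1L &&
             !grepl("[>\n]", x) && !file.exists(x)) {
    records <- list(protein_record("seq1", x))
    skipped <- data.frame(id = character(), reason = character())
  } else {
    records <- parse_fasta(x)
    skipped <- attr(records, "skipped")
  }

  profiles <- list()
  reports <- list()
  n_done <- 0L
  for (rec in records) {
    n_done <- n_done + 1L
    if (progress && n_done %% 1000L == 0L) {
      message(sprintf("... %d / %d sequences scanned", n_done,
                      length(records)))
    }
    prof <- tryCatch(
      scan_sequence(rec, grid, window, scale, pkas, boundary,
                    include_termini),
      error = function(e) {
        warning("skipping '", rec$id, "': ", conditionMessage(e),
                call. = FALSE)
        skipped <<- rbind(skipped, data.frame(id = rec$id,
                                              reason = conditionMessage(e)))
        NULL
      }
    )
    if (is.null(prof)) next
    profiles[[rec$id]] <- prof
    reports[[rec$id]] <- detect_transitions(prof, ci)
  }
  if (!length(reports)) stop("no sequence could be scanned", call. = FALSE)

  config <- list(
    ph_min = grid$ph_min, ph_max = grid$ph_max, step = grid$step,
    single_ph = length(grid$values) == 1L,
    window = window, ci = ci,
    boundary_c1 = boundary$c1, boundary_c2 = boundary$c2,
    scale = scale$name,
    pka = as.list(pkas$pka),
    include_termini = include_termini
  )
  structure(list(profiles = profiles, reports = reports,
                 summary = summarize_scan(reports),
                 skipped = skipped, config = config,
                 grid = grid, scale = scale, pkas = pkas,
                 boundary = boundary),
            class = "disph_scan")
}

#' @export
print.disph_scan <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("pH-dependent disorder scan: %d sequence(s), pH %g-%g step %g, window %d\n",
              length(x$reports), cfg$ph_min, cfg$ph_max, cfg$step,
              cfg$window))
  n_show <- min(length(x$reports), 10L)
  for (r in x$reports[seq_len(n_show)]) print(r)
  if (length(x$reports) > n_show) {
    cat("  ... and", length(x$reports) - n_show, "more; see summary()\n")
  }
  if (nrow(x$skipped)) {
    cat(nrow(x$skipped), "record(s) skipped (see $skipped)\n")
  }
  invisible(x)
}

#' @export
summary.disph_scan <- function(object, ...) {
  object$summary
}

#' Flatten a scan into one row per sequence
#'
#' @param x a [disph_scan()] object.
#' @param ... unused.
#' @return data.frame with identifier, verdict, semicolon-joined crossing
#'   pHs / directions / pH classes and score extrema (the summary-CSV
#'   layout).
#' @export
as.data.frame.disph_scan <- function(x, ...) {
  rows <- lapply(x$reports, function(r) {
    tr <- r$transitions
    data.frame(
      id = r$id,
      verdict = r$verdict,
      transition_ph = paste(sprintf("%.6f", tr$ph), collapse = ";"),
      directions = paste(tr$direction, collapse = ";"),
      ph_classes = paste(tr$ph_class, collapse = ";"),
      max_score = r$max_score, max_score_ph = r$max_score_ph,
      min_score = r$min_score, min_score_ph = r$min_score_ph,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot DispH score against pH
#'
#' One curve per sequence with the confidence band shaded and interpolated
#' crossings marked. For a single-pH scan, plots the per-residue DispH
#' profile of the first (or selected) sequence instead.
#'
#' @param x a [disph_scan()] object.
#' @param ids identifiers to draw (default: all, up to 12).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.disph_scan <- function(x, ids = NULL, ...) {
  if (is.null(ids)) ids <- utils::head(names(x$profiles), 12L)
  ids <- intersect(ids, names(x$profiles))
  if (!length(ids)) stop("no matching sequence identifiers", call. = FALSE)
  if (x$config$single_ph) {
    rec_id <- ids[1]
    rec <- protein_record(rec_id, attr(x$profiles[[rec_id]], "sequence"))
    prof <- residue_disph_profile(rec, x$grid$values[1], x$config$window,
                                  x$scale, x$pkas, x$boundary)
    graphics::plot(seq_along(prof), prof, type = "l",
                   xlab = "residue position", ylab = "DispH score",
                   main = sprintf("%s at pH %g", rec_id, x$grid$values[1]),
                   ...)
    graphics::abline(h = 0, col = "grey40")
    return(invisible(x))
  }
  ph <- x$grid$values
  scores <- sapply(ids, function(id) x$profiles[[id]]$score)
  graphics::matplot(ph, scores, type = "l", lty = 1,
                    xlab = "pH", ylab = "DispH score", ...)
  graphics::abline(h = 0, col = "grey40")
  graphics::abline(h = c(-1, 1) * x$config$ci, col = "grey70", lty = 3)
  for (id in ids) {
    tr <- x$reports[[id]]$transitions
    if (nrow(tr)) graphics::points(tr$ph, rep(0, nrow(tr)), pch = 4)
  }
  graphics::legend("topleft", legend = ids, col = seq_along(ids), lty = 1,
                   cex = 0.7, bty = "n")
  invisible(x)
}
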