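# pH-grid scanning, transition detection and dataset aggregation.

#' Build an evenly spaced pH grid
#'
#' Returns `floor((pH_max - pH_min)/step) + 1` values starting at `pH_min`;
#' the last value never exceeds `pH_max`. `pH_min == pH_max` gives the
#' degenerate single-pH grid regardless of step. The default 0-14 grid at
#' step 0.5 has 29 values.
#'
#' @param ph_min,ph_max grid bounds, within [0, 14].
#' @param step grid spacing in pH units (> 0 unless the grid is degenerate).
#' @return an object of class `ph_grid`: list with `ph_min`, `ph_max`,
#'   `step`, and the ordered numeric vector `values`.
#' @examples
#' length(build_ph_grid(0, 14, 0.5)$values)  # 29
#' @export
build_ph_grid <- function(ph_min = 0, ph_max = 14, step = 0.5) {
  check_ph(c(ph_min, ph_max))
  if (ph_min > ph_max) {
    stop("ph_min must not exceed ph_max", call. = FALSE)
  }
  if (ph_min == ph_max) {
    values <- ph_min
  } else {
    if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
        step <= 0) {
      stop("step must be > 0", call. = FALSE)
    }
    # small relative tolerance so e.g. 14/0.5 is not floored to 27
    count <- floor((ph_max - ph_min) / step + 1e-9) + 1
    values <- ph_min + step * (seq_len(count) - 1)
    values[count] <- min(values[count], ph_max)
  }
  structure(list(ph_min = ph_min, ph_max = ph_max, step = step,
                 values = values),
            class = "ph_grid")
}

#' @export
print.ph_grid <- function(x, ...) {
  cat(sprintf("pH grid: %g to %g, step %g (%d values)\n",
              x$ph_min, x$ph_max, x$step, length(x$values)))
  invisible(x)
}

#' Scan one sequence across a pH grid
#'
#' Evaluates mean hydrophobicity, NCPR, the DispH score and the
#' folded/unfolded state at every grid pH.
#'
#' @inheritParams windowed_hydrophobicity
#' @param grid a [ph_grid][build_ph_grid()].
#' @param boundary a [boundary_params()].
#' @param include_termini include terminal group charges in NCPR.
#' @return an object of class `ph_profile`: a data.frame with columns
#'   `ph`, `mean_h`, `ncpr`, `score`, `state`, carrying the sequence `id`
#'   and run parameters as attributes.
#' @examples
#' pr <- scan_sequence("KVKVKVKVKV", build_ph_grid(0, 14, 1), window = 5)
#' head(pr)
#' @export
scan_sequence <- function(seq, grid = build_ph_grid(), window = 51,
                          scale = lipophilicity_scale(), pkas = pka_set(),
                          boundary = boundary_params(),
                          include_termini = FALSE) {
  seq <- as_protein_record(seq)
  stopifnot(inherits(grid, "ph_grid"))
  window <- check_window(window)
  chars <- seq_letters(seq)
  L <- length(chars)
  n <- length(grid$values)
  mean_h <- numeric(n)
  ncpr <- numeric(n)
  term_q <- 0
  for (i in seq_len(n)) {
    pH <- grid$values[i]
    mean_h[i] <- mean(running_mean_truncated(
      unname(lipo_table(pH, scale, pkas)[chars]), window))
    total <- sum(charge_table(pH, pkas)[chars])
    if (include_termini) {
      total <- total +
        hh_charge(pkas$pka[["Nterm"]], pH, pkas$polarity[["Nterm"]]) +
        hh_charge(pkas$pka[["Cterm"]], pH, pkas$polarity[["Cterm"]])
    }
    ncpr[i] <- total / L
  }
  score <- disph_score(mean_h, ncpr, boundary)
  out <- data.frame(ph = grid$values, mean_h = mean_h, ncpr = ncpr,
                    score = score, state = score_state(score),
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("ph_profile", "data.frame"),
            id = seq$id, length = L, sequence = seq$sequence,
            grid = grid, window = window,
            boundary = boundary, scale_name = scale$name,
            include_termini = include_termini)
}

#' Classify a crossing pH as acid, neutral or basic
#'
#' Acid below 6, neutral on the closed interval 6 to 8, basic above 8.
#'
#' @param pH pH value(s) in [0, 14].
#' @return character vector: `"acid"`, `"neutral"` or `"basic"`.
#' @examples
#' classify_transition_ph(c(5.9, 6, 8, 8.5))
#' @export
classify_transition_ph <- function(pH) {
  check_ph(pH)
  ifelse(pH < 6, "acid", ifelse(pH <= 8, "neutral", "basic"))
}

# Collapse a +1/0/-1 band-sign series: zeros inherit the previous non-zero
# sign; leading zeros inherit the first non-zero sign. All-zero series stays 0.
collapse_band_signs <- function(s) {
  nz <- which(s != 0)
  if (length(nz) == 0L) return(s)
  s[seq_len(nz[1] - 1L)] <- s[nz[1]]
  for (i in seq_along(s)[-1]) {
    if (s[i] == 0) s[i] <- s[i - 1]
  }
  s
}

# first adjacent raw-score pair straddling zero in [i1, i2]; interpolated pH
interpolate_crossing <- function(ph, score, i1, i2) {
  for (k in i1:(i2 - 1L)) {
    a <- score[k]; b <- score[k + 1L]
    if (a == 0 || a * b < 0) {
      if (a == b) return(ph[k])
      return(ph[k] + a / (a - b) * (ph[k + 1L] - ph[k]))
    }
  }
  # fall back to the midpoint of the span (not reachable for definite signs)
  (ph[i1] + ph[i2]) / 2
}

#' Detect pH-induced order-disorder transitions in a profile
#'
#' A transition exists only if the maximum score exceeds `+ci` and the
#' minimum falls below `-ci` (the confidence-band gate). Scores are mapped
#' to +1 (> ci), -1 (< -ci) or 0 (in band); in-band runs inherit the
#' previous definite sign (debouncing) so band-sized wiggles never count as
#' transitions. Each remaining sign flip is a transition; its crossing pH is
#' the linearly interpolated zero of the score between the bracketing grid
#' points. A sign change from negative to positive with increasing pH is
#' conditional folding, the reverse conditional unfolding. Profiles without
#' transitions are labelled folded or unfolded by the score sign at the
#' median grid pH.
#'
#' @param profile a [ph_profile][scan_sequence()].
#' @param ci confidence band half-width (default 0.02).
#' @return an object of class `transition_report`: list with `id`, `verdict`
#'   (`folded`/`unfolded`/`transition`/`multitransition`), a data.frame
#'   `transitions` (`ph`, `direction`, `ph_class`), score extrema with their
#'   pH values, and `ci`.
#' @examples
#' pr <- scan_sequence(strrep("VK", 25), build_ph_grid(0, 14, 0.5))
#' detect_transitions(pr)
#' @export
detect_transitions <- function(profile, ci = 0.02) {
  stopifnot(inherits(profile, "ph_profile"))
  if (!is.numeric(ci) || length(ci) != 1L || !is.finite(ci) || ci < 0) {
    stop("ci must be a non-negative number", call. = FALSE)
  }
  score <- profile$score
  ph <- profile$ph
  n <- length(score)
  imax <- which.max(score)
  imin <- which.min(score)
  empty_tr <- data.frame(ph = numeric(), direction = character(),
                         ph_class = character(), stringsAsFactors = FALSE)
  transitions <- empty_tr
  gate <- n > 1L && score[imax] > ci && score[imin] < -ci
  if (gate) {
    band <- ifelse(score > ci, 1L, ifelse(score < -ci, -1L, 0L))
    collapsed <- collapse_band_signs(band)
    flips <- which(diff(collapsed) != 0)
    if (length(flips)) {
      rows <- lapply(flips, function(j) {
        # span from the last definite old-sign point to the first definite
        # new-sign point around the flip
        i1 <- max(which(band[seq_len(j)] == collapsed[j]))
        i2 <- j + min(which(band[(j + 1L):n] == collapsed[j + 1L]))
        data.frame(
          ph = interpolate_crossing(ph, score, i1, i2),
          direction = if (collapsed[j + 1L] > collapsed[j])
            "conditional folding" else "conditional unfolding",
          stringsAsFactors = FALSE
        )
      })
      transitions <- do.call(rbind, rows)
      transitions$ph_class <- classify_transition_ph(transitions$ph)
    }
  }
  k <- nrow(transitions)
  if (k == 0L) {
    med <- score[(n + 1L) %/% 2L]
    if (abs(med) <= ci) {
      warning("profile '", attr(profile, "id"),
              "': all-in-band or in-band median score; low-confidence ",
              score_state(med), " label", call. = FALSE)
    }
    verdict <- score_state(med)
  } else if (k == 1L) {
    verdict <- "transition"
  } else {
    verdict <- "multitransition"
  }
  structure(list(
    id = attr(profile, "id"),
    verdict = verdict,
    transitions = transitions,
    max_score = score[imax], max_score_ph = ph[imax],
    min_score = score[imin], min_score_ph = ph[imin],
    ci = ci
  ), class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(x$id, ": ", x$verdict, sep = "")
  cat(sprintf("  [max %.4f @ pH %g; min %.4f @ pH %g]\n",
              x$max_score, x$max_score_ph, x$min_score, x$min_score_ph))
  if (nrow(x$transitions)) {
    for (i in seq_len(nrow(x$transitions))) {
      cat(sprintf("  %s at pH %.2f (%s)\n",
                  x$transitions$direction[i], x$transitions$ph[i],
                  x$transitions$ph_class[i]))
    }
  }
  invisible(x)
}

#' Aggregate transition reports into dataset-level statistics
#'
#' Reports the no-transition vs transition split of the whole dataset, the
#' single vs multitransition split and the conditional folding vs unfolding
#' split among transitioning sequences (directions use each sequence's
#' first transition), and the acid/neutral/basic split over all crossings.
#'
#' @param reports a list of [transition_report][detect_transitions()]
#'   objects.
#' @return an object of class `scan_summary` (a list of counts and
#'   percentages; every percentage pair/triple sums to 100 within rounding,
#'   percentages over empty denominators are `NA`).
#' @export
summarize_scan <- function(reports) {
  if (inherits(reports, "transition_report")) reports <- list(reports)
  if (!length(reports)) stop("no reports to summarize", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "transition_report")))
  verdicts <- vapply(reports, `[[`, character(1), "verdict")
  n <- length(reports)
  n_single <- sum(verdicts == "transition")
  n_multi <- sum(verdicts == "multitransition")
  n_none <- n - n_single - n_multi
  n_trans <- n_single + n_multi
  trans_reports <- reports[verdicts %in% c("transition", "multitransition")]
  first_dir <- vapply(trans_reports,
                      function(r) r$transitions$direction[1], character(1))
  all_classes <- unlist(lapply(trans_reports,
                               function(r) r$transitions$ph_class))
  pct <- function(k, d) if (d > 0) 100 * k / d else NA_real_
  structure(list(
    n = n,
    n_no_transition = n_none,
    n_single_transition = n_single,
    n_multitransition = n_multi,
    pct_no_transition = pct(n_none, n),
    pct_transition = pct(n_trans, n),
    pct_single_of_transitioning = pct(n_single, n_trans),
    pct_multi_of_transitioning = pct(n_multi, n_trans),
    pct_conditional_folding =
      pct(sum(first_dir == "conditional folding"), n_trans),
    pct_conditional_unfolding =
      pct(sum(first_dir == "conditional unfolding"), n_trans),
    n_crossings = length(all_classes),
    pct_acid = pct(sum(all_classes == "acid"), length(all_classes)),
    pct_neutral = pct(sum(all_classes == "neutral"), length(all_classes)),
    pct_basic = pct(sum(all_classes == "basic"), length(all_classes))
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("%d sequences scanned\n", x$n))
  cat(sprintf("  no transition: %5d (%.1f%%)   transition: %5d (%.1f%%)\n",
              x$n_no_transition, x$pct_no_transition,
              x$n_single_transition + x$n_multitransition,
              x$pct_transition))
  if (x$n_crossings > 0) {
    cat(sprintf("  of transitioning: %.1f%% single / %.1f%% multitransition\n",
                x$pct_single_of_transitioning,
                x$pct_multi_of_transitioning))
    cat(sprintf("  first transition: %.1f%% conditional folding, %.1f%% unfolding\n",
                x$pct_conditional_folding, x$pct_conditional_unfolding))
    cat(sprintf("  crossings: %.1f%% acid / %.1f%% neutral / %.1f%% basic (%d total)\n",
                x$pct_acid, x$pct_neutral, x$pct_basic, x$n_crossings))
  }
  invisible(x)
}
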