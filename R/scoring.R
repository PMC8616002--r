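# Linear charge-hydrophobicity boundary and the DispH score.

#' Boundary coefficients of the charge-hydrophobicity plane
#'
#' The folded and disordered regions of the mean-hydrophobicity / net-charge
#' plane separate across a line; the signed distance-like DispH score is
#' `c1 * <H> - |NCPR| - c2`. The defaults are the classic charge-
#' hydrophobicity boundary coefficients (c1 = 2.785, c2 = 1.151); both are
#' overridable so a recalibrated boundary can be dropped in.
#'
#' @param c1 slope coefficient (> 0).
#' @param c2 intercept coefficient.
#' @return an object of class `boundary_params`.
#' @export
boundary_params <- function(c1 = 2.785, c2 = 1.151) {
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) || c1 <= 0) {
    stop("boundary slope c1 must be a positive number", call. = FALSE)
  }
  if (!is.numeric(c2) || length(c2) != 1L || !is.finite(c2)) {
    stop("boundary intercept c2 must be a finite number", call. = FALSE)
  }
  structure(list(c1 = c1, c2 = c2), class = "boundary_params")
}

#' @export
print.boundary_params <- function(x, ...) {
  cat(sprintf("charge-hydrophobicity boundary: score = %g*<H> - |NCPR| - %g\n",
              x$c1, x$c2))
  invisible(x)
}

#' DispH score from mean hydrophobicity and NCPR
#'
#' `c1 * <H> - |NCPR| - c2`. A positive score predicts a folded state, a
#' negative score a disordered (unfolded) state. A score of exactly 0 sits
#' on the boundary and is labelled unfolded (conservative tie rule).
#'
#' @param mean_h mean hydrophobicity in [0, 1] (vectorized).
#' @param ncpr net charge per residue (vectorized; only |NCPR| enters).
#' @param boundary a [boundary_params()].
#' @return signed DispH score(s).
#' @examples
#' disph_score(0.5, 0)       # 0.2415, folded
#' disph_score(0.3, -0.5)    # -0.8155, unfolded
#' @export
disph_score <- function(mean_h, ncpr, boundary = boundary_params()) {
  if (any(mean_h < -1e-9 | mean_h > 1 + 1e-9, na.rm = TRUE)) {
    stop("mean hydrophobicity must lie in [0, 1]", call. = FALSE)
  }
  boundary$c1 * mean_h - abs(ncpr) - boundary$c2
}

# folded/unfolded label under the tie rule (0 -> unfolded)
score_state <- function(score) {
  ifelse(score > 0, "folded", "unfolded")
}

#' Per-residue DispH profile at a single pH
#'
#' Computes, for every position, the DispH score from that position's
#' windowed mean hydrophobicity and windowed NCPR (same centered window,
#' same end truncation for both), giving a local picture of disorder along
#' the chain at one pH.
#'
#' @inheritParams windowed_hydrophobicity
#' @param boundary a [boundary_params()].
#' @return numeric vector of per-position DispH scores, one per residue.
#' @export
residue_disph_profile <- function(seq, pH, window = 51,
                                  scale = lipophilicity_scale(),
                                  pkas = pka_set(),
                                  boundary = boundary_params()) {
  seq <- as_protein_record(seq)
  check_ph(pH)
  window <- check_window(window)
  chars <- seq_letters(seq)
  h <- running_mean_truncated(unname(lipo_table(pH, scale, pkas)[chars]),
                              window)
  q <- running_mean_truncated(unname(charge_table(pH, pkas)[chars]),
                              window)
  disph_score(h, q, boundary)
}
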