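# pH-dependent per-residue charge and lipophilicity, and windowed averaging.
# Internals work on per-letter lookup tables so whole-sequence evaluation is
# a single indexed read; the exported per-residue functions share the same
# lookups.

# Henderson-Hasselbalch charge of one ionizable group.
# acids: -1 / (1 + 10^(pKa - pH));  bases: +1 / (1 + 10^(pH - pKa))
hh_charge <- function(pka, pH, polarity) {
  ifelse(polarity == "acid",
         -1 / (1 + 10^(pka - pH)),
         +1 / (1 + 10^(pH - pka)))
}

# Fraction of the *neutral* species at a given pH.
# acid: neutral = protonated -> 1/(1+10^(pH-pKa));
# base: neutral = deprotonated -> 1/(1+10^(pKa-pH))
hh_neutral_fraction <- function(pka, pH, polarity) {
  ifelse(polarity == "acid",
         1 / (1 + 10^(pH - pka)),
         1 / (1 + 10^(pka - pH)))
}

# named charge lookup over all tolerated letters at one pH
charge_table <- function(pH, pkas) {
  side <- setdiff(names(pkas$pka), c("Nterm", "Cterm"))
  tab <- stats::setNames(numeric(length(AA_STANDARD) + length(AA_AMBIGUOUS)),
                         c(AA_STANDARD, AA_AMBIGUOUS))
  tab[side] <- hh_charge(pkas$pka[side], pH, pkas$polarity[side])
  tab
}

# named lipophilicity lookup over all tolerated letters at one pH
lipo_table <- function(pH, scale, pkas) {
  tab <- c(scale$h_neutral,
           stats::setNames(rep(mean(scale$h_neutral), length(AA_AMBIGUOUS)),
                           AA_AMBIGUOUS))
  ion <- intersect(names(scale$h_charged), names(pkas$pka))
  f <- hh_neutral_fraction(pkas$pka[ion], pH, pkas$polarity[ion])
  tab[ion] <- f * scale$h_neutral[ion] + (1 - f) * scale$h_charged[ion]
  tab
}

check_ph <- function(pH) {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH < 0) || any(pH > 14)) {
    stop("pH must lie in [0, 14]", call. = FALSE)
  }
  pH
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window < 1 || window != floor(window)) {
    stop("window must be a positive integer", call. = FALSE)
  }
  if (window %% 2 == 0) {
    stop("window must be odd so that it has a well-defined center (got ",
         window, ")", call. = FALSE)
  }
  as.integer(window)
}

seq_letters <- function(seq) {
  chars <- strsplit(seq$sequence, "")[[1]]
  bad <- !(chars %in% c(AA_STANDARD, AA_AMBIGUOUS))
  if (any(bad)) {
    pos <- which(bad)[1]
    stop("invalid residue '", chars[pos], "' at position ", pos,
         " in sequence '", seq$id, "'", call. = FALSE)
  }
  chars
}

#' Henderson-Hasselbalch charge of a single residue at a given pH
#'
#' Acids titrate to -1/(1 + 10^(pKa - pH)); bases to +1/(1 + 10^(pH - pKa)).
#' Non-ionizable residues and tolerated ambiguity codes (X, B, Z, U, O)
#' return 0.
#'
#' @param aa single-letter amino-acid code.
#' @param pH solution pH in [0, 14].
#' @param pkas a [pka_set()].
#' @return signed charge fraction in [-1, 1].
#' @examples
#' residue_charge("D", 3.9)   # half-titration: -0.5
#' residue_charge("G", 7)     # 0
#' @export
residue_charge <- function(aa, pH, pkas = pka_set()) {
  check_ph(pH)
  if (!is.character(aa) || length(aa) != 1L || nchar(aa) != 1L) {
    stop("aa must be a single-letter code", call. = FALSE)
  }
  aa <- toupper(aa)
  if (!aa %in% c(AA_STANDARD, AA_AMBIGUOUS)) {
    stop("invalid residue '", aa, "': not a standard amino acid or ",
         "tolerated ambiguity code", call. = FALSE)
  }
  unname(charge_table(pH, pkas)[aa])
}

#' Net charge per residue (NCPR) of a sequence at a given pH
#'
#' Sums Henderson-Hasselbalch per-residue charges and divides by sequence
#' length. Terminal amino and carboxyl group charges are excluded by default
#' and added to the sum (before length normalization) when
#' `include_termini = TRUE`.
#'
#' @param seq a [protein_record()] or plain sequence string.
#' @param pH solution pH in [0, 14].
#' @param pkas a [pka_set()].
#' @param include_termini add the N- and C-terminal group charges.
#' @return NCPR, a value in [-1 - 2/L, 1 + 2/L].
#' @examples
#' net_charge_per_residue("KKKK", 7)
#' @export
net_charge_per_residue <- function(seq, pH, pkas = pka_set(),
                                   include_termini = FALSE) {
  seq <- as_protein_record(seq)
  check_ph(pH)
  chars <- seq_letters(seq)
  total <- sum(charge_table(pH, pkas)[chars])
  if (include_termini) {
    total <- total +
      hh_charge(pkas$pka[["Nterm"]], pH, pkas$polarity[["Nterm"]]) +
      hh_charge(pkas$pka[["Cterm"]], pH, pkas$polarity[["Cterm"]])
  }
  total / length(chars)
}

#' pH-dependent lipophilicity of a single residue
#'
#' Ionizable residues mix their neutral- and charged-species scale values by
#' the Henderson-Hasselbalch fraction of the neutral species at the given
#' pH: `f * h_neutral + (1 - f) * h_charged`. Non-ionizable residues return
#' their neutral value independent of pH; ambiguity codes return the mean of
#' the neutral scale.
#'
#' @inheritParams residue_charge
#' @param scale a [lipophilicity_scale()].
#' @return lipophilicity in [0, 1].
#' @examples
#' residue_lipophilicity("E", 1)    # fully protonated: neutral value
#' residue_lipophilicity("E", 4.1)  # half-titrated: species midpoint
#' @export
residue_lipophilicity <- function(aa, pH, scale = lipophilicity_scale(),
                                  pkas = pka_set()) {
  check_ph(pH)
  aa <- toupper(aa)
  if (!aa %in% c(AA_STANDARD, AA_AMBIGUOUS)) {
    stop("invalid residue '", aa, "'", call. = FALSE)
  }
  unname(lipo_table(pH, scale, pkas)[aa])
}

# running mean with centered window truncated at the ends, via cumsum
running_mean_truncated <- function(v, window) {
  n <- length(v)
  k <- (window - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(idx - k, 1L)
  hi <- pmin(idx + k, n)
  cs <- c(0, cumsum(v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding-window lipophilicity profile
#'
#' One value per residue: the mean residue lipophilicity over an odd-sized
#' window centered on that position, truncated at the sequence ends (windows
#' shrink near the termini; sequences shorter than the window collapse to
#' the whole-sequence average).
#'
#' @inheritParams net_charge_per_residue
#' @param window odd positive integer window size (default 51).
#' @param scale a [lipophilicity_scale()].
#' @return numeric vector, one value in [0, 1] per residue.
#' @export
windowed_hydrophobicity <- function(seq, pH, window = 51,
                                    scale = lipophilicity_scale(),
                                    pkas = pka_set()) {
  seq <- as_protein_record(seq)
  check_ph(pH)
  window <- check_window(window)
  chars <- seq_letters(seq)
  v <- unname(lipo_table(pH, scale, pkas)[chars])
  running_mean_truncated(v, window)
}

#' Mean hydrophobicity of a sequence at a given pH
#'
#' The average of the sliding-window lipophilicity profile
#' ([windowed_hydrophobicity()]).
#'
#' @inheritParams windowed_hydrophobicity
#' @return mean hydrophobicity in [0, 1].
#' @export
mean_hydrophobicity <- function(seq, pH, window = 51,
                                scale = lipophilicity_scale(),
                                pkas = pka_set()) {
  mean(windowed_hydrophobicity(seq, pH, window, scale, pkas))
}
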