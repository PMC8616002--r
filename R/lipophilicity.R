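#' pH-dependent lipophilicity scale
#'
#' A `lipophilicity_scale` stores, for each of the 20 standard amino acids,
#' a neutral-species lipophilicity in [0, 1], and for each ionizable residue
#' additionally a charged-species value. At a given pH the effective residue
#' lipophilicity is the protonation-weighted mix of the two species (see
#' [residue_lipophilicity()]). Ionization never increases lipophilicity, so
#' charged-species values must not exceed their neutral counterparts.
#'
#' The bundled default is a documented stand-in: Kyte-Doolittle hydropathy
#' min-max normalized to [0, 1] for the neutral species, with every charged
#' species assigned the scale minimum (0.0). It preserves the structure of a
#' protonation-weighted pH-dependent scale while remaining fully replaceable
#' through [read_scale_csv()].
#'
#' @param h_neutral named numeric vector over the 20 standard residues,
#'   values in [0, 1].
#' @param h_charged named numeric vector over the ionizable residues
#'   (D, E, C, Y, H, K, R), values in [0, 1], each <= its neutral value.
#' @param name scale name used in output provenance headers.
#' @return an object of class `lipophilicity_scale`.
#' @examples
#' sc <- lipophilicity_scale()
#' sc$h_neutral[["V"]]
#' @export
lipophilicity_scale <- function(h_neutral = NULL, h_charged = NULL,
                                name = "KD-normalized stand-in") {
  if (is.null(h_neutral)) {
    kd <- c(
      I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
      G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
      E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
    )
    h_neutral <- (kd - min(kd)) / (max(kd) - min(kd))
  }
  if (is.null(h_charged)) {
    h_charged <- c(D = 0, E = 0, C = 0, Y = 0, H = 0, K = 0, R = 0)
  }
  if (is.null(names(h_neutral)) || !all(AA_STANDARD %in% names(h_neutral))) {
    stop("h_neutral must cover all 20 standard amino acids", call. = FALSE)
  }
  h_neutral <- h_neutral[AA_STANDARD]
  ionizable <- c("D", "E", "C", "Y", "H", "K", "R")
  if (is.null(names(h_charged)) || !all(ionizable %in% names(h_charged))) {
    stop("h_charged must cover the ionizable residues ",
         paste(ionizable, collapse = ", "), call. = FALSE)
  }
  h_charged <- h_charged[ionizable]
  vals <- c(h_neutral, h_charged)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all lipophilicity values must lie in [0, 1]", call. = FALSE)
  }
  if (any(h_charged > h_neutral[ionizable] + 1e-12)) {
    stop("charged-species lipophilicity must not exceed the neutral value",
         call. = FALSE)
  }
  structure(list(h_neutral = h_neutral, h_charged = h_charged, name = name),
            class = "lipophilicity_scale")
}

#' Read a lipophilicity scale from a CSV file
#'
#' Expected columns: `residue`, `h_neutral`, `h_charged` (blank/NA for
#' non-ionizable residues). All 20 standard residues must be present.
#'
#' @param path path to the CSV file.
#' @return a [lipophilicity_scale()].
#' @export
read_scale_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("residue", "h_neutral", "h_charged")
  if (!all(need %in% names(df))) {
    stop("scale CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hn <- stats::setNames(as.numeric(df$h_neutral), df$residue)
  hc_raw <- suppressWarnings(as.numeric(df$h_charged))
  keep <- !is.na(hc_raw)
  hc <- stats::setNames(hc_raw[keep], df$residue[keep])
  ionizable <- c("D", "E", "C", "Y", "H", "K", "R")
  missing_ion <- setdiff(ionizable, names(hc))
  if (length(missing_ion)) {
    stop("scale CSV lacks charged-species values for: ",
         paste(missing_ion, collapse = ", "), call. = FALSE)
  }
  lipophilicity_scale(hn, hc,
                      name = paste0("user:", basename(path)))
}

#' @export
print.lipophilicity_scale <- function(x, ...) {
  cat("lipophilicity scale: ", x$name, "\n", sep = "")
  ion <- names(x$h_charged)
  df <- data.frame(
    residue = names(x$h_neutral),
    h_neutral = round(unname(x$h_neutral), 4),
    h_charged = ifelse(names(x$h_neutral) %in% ion,
                       round(x$h_charged[names(x$h_neutral)], 4), NA)
  )
  print(df, row.names = FALSE)
  invisible(x)
}
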