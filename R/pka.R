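#' Titration constants for ionizable groups
#'
#' A `pka_set` holds one pKa per ionizable side chain (D, E, C, Y, H, K, R)
#' plus the free N- and C-terminal groups, together with a polarity flag:
#' acids carry -1 when deprotonated, bases +1 when protonated. The default
#' set is the widely used EMBOSS set.
#'
#' @param values named numeric vector of pKa values. Names must cover the
#'   seven ionizable residues `D,E,C,Y,H,K,R` plus `Nterm` and `Cterm`.
#' @param polarity named character vector (`"acid"` or `"base"`) aligned
#'   with `values`. Defaults to the chemically fixed assignment: acids are
#'   D, E, C, Y and the C-terminus; bases are H, K, R and the N-terminus.
#' @return an object of class `pka_set`: a list with elements `pka`
#'   (named numeric) and `polarity` (named character).
#' @examples
#' pk <- pka_set()
#' pk$pka[["K"]]
#' @export
pka_set <- function(values = NULL, polarity = NULL) {
  default_polarity <- c(
    D = "acid", E = "acid", C = "acid", Y = "acid", Cterm = "acid",
    H = "base", K = "base", R = "base", Nterm = "base"
  )
  if (is.null(values)) {
    # EMBOSS defaults
    values <- c(
      D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
      H = 6.5, K = 10.8, R = 12.5,
      Nterm = 8.6, Cterm = 3.6
    )
  }
  required <- names(default_polarity)
  if (is.null(names(values)) || !all(required %in% names(values))) {
    stop("pKa set must name every ionizable group: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  values <- values[required]
  if (any(!is.finite(values)) || any(values <= 0) || any(values >= 14)) {
    stop("every pKa must lie in the open interval (0, 14)", call. = FALSE)
  }
  if (is.null(polarity)) {
    polarity <- default_polarity
  } else {
    polarity <- polarity[required]
    if (any(is.na(polarity)) || !all(polarity %in% c("acid", "base"))) {
      stop("polarity must be 'acid' or 'base' for every group", call. = FALSE)
    }
  }
  structure(list(pka = values, polarity = polarity), class = "pka_set")
}

#' Read a pKa set from a CSV file
#'
#' Expected columns: `residue` (one of D,E,C,Y,H,K,R,Nterm,Cterm), `pka`
#' (numeric), `polarity` (`acid`/`base`). Groups omitted from the file keep
#' their default value, so a file can override a single pKa.
#'
#' @param path path to the CSV file.
#' @return a [pka_set()].
#' @export
read_pka_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("residue", "pka", "polarity")
  if (!all(need %in% names(df))) {
    stop("pKa CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- pka_set()
  pk <- base$pka
  pol <- base$polarity
  unknown <- setdiff(df$residue, names(pk))
  if (length(unknown)) {
    stop("unknown ionizable group(s) in pKa CSV: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pk[df$residue] <- as.numeric(df$pka)
  pol[df$residue] <- tolower(df$polarity)
  pka_set(pk, pol)
}

#' @export
print.pka_set <- function(x, ...) {
  cat("pKa set (", length(x$pka), " ionizable groups)\n", sep = "")
  df <- data.frame(group = names(x$pka), pKa = unname(x$pka),
                   polarity = unname(x$polarity))
  print(df, row.names = FALSE)
  invisible(x)
}
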