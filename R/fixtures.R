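# Deterministic synthetic sequences with designed titration behaviour.
# Homopolymers are pH-inert or single-group titration controls; alternating
# hydrophobic/ionizable copolymers are built to cross the charge-
# hydrophobicity boundary near the ionizable residue's pKa.

#' Generate a deterministic synthetic sequence
#'
#' Construct kinds:
#' \describe{
#'   \item{homopolymer}{`residues[1]` repeated `length` times.}
#'   \item{alternating}{`residues[1]`/`residues[2]` alternating; total
#'     length `2 * length` (length = number of repeats of the pair).}
#'   \item{block}{each residue in `residues` repeated `length` times and
#'     concatenated.}
#'   \item{random}{`length` residues drawn uniformly from `residues`
#'     (default: the 20 standard amino acids) under `seed`.}
#' }
#'
#' @param kind one of `"homopolymer"`, `"alternating"`, `"block"`,
#'   `"random"`.
#' @param residues character vector of residue codes used by the construct.
#' @param length construct length parameter (see kinds above); >= 1.
#' @param seed integer seed (random kind only); same spec + seed always
#'   yields the same sequence.
#' @param id identifier for the resulting record.
#' @return a [protein_record()].
#' @examples
#' make_fixture("alternating", c("V", "K"), 25)$sequence
#' @export
make_fixture <- function(kind = c("homopolymer", "alternating", "block",
                                  "random"),
                         residues = NULL, length = 50, seed = 1,
                         id = NULL) {
  kind <- match.arg(kind)
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  if (is.null(residues)) {
    residues <- if (kind == "random") AA_STANDARD else "G"
  }
  residues <- toupper(residues)
  bad <- setdiff(residues, AA_STANDARD)
  if (base::length(bad)) {
    stop("unknown residue(s) in fixture spec: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seqstr <- switch(kind,
    homopolymer = strrep(residues[1], length),
    alternating = {
      if (base::length(residues) < 2) {
        stop("alternating construct needs two residues", call. = FALSE)
      }
      strrep(paste0(residues[1], residues[2]), length)
    },
    block = paste(vapply(residues, strrep, character(1), times = length),
                  collapse = ""),
    random = {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      paste(sample(residues, length, replace = TRUE), collapse = "")
    }
  )
  if (is.null(id)) {
    id <- switch(kind,
      homopolymer = sprintf("poly%s_%d", residues[1], length),
      alternating = sprintf("alt%s%s_%d", residues[1], residues[2], length),
      block = sprintf("block%s_%d", paste(residues, collapse = ""), length),
      random = sprintf("rand%d_s%d", length, seed))
  }
  protein_record(id, seqstr)
}

#' The labelled fixture catalog
#'
#' A fixed set of constructs covering the behaviours the scanner must
#' resolve: poly-G(50) (pH-inert control), poly-K(50) and poly-E(50)
#' (single-group titration controls), (VK)25 (designed conditional
#' folding near pKa(K)), (VE)25 (designed conditional unfolding near
#' pKa(E)), (VH)25 (near-neutral crossing), and a uniform random 100-mer.
#'
#' @param seed seed for the random member.
#' @return named list of [protein_record()] objects.
#' @export
fixture_catalog <- function(seed = 1) {
  list(
    polyG = make_fixture("homopolymer", "G", 50, id = "polyG"),
    polyK = make_fixture("homopolymer", "K", 50, id = "polyK"),
    polyE = make_fixture("homopolymer", "E", 50, id = "polyE"),
    VK25 = make_fixture("alternating", c("V", "K"), 25, id = "VK25"),
    VE25 = make_fixture("alternating", c("V", "E"), 25, id = "VE25"),
    VH25 = make_fixture("alternating", c("V", "H"), 25, id = "VH25"),
    rand100 = make_fixture("random", length = 100, seed = seed,
                           id = "rand100")
  )
}

#' Build a deterministic mini-proteome with a companion truth table
#'
#' Draws `n` records from the fixture catalog (cycling with distinct
#' random-member seeds), writes them as multi-FASTA text, and computes the
#' expected verdict and first-transition direction for each record by
#' running the scanner itself under the supplied configuration. Swapping in
#' a different scale, pKa set or boundary therefore regenerates a
#' consistent truth table rather than invalidating it.
#'
#' @param n number of records (>= 1).
#' @param seed integer seed controlling the random members.
#' @param scale,pkas,boundary configuration used for the truth table.
#' @param window,ci scan parameters for the truth table.
#' @return list with `fasta` (character scalar of FASTA text) and `truth`
#'   (data.frame: `id`, `verdict`, `first_direction`).
#' @export
make_mini_proteome <- function(n, seed = 0,
                               scale = lipophilicity_scale(),
                               pkas = pka_set(),
                               boundary = boundary_params(),
                               window = 51, ci = 0.02) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  base_kinds <- c("polyG", "polyK", "polyE", "VK25", "VE25", "VH25",
                  "rand100")
  records <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- base_kinds[((i - 1L) %% length(base_kinds)) + 1L]
    rec <- if (kind == "rand100") {
      make_fixture("random", length = 100, seed = seed + i,
                   id = sprintf("rand100_%03d", i))
    } else {
      cat_rec <- fixture_catalog()[[kind]]
      protein_record(sprintf("%s_%03d", kind, i), cat_rec$sequence)
    }
    records[[i]] <- rec
  }
  grid <- build_ph_grid(0, 14, 0.5)
  truth <- do.call(rbind, lapply(records, function(rec) {
    rep <- detect_transitions(
      scan_sequence(rec, grid, window, scale, pkas, boundary), ci)
    data.frame(
      id = rec$id, verdict = rep$verdict,
      first_direction = if (nrow(rep$transitions))
        rep$transitions$direction[1] else "",
      stringsAsFactors = FALSE)
  }))
  fasta <- paste(vapply(records, function(r)
    paste0(">", r$id, "\n", r$sequence), character(1)), collapse = "\n")
  list(fasta = paste0(fasta, "\n"), truth = truth)
}
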