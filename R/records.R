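# Sequence records and FASTA ingestion.

#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Tolerated ambiguity / non-standard codes: zero charge, mean lipophilicity.
#' @keywords internal
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

#' Construct a validated protein record
#'
#' @param id sequence identifier, non-empty and unique within a run.
#' @param sequence amino-acid sequence; upper-cased, must contain only the
#'   20 standard residues plus the tolerated ambiguity codes X, B, Z, U, O.
#' @param description optional free-text description.
#' @return an object of class `protein_record` with fields `id`,
#'   `description`, `sequence`.
#' @examples
#' protein_record("toy", "MKVE")
#' @export
protein_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("identifier must be a non-empty string", call. = FALSE)
  }
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("sequence for '", id, "' is empty", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- !(chars %in% c(AA_STANDARD, AA_AMBIGUOUS))
  if (any(bad)) {
    pos <- which(bad)[1]
    stop("invalid residue '", chars[pos], "' at position ", pos,
         " in sequence '", id, "'", call. = FALSE)
  }
  n_amb <- sum(chars %in% AA_AMBIGUOUS)
  if (n_amb > 0) {
    warning("sequence '", id, "' contains ", n_amb,
            " ambiguity code(s); scored as zero charge and mean lipophilicity",
            call. = FALSE)
  }
  structure(list(id = id, description = description, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(">", x$id, if (nzchar(x$description)) paste0(" ", x$description),
      "  (", n, " aa)\n", sep = "")
  if (n <= 60) cat(x$sequence, "\n", sep = "")
  else cat(substr(x$sequence, 1, 57), "...\n", sep = "")
  invisible(x)
}

#' Parse protein sequences from FASTA
#'
#' Accepts either a file path or FASTA text. Records are returned in input
#' order. Duplicate identifiers (the first whitespace-delimited token of the
#' header) are disambiguated with a numeric suffix (`x`, `x_2`, ...) and a
#' warning. Records failing validation (empty sequence, gap characters,
#' untolerated letters) are dropped with a warning and listed in the
#' `skipped` attribute; they never abort the run.
#'
#' @param x path to a FASTA file, or a character scalar of FASTA text.
#' @return a list of [protein_record()] objects, with attribute `skipped`:
#'   a data.frame of `id`, `reason` for rejected records.
#' @examples
#' parse_fasta(">a\nMKV\n>b\nGGG\n")
#' @export
parse_fasta <- function(x) {
  if (length(x) != 1L || !is.character(x)) {
    stop("input must be a single path or FASTA text string", call. = FALSE)
  }
  path <- x
  cleanup <- FALSE
  if (grepl("[\n>]", x)) {
    path <- tempfile(fileext = ".fasta")
    writeLines(sub("\n$", "", gsub("\r\n?", "\n", x)), path)
    cleanup <- TRUE
  } else if (!file.exists(x)) {
    stop("FASTA file not found: ", x, call. = FALSE)
  }
  on.exit(if (cleanup) unlink(path))
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("cannot read FASTA input: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(aas) == 0L) stop("no FASTA records found", call. = FALSE)
  headers <- names(aas)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[`, character(1), 1)
  desc <- sub("^[^[:space:]]+[[:space:]]*", "", headers)
  ids[is.na(ids) | !nzchar(ids)] <- sprintf("seq%d", which(is.na(ids) | !nzchar(ids)))
  # disambiguate duplicates with a numeric suffix
  if (anyDuplicated(ids)) {
    seen <- table(ids)
    dup_names <- names(seen)[seen > 1]
    warning("duplicate identifier(s) disambiguated: ",
            paste(dup_names, collapse = ", "), call. = FALSE)
    counts <- new.env(parent = emptyenv())
    ids <- vapply(ids, function(id) {
      k <- if (is.null(counts[[id]])) 1L else counts[[id]] + 1L
      counts[[id]] <- k
      if (k == 1L) id else paste0(id, "_", k)
    }, character(1), USE.NAMES = FALSE)
  }
  records <- vector("list", length(aas))
  skipped <- list()
  for (i in seq_along(aas)) {
    seq_i <- as.character(aas[[i]])
    rec <- tryCatch(
      protein_record(ids[i], seq_i, desc[i]),
      error = function(e) {
        warning("skipping record '", ids[i], "': ", conditionMessage(e),
                call. = FALSE)
        skipped[[length(skipped) + 1L]] <<- data.frame(
          id = ids[i], reason = conditionMessage(e),
          stringsAsFactors = FALSE)
        NULL
      }
    )
    records[[i]] <- rec
  }
  records <- records[!vapply(records, is.null, logical(1))]
  if (length(records) == 0L) {
    stop("no valid FASTA records after validation", call. = FALSE)
  }
  attr(records, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
  }
  records
}

# coerce a record or a plain string into a protein_record
as_protein_record <- function(x, id = "seq") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record(id, x))
  stop("expected a protein_record or a sequence string", call. = FALSE)
}
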