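#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein sequences, one row per
#' record, in file order. Sequence lines are unwrapped and uppercased.
#' Structural problems (a sequence line before any ">" header, a record
#' with no residues) raise an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (header text up to the first
#'   whitespace), `residues` (uppercased sequence string) and `length`.
#' @seealso [validate_sequences()], [load_labeled_dataset()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "LLLL"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  .check_fasta_structure(lines, path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  res <- toupper(as.character(set))
  out <- tibble::tibble(id = ids, residues = unname(res),
                        length = nchar(unname(res)))
  dup <- duplicated(out$id)
  if (any(dup)) {
    message("read_fasta: ", sum(dup), " duplicate id(s) in ", path,
            " (rows are keyed by position, not id)")
  }
  out
}

# Line-level structural checks so errors can name the line; record
# extraction itself is done by Biostrings.
.check_fasta_structure <- function(lines, path) {
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  is_header <- startsWith(trimws(lines), ">")
  first <- nonblank[1]
  if (!is_header[first]) {
    stop("malformed FASTA at line ", first, " of ", path,
         ": sequence data before any '>' header", call. = FALSE)
  }
  headers <- which(is_header)
  for (h in seq_along(headers)) {
    from <- headers[h] + 1L
    to <- if (h < length(headers)) headers[h + 1] - 1L else length(lines)
    body <- if (from > to) character(0) else lines[from:to]
    if (sum(nchar(trimws(body))) == 0) {
      stop("malformed FASTA at line ", headers[h], " of ", path,
           ": record '", sub("^>\\s*", "", trimws(lines[headers[h]])),
           "' has an empty sequence", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences A tibble with `id` and `residues` columns, as returned
#'   by [read_fasta()] or [simulate_enzyme_dataset()].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  set <- Biostrings::BStringSet(sequences$residues)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate protein sequences against the standard alphabet
#'
#' Flags residues outside the 20-letter standard amino-acid alphabet.
#' Ambiguous residues (B, J, O, U, X, Z), whitespace, stop codes ("*") and
#' any other character are all offenses; sequences are uppercased before
#' validation so case never causes rejection. Each offense is reported with
#' its 1-based position.
#'
#' @param sequences A tibble with `id` and `residues` columns (a single
#'   string is also accepted and treated as one unnamed sequence).
#' @return The input tibble with two added columns: `valid` (logical) and
#'   `offenses` (list column of tibbles with `position` and `residue` for
#'   each offending character; empty for valid sequences).
#' @export
#' @examples
#' validate_sequences(tibble::tibble(id = "s1", residues = "ACXDE"))
validate_sequences <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      id = paste0("seq", seq_along(sequences)), residues = sequences)
  }
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  res <- toupper(sequences$residues)
  aa <- amino_acids()
  offenses <- lapply(res, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% aa))
    tibble::tibble(position = bad, residue = ch[bad])
  })
  out <- sequences
  out$residues <- res
  out$length <- nchar(res)
  out$valid <- vapply(offenses, nrow, integer(1)) == 0L & nchar(res) > 0L
  out$offenses <- offenses
  out
}

#' Load a labeled two-class sequence dataset from FASTA files
#'
#' Reads a positive-class (enzyme) and a negative-class (non-enzyme) FASTA
#' file, validates every sequence against the standard alphabet, and returns
#' a single labeled tibble. Alternatively, a single FASTA plus a two-column
#' label table (id, label in {1, 0}) may be given via `labels`.
#'
#' @param pos_path FASTA of positive-class sequences (or, with `labels`,
#'   the single combined FASTA).
#' @param neg_path FASTA of negative-class sequences; ignored when `labels`
#'   is supplied.
#' @param on_invalid What to do with sequences failing validation:
#'   `"drop"` (remove, with a message stating how many) or `"fail"` (error).
#' @param labels Optional path to a TSV with columns `id` and `label`
#'   (1 = positive/enzyme, 0 = negative), used instead of `neg_path`.
#' @return A tibble with columns `id`, `residues`, `length` and `label`
#'   (factor with levels "positive", "negative").
#' @export
load_labeled_dataset <- function(pos_path, neg_path = NULL,
                                 on_invalid = c("drop", "fail"),
                                 labels = NULL) {
  on_invalid <- match.arg(on_invalid)
  if (!is.null(labels)) {
    seqs <- read_fasta(pos_path)
    lab_tbl <- readr::read_tsv(labels, show_col_types = FALSE,
                               col_types = readr::cols(
                                 id = readr::col_character(),
                                 label = readr::col_integer()))
    if (!all(seqs$id %in% lab_tbl$id)) {
      missing <- setdiff(seqs$id, lab_tbl$id)
      stop("label table is missing id(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    lab <- lab_tbl$label[match(seqs$id, lab_tbl$id)]
    seqs$label <- factor(ifelse(lab == 1, "positive", "negative"),
                         levels = c("positive", "negative"))
  } else {
    pos <- read_fasta(pos_path)
    neg <- read_fasta(neg_path)
    pos$label <- factor("positive", levels = c("positive", "negative"))
    neg$label <- factor("negative", levels = c("positive", "negative"))
    seqs <- dplyr::bind_rows(pos, neg)
  }
  checked <- validate_sequences(seqs)
  n_bad <- sum(!checked$valid)
  if (n_bad > 0) {
    if (on_invalid == "fail") {
      bad <- checked[!checked$valid, ]
      stop(n_bad, " sequence(s) failed validation (e.g. '", bad$id[1],
           "', offending residue '", bad$offenses[[1]]$residue[1],
           "' at position ", bad$offenses[[1]]$position[1], ")",
           call. = FALSE)
    }
    message("load_labeled_dataset: dropped ", n_bad,
            " sequence(s) containing non-standard residues")
    checked <- checked[checked$valid, ]
  }
  out <- checked[, c("id", "residues", "length", "label")]
  counts <- table(out$label)
  if (any(counts == 0)) {
    stop("class '", names(counts)[counts == 0][1],
         "' is empty after validation", call. = FALSE)
  }
  out
}
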