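# Readers and writers: FASTA sequences, interaction-pair tables, the
# AAindex1 flat file, and feature-matrix TSV.

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein records. The identifier is
#' the header token up to the first whitespace. Sequences are uppercased,
#' internal whitespace is dropped, and any letter outside the 20 canonical
#' residues (e.g. B, J, O, U, Z, or digits) is replaced by `"X"`; the number
#' of replacements is reported in a warning and attached as the
#' `"n_replaced"` attribute.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, one row per record, with
#'   attribute `n_replaced` (total residues replaced by `X`).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MVICL", ">p2", "ACDEFGH"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_format(paste0("FASTA file contains no records: ", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop_format("FASTA record with an empty header id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_format(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(gsub("\\s+", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop_format(paste0("empty sequence for id(s): ",
                       paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  canon <- paste0(c(amino_acids(), "X"), collapse = "")
  n_before <- sum(nchar(seqs))
  n_x_before <- vapply(seqs, function(s) {
    sum(strsplit(s, "")[[1]] == "X")
  }, integer(1))
  clean <- vapply(seqs, function(s) {
    gsub(paste0("[^", canon, "]"), "X", s)
  }, character(1), USE.NAMES = FALSE)
  n_x_after <- vapply(clean, function(s) sum(strsplit(s, "")[[1]] == "X"),
                      integer(1))
  n_replaced <- sum(n_x_after) - sum(n_x_before)
  if (n_replaced > 0L) {
    rlang::warn(paste0("read_fasta: replaced ", n_replaced,
                       " noncanonical residue(s) with 'X' in ", path))
  }
  out <- tibble::tibble(id = ids, seq = clean)
  attr(out, "n_replaced") <- n_replaced
  out
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  .check_records(records)
  set <- Biostrings::AAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.check_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    stop_input("protein records must be a data frame with columns 'id' and 'seq'")
  }
  if (nrow(records) == 0L) stop_input("protein record collection is empty")
  if (anyDuplicated(records$id)) {
    stop_input(paste0("duplicate protein id(s): ",
                      paste(unique(records$id[duplicated(records$id)]),
                            collapse = ", ")))
  }
  bad <- grepl(paste0("[^", paste0(c(amino_acids(), "X"), collapse = ""), "]"),
               records$seq) | !nzchar(records$seq)
  if (any(bad)) {
    stop_input(paste0("invalid sequence(s) for id(s): ",
                      paste(records$id[bad], collapse = ", ")))
  }
  invisible(records)
}

#' Bundle interaction pairs with their sequences
#'
#' Constructs a validated pair dataset: a pair table (`id_a`, `id_b`,
#' `label`) whose identifiers all resolve against a protein-record table.
#' Duplicate pairs with the same label are kept; the same unordered pair
#' appearing with conflicting labels is rejected.
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label` (0/1).
#' @param sequences Data frame with columns `id`, `seq`.
#' @return An object of class `pair_dataset`: a list with elements `pairs`
#'   (tibble) and `sequences` (tibble).
#' @export
pair_dataset <- function(pairs, sequences) {
  .check_records(sequences)
  if (!is.data.frame(pairs) ||
      !all(c("id_a", "id_b", "label") %in% names(pairs))) {
    stop_input("pairs must have columns 'id_a', 'id_b', 'label'")
  }
  lab <- pairs$label
  if (!all(lab %in% c(0L, 1L))) {
    stop_format(paste0("pair label(s) outside {0,1} at row(s): ",
                       paste(utils::head(which(!lab %in% c(0L, 1L)), 5),
                             collapse = ", ")))
  }
  missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)), sequences$id)
  if (length(missing_ids) > 0L) {
    stop_resolution(paste0("pair id(s) not found among sequences: ",
                           paste(utils::head(missing_ids, 10), collapse = ", ")))
  }
  key <- paste(pmin(pairs$id_a, pairs$id_b), pmax(pairs$id_a, pairs$id_b))
  conflict <- vapply(split(pairs$label, key),
                     function(l) length(unique(l)) > 1L, logical(1))
  if (any(conflict)) {
    stop_input(paste0("conflicting labels for unordered pair(s): ",
                      paste(utils::head(names(conflict)[conflict], 5),
                            collapse = "; ")))
  }
  structure(
    list(pairs = tibble::tibble(id_a = as.character(pairs$id_a),
                                id_b = as.character(pairs$id_b),
                                label = as.integer(lab)),
         sequences = tibble::as_tibble(sequences[, c("id", "seq")])),
    class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  n <- nrow(x$pairs)
  cat("<pair_dataset> ", n, " pairs (",
      sum(x$pairs$label == 1L), " positive / ",
      sum(x$pairs$label == 0L), " negative), ",
      nrow(x$sequences), " sequences\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pair_dataset <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_positive = sum(x$pairs$label == 1L),
    n_negative = sum(x$pairs$label == 0L),
    n_sequences = nrow(x$sequences),
    median_length = stats::median(nchar(x$sequences$seq)))
}

#' Read an interaction-pair table
#'
#' Reads a 3-column delimited text file (`id_a`, `id_b`, `label`); tab or
#' comma delimiters are auto-detected and an optional header row is skipped.
#' Identifiers are resolved against `sequences`; unresolved ids either raise
#' an error listing them (default) or drop those rows with a warning.
#'
#' @param path Path to the pair table.
#' @param sequences Protein records (data frame with `id`, `seq`), e.g. from
#'   [read_fasta()].
#' @param on_missing `"error"` (default) or `"drop"` for rows whose ids do
#'   not resolve.
#' @return A [pair_dataset()].
#' @export
read_pair_table <- function(path, sequences, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop_input(paste0("pair table not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(paste0("empty pair table: ", path))
  delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop_format(paste0("pair table row(s) without 3 fields at line(s): ",
                       paste(utils::head(which(nf != 3L), 5), collapse = ", ")))
  }
  m <- matrix(trimws(unlist(fields)), ncol = 3, byrow = TRUE)
  has_header <- is.na(suppressWarnings(as.integer(m[1, 3])))
  rows_offset <- 0L
  if (has_header) {
    m <- m[-1, , drop = FALSE]
    rows_offset <- 1L
    if (nrow(m) == 0L) stop_format(paste0("pair table has only a header: ", path))
  }
  lab_num <- suppressWarnings(as.integer(m[, 3]))
  bad <- is.na(lab_num) | !(lab_num %in% c(0L, 1L)) | !(m[, 3] %in% c("0", "1"))
  if (any(bad)) {
    stop_format(paste0("pair label outside {0,1} at file row(s): ",
                       paste(utils::head(which(bad) + rows_offset, 5),
                             collapse = ", ")))
  }
  pairs <- tibble::tibble(id_a = m[, 1], id_b = m[, 2], label = lab_num)
  missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)), sequences$id)
  if (length(missing_ids) > 0L && on_missing == "drop") {
    keep <- !(pairs$id_a %in% missing_ids | pairs$id_b %in% missing_ids)
    rlang::warn(paste0("read_pair_table: dropped ", sum(!keep),
                       " pair(s) with unresolved id(s): ",
                       paste(utils::head(missing_ids, 10), collapse = ", ")))
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) stop_resolution("all pairs had unresolved ids")
  }
  pair_dataset(pairs, sequences)
}

#' Write an interaction-pair table
#'
#' @param pairs Data frame with `id_a`, `id_b`, `label`, or a
#'   [pair_dataset()] (its `pairs` element is used).
#' @param path Output path; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  if (inherits(pairs, "pair_dataset")) pairs <- pairs$pairs
  readr::write_tsv(pairs[, c("id_a", "id_b", "label")], path, progress = FALSE)
  invisible(path)
}

#' Read an AAindex1 flat file
#'
#' Parses the AAindex1 dialect: entries start at an `H <accession>` line,
#' the numeric block follows the `I` line as two rows of ten values in the
#' standard residue order (`A R N D C Q E G H I / L K M F P S T W Y V`), and
#' entries end with `//`. Indices containing any `NA` value are excluded
#' (their accessions are kept in the `"excluded"` attribute); the remainder
#' are retained in file order.
#'
#' @param path Path to an AAindex1-format file.
#' @return An `aaindex_table`: a tibble with column `accession` plus one
#'   column per canonical residue (alphabetical order), one row per retained
#'   index; attributes `excluded` (character) and `retained_count`.
#' @export
#' @examples
#' tab <- read_aaindex1(system.file("extdata", "aaindex1_sample.txt",
#'                                  package = "ppitriad"))
#' attr(tab, "retained_count")
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop_input(paste0("AAindex file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  h_at <- grep("^H ", lines)
  if (length(h_at) == 0L) stop_format(paste0("no AAindex entries in: ", path))
  end_at <- grep("^//", lines)
  rows <- list()
  excluded <- character(0)
  for (h in h_at) {
    acc <- trimws(sub("^H ", "", lines[[h]]))
    entry_end <- end_at[end_at > h][1]
    if (is.na(entry_end)) stop_format(paste0("unterminated AAindex entry: ", acc))
    i_at <- grep("^I ", lines[h:entry_end])[1]
    if (is.na(i_at)) stop_format(paste0("AAindex entry without I line: ", acc))
    i_at <- h + i_at - 1L
    if (i_at + 2L > entry_end) {
      stop_format(paste0("truncated numeric block in AAindex entry: ", acc))
    }
    toks <- unlist(strsplit(trimws(lines[(i_at + 1L):(i_at + 2L)]), "\\s+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != 20L) {
      stop_format(paste0("AAindex entry ", acc, " has ", length(toks),
                         " values (expected 20)"))
    }
    if (any(toks == "NA")) {
      excluded <- c(excluded, acc)
      next
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop_format(paste0("malformed numeric block in AAindex entry: ", acc))
    }
    names(vals) <- .aaindex_order
    rows[[acc]] <- vals[amino_acids()]
  }
  if (length(rows) == 0L) {
    tab <- tibble::as_tibble(
      c(list(accession = character(0)),
        stats::setNames(rep(list(numeric(0)), 20), amino_acids())))
  } else {
    vals <- do.call(rbind, rows)
    tab <- tibble::as_tibble(as.data.frame(vals))
    tab <- tibble::add_column(tab, accession = names(rows), .before = 1)
  }
  attr(tab, "excluded") <- excluded
  attr(tab, "retained_count") <- nrow(tab)
  class(tab) <- c("aaindex_table", class(tab))
  tab
}

#' Write / read a feature matrix as tab-separated text
#'
#' The file has a header row (`pair_id` followed by the feature labels) and
#' one row per observation; values are written with 12 significant digits so
#' a write/read round-trip preserves them to that precision.
#'
#' @param x Numeric matrix (rows = pairs or proteins).
#' @param path Output path.
#' @param ids Row identifiers; defaults to `rownames(x)`.
#' @param feature_names Column labels; default `colnames(x)`.
#' @return `path` invisibly (writer); a numeric matrix with rownames
#'   (reader).
#' @export
write_feature_matrix <- function(x, path, ids = rownames(x),
                                 feature_names = colnames(x)) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(feature_names)) {
    stop_dimension("feature names are required (none supplied or on colnames)")
  }
  if (length(feature_names) != ncol(x)) {
    stop_dimension(paste0("feature name count (", length(feature_names),
                          ") does not match column count (", ncol(x), ")"))
  }
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(x)))
  if (length(ids) != nrow(x)) {
    stop_dimension("id count does not match row count")
  }
  body <- apply(x, 1, function(r) {
    paste(formatC(r, digits = 12, format = "g"), collapse = "\t")
  })
  if (nrow(x) == 0L) body <- character(0)
  writeLines(c(paste(c("pair_id", feature_names), collapse = "\t"),
               paste(ids, body, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_input(paste0("feature matrix not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) stop_format("feature matrix needs an id column and data")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}
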