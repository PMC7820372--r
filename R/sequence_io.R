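# Sequence I/O: labelled protein datasets, FASTA read/write, alphabet
# validation. All downstream modules consume the `apo_dataset` container
# built here.

#' Construct a labelled protein-sequence dataset
#'
#' The basic data container of the package: an ordered set of protein records
#' (id + amino-acid sequence) with optional parallel class labels. Sequences
#' are normalized to upper case; ids must be unique.
#'
#' @param ids Character vector of record identifiers, unique within the
#'   dataset.
#' @param sequences Character vector of amino-acid sequences, same length as
#'   `ids`. Lower-case residues are upper-cased; sequences are not otherwise
#'   validated here (see [validate_sequence()] and [filter_invalid()]).
#' @param labels Optional character vector of class labels parallel to
#'   `ids`, or `NULL` for an unlabelled dataset.
#' @param label_set Optional character vector declaring the admissible
#'   labels. Defaults to the distinct values of `labels`. Every label must be
#'   a member.
#' @return An object of class `apo_dataset`: a list with elements `ids`,
#'   `sequences`, `labels`, `label_set`.
#' @examples
#' d <- apo_dataset(c("p1", "p2"), c("ACDEFGHIK", "MNPQRSTVWY"),
#'                  labels = c("apo", "non-apo"))
#' length(d)
#' @export
apo_dataset <- function(ids, sequences, labels = NULL, label_set = NULL) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    stop_apofam("ids and sequences must have the same length")
  }
  if (anyDuplicated(ids)) {
    stop_apofam("duplicate record id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(ids)) {
      stop_apofam("labels must be parallel to records")
    }
    if (is.null(label_set)) label_set <- unique(labels)
    bad <- setdiff(labels, label_set)
    if (length(bad)) {
      stop_apofam("label(s) outside the declared label set: ",
                  paste(unique(bad), collapse = ", "))
    }
  }
  structure(list(ids = ids, sequences = sequences, labels = labels,
                 label_set = label_set),
            class = "apo_dataset")
}

#' @export
length.apo_dataset <- function(x) length(x$ids)

#' @export
`[.apo_dataset` <- function(x, i) {
  apo_dataset(x$ids[i], x$sequences[i],
              labels = if (!is.null(x$labels)) x$labels[i],
              label_set = x$label_set)
}

#' @export
print.apo_dataset <- function(x, ...) {
  cat("apo_dataset:", length(x), "records")
  if (!is.null(x$labels)) {
    cat(";", length(unique(x$labels)), "classes (",
        paste(utils::head(sort(unique(x$labels)), 8), collapse = ", "), ")")
  }
  cat("\n")
  if (length(x)) {
    cat("  sequence length range:", min(nchar(x$sequences)), "-",
        max(nchar(x$sequences)), "\n")
  }
  invisible(x)
}

#' Validate a sequence against the 20-letter amino-acid alphabet
#'
#' A sequence is valid iff it is non-empty and every character is one of the
#' 20 standard residues. Ambiguity and non-standard codes (B, J, O, U, X, Z)
#' and anything else are reported as offending characters.
#'
#' @param sequence A single character string (case-insensitive).
#' @return A list with `valid` (logical) and `invalid_chars` (character
#'   vector of distinct offending characters; empty when valid or when the
#'   sequence is empty).
#' @examples
#' validate_sequence("ACDEFG")$valid
#' validate_sequence("ACXDE")$invalid_chars
#' @export
validate_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(chars)) {
    return(list(valid = FALSE, invalid_chars = character(0)))
  }
  bad <- unique(chars[!chars %in% AA_ALPHABET])
  list(valid = length(bad) == 0L, invalid_chars = bad)
}

#' Read a FASTA file into a labelled dataset
#'
#' Records are returned in file order and residues upper-cased. Class labels
#' can ride in the header after a `|` separator (`>id|label`), be supplied as
#' a two-column TSV (columns `id`, `label`, with header), or be absent.
#'
#' @param path Path to a FASTA file.
#' @param label_source One of `"none"` (unlabelled), `"header"` (parse
#'   `id|label` headers), `"table"` (look ids up in `label_table`).
#' @param label_table For `label_source = "table"`: path to a TSV with header
#'   line `id<TAB>label`, or a data.frame with those columns.
#' @param label_set Optional declared label set (checked against the resolved
#'   labels).
#' @return An [apo_dataset].
#' @export
read_fasta <- function(path,
                       label_source = c("none", "header", "table"),
                       label_table = NULL, label_set = NULL) {
  label_source <- match.arg(label_source)
  if (!file.exists(path)) stop_apofam("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop_apofam("malformed FASTA in ", path, ": ",
                                conditionMessage(e))
                  })
  headers <- names(set)
  seqs <- as.character(set)
  # header token up to first whitespace
  headers <- sub("\\s.*$", "", headers)
  bad <- which(!nzchar(seqs))
  if (length(bad)) {
    stop_apofam("malformed FASTA: empty sequence for record '",
                headers[bad[1]], "'")
  }
  ids <- headers
  labels <- NULL
  if (label_source == "header") {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1L)
    labels <- vapply(parts, function(p) {
      if (length(p) >= 2L) p[[2L]] else NA_character_
    }, character(1))
    if (anyNA(labels)) {
      stop_apofam("record '", ids[which(is.na(labels))[1]],
                  "' has no |label in its header")
    }
  } else if (label_source == "table") {
    tab <- label_table
    if (is.character(tab)) tab <- read_label_table(tab)
    if (!all(c("id", "label") %in% names(tab))) {
      stop_apofam("label table must have columns 'id' and 'label'")
    }
    m <- match(ids, tab$id)
    if (anyNA(m)) {
      stop_apofam("no label for record(s): ",
                  paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
    }
    labels <- as.character(tab$label)[m]
  }
  if (!is.null(labels) && !is.null(label_set)) {
    bad <- setdiff(labels, label_set)
    if (length(bad)) {
      stop_apofam("unknown label string(s): ",
                  paste(unique(bad), collapse = ", "))
    }
  }
  apo_dataset(ids, seqs, labels = labels, label_set = label_set)
}

#' Read a two-column label table
#'
#' @param path TSV file with header line `id<TAB>label`.
#' @return A data.frame with character columns `id` and `label`.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("id", "label") %in% names(tab))) {
    stop_apofam("label table must have header 'id<TAB>label'")
  }
  tab
}

#' Write a dataset to FASTA (and optionally its labels to TSV)
#'
#' Sequences are wrapped at 60 columns. When the dataset is labelled, each
#' label is appended to the header after a `|` separator.
#'
#' @param dataset An [apo_dataset].
#' @param path Output FASTA path.
#' @param label_table_path Optional path; when given and the dataset is
#'   labelled, a TSV label table (`id<TAB>label`) is written there too.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(dataset, path, label_table_path = NULL) {
  stopifnot(inherits(dataset, "apo_dataset"))
  headers <- dataset$ids
  if (!is.null(dataset$labels)) {
    headers <- paste(dataset$ids, dataset$labels, sep = "|")
  }
  set <- Biostrings::BStringSet(dataset$sequences)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  if (!is.null(label_table_path) && !is.null(dataset$labels)) {
    utils::write.table(
      data.frame(id = dataset$ids, label = dataset$labels),
      label_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
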