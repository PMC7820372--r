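# Benchmark curation: character/length filtering, greedy identity-based
# redundancy reduction (CD-HIT-style, at 0.8 by default), and subfamily
# merging into the pooled "Apoelse" class.

#' Default subfamily merge map
#'
#' The small subfamilies ApoF, ApoH, ApoM, ApoN and ApoR are pooled into a
#' single class `Apoelse` for statistical tractability; the six large
#' subfamilies pass through unchanged.
#'
#' @return Named character vector mapping input label to output label.
#' @export
default_merge_map <- function() {
  keep <- c("ApoA", "ApoB", "ApoC", "ApoD", "ApoE", "ApoL")
  merged <- c("ApoF", "ApoH", "ApoM", "ApoN", "ApoR")
  c(stats::setNames(keep, keep),
    stats::setNames(rep("Apoelse", length(merged)), merged),
    Apoelse = "Apoelse")
}

#' Remove records with invalid characters or short sequences
#'
#' Keeps only records whose sequences consist solely of the 20 standard
#' residues (dropping e.g. B, J, O, U, X, Z) and have length at least
#' `min_length`. Order is preserved.
#'
#' @param dataset An [apo_dataset].
#' @param min_length Minimum sequence length retained (default 10).
#' @return The filtered [apo_dataset].
#' @export
filter_invalid <- function(dataset, min_length = 10L) {
  stopifnot(inherits(dataset, "apo_dataset"))
  if (!length(dataset)) return(dataset)
  ok <- vapply(dataset$sequences,
               function(s) validate_sequence(s)$valid, logical(1),
               USE.NAMES = FALSE) & nchar(dataset$sequences) >= min_length
  dataset[ok]
}

#' Pairwise sequence identity
#'
#' Global alignment (match 1, mismatch 0, linear gap penalty 1 per position)
#' via [Biostrings::pairwiseAlignment]; identity is the number of identical
#' aligned positions divided by the length of the shorter sequence (the
#' CD-HIT convention).
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  mat <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1, type = "global")
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity-based redundancy reduction
#'
#' CD-HIT-style clustering: sequences are visited in descending length order
#' (ties broken by id); each joins the first retained representative with
#' pairwise identity at or above the cutoff, otherwise it becomes a new
#' representative. Only representatives are returned, in their original
#' dataset order.
#'
#' @param dataset A non-empty [apo_dataset] of valid sequences.
#' @param identity_cutoff Identity threshold in (0, 1\]; the benchmark
#'   convention for this problem is 0.8.
#' @param representatives Optional character vector of record ids produced by
#'   an external clustering tool; when given, those records are returned
#'   directly and no alignment is performed.
#' @return The reduced [apo_dataset].
#' @export
reduce_redundancy <- function(dataset, identity_cutoff = 0.8,
                              representatives = NULL) {
  stopifnot(inherits(dataset, "apo_dataset"))
  if (!is.null(representatives)) {
    return(dataset[dataset$ids %in% representatives])
  }
  if (!is.numeric(identity_cutoff) || length(identity_cutoff) != 1L ||
      identity_cutoff <= 0 || identity_cutoff > 1) {
    stop_apofam("identity_cutoff must be in (0, 1]")
  }
  if (!length(dataset)) stop_apofam("dataset is empty")
  ord <- order(-nchar(dataset$sequences), dataset$ids)
  reps <- integer(0)
  for (i in ord) {
    s <- dataset$sequences[i]
    hit <- FALSE
    for (r in reps) {
      if (pairwise_identity(dataset$sequences[r], s) >= identity_cutoff) {
        hit <- TRUE
        break
      }
    }
    if (!hit) reps <- c(reps, i)
  }
  dataset[sort(reps)]
}

#' Merge subfamily labels
#'
#' Applies a label-to-label map to the dataset's labels, leaving records
#' untouched. By default the five small subfamilies are pooled into
#' `Apoelse` (see [default_merge_map()]).
#'
#' @param dataset A labelled [apo_dataset].
#' @param merge_map Named character vector mapping input label to output
#'   label. Labels absent from the map pass through unchanged only if they
#'   are already valid output labels.
#' @return The relabelled [apo_dataset]; record count and order unchanged.
#' @export
merge_subfamilies <- function(dataset, merge_map = default_merge_map()) {
  stopifnot(inherits(dataset, "apo_dataset"))
  if (is.null(dataset$labels)) stop_apofam("dataset has no labels")
  target_set <- unique(unname(merge_map))
  out <- ifelse(dataset$labels %in% names(merge_map),
                unname(merge_map[dataset$labels]), dataset$labels)
  bad <- setdiff(out, target_set)
  if (length(bad)) {
    stop_apofam("label(s) not in merge map and not a target label: ",
                paste(unique(bad), collapse = ", "))
  }
  apo_dataset(dataset$ids, dataset$sequences, labels = out,
              label_set = target_set)
}
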