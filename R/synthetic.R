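# Synthetic labelled protein generator. Emulates the two signal types the
# real classifiers exploit: per-class residue-composition bias (a Dirichlet
# profile per class) and class-specific k-spaced residue pairs stamped into
# the sequences. Ground truth (profiles + planted pairs) is returned with
# the data so tests never re-derive it.

#' Specification of a synthetic labelled protein dataset
#'
#' @param n_classes Number of classes (default 2).
#' @param n_per_class Sequences per class (default 30).
#' @param length_range Integer `c(min, max)` sequence length, `min >= 12`
#'   so every encoder precondition (k_max <= 5, gamma <= 10) holds
#'   (default `c(80, 200)`).
#' @param composition_concentration Symmetric Dirichlet concentration for
#'   the per-class residue profiles; small values give strongly contrasting
#'   compositions, large values make classes compositionally
#'   indistinguishable (default 5).
#' @param pair_signal_strength Probability that each eligible start position
#'   of a planted (a, b, k) pair is overwritten to realize the pair; 0
#'   disables pair signal (default 0.08).
#' @param planted_pairs_per_class Number of class-specific (a, b, k) pairs
#'   (default 3).
#' @param k_range Spacings the planted pairs are drawn from (default 0:3).
#' @param label_prefix Prefix for class labels and record ids.
#' @param seed RNG seed; the whole generation is a pure function of the spec
#'   (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L, n_per_class = 30L,
                           length_range = c(80L, 200L),
                           composition_concentration = 5,
                           pair_signal_strength = 0.08,
                           planted_pairs_per_class = 3L,
                           k_range = 0:3, label_prefix = "class",
                           seed = 1L) {
  if (n_classes < 1L) stop_apofam("n_classes must be >= 1")
  if (length_range[1L] < 12L) {
    stop_apofam("length_range minimum must be >= 12")
  }
  if (length_range[2L] < length_range[1L]) {
    stop_apofam("length_range must be increasing")
  }
  if (pair_signal_strength < 0) {
    stop_apofam("pair_signal_strength must be >= 0")
  }
  if (composition_concentration <= 0) {
    stop_apofam("composition_concentration must be > 0")
  }
  if (planted_pairs_per_class > 0 &&
      max(k_range) + 2L > length_range[1L]) {
    stop_apofam("sequences too short to plant pairs at spacing ",
                max(k_range))
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 composition_concentration = composition_concentration,
                 pair_signal_strength = pair_signal_strength,
                 planted_pairs_per_class = as.integer(planted_pairs_per_class),
                 k_range = as.integer(k_range),
                 label_prefix = label_prefix,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic labelled dataset
#'
#' Per class: a residue-frequency profile is drawn from a symmetric
#' Dirichlet; sequences are emitted i.i.d. from the profile; then each
#' planted class-specific (a, b, k) pair is stamped at every eligible start
#' position independently with probability `pair_signal_strength`
#' (position i gets residue a and position i + k + 1 residue b). Generation
#' is deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (labelled [apo_dataset]) and `truth`
#'   (per-class `profiles` 20-column matrix and `planted_pairs` data.frame
#'   with columns `class`, `a`, `b`, `k`, and the matching CKSAAP feature
#'   name).
#' @examples
#' g <- generate(synthetic_spec(n_classes = 2, n_per_class = 5, seed = 42))
#' g$dataset
#' g$truth$planted_pairs
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    labels_set <- paste0(spec$label_prefix, seq_len(spec$n_classes))
    profiles <- t(vapply(seq_len(spec$n_classes), function(i) {
      .rdirichlet1(rep(spec$composition_concentration, 20L))
    }, numeric(20L)))
    dimnames(profiles) <- list(labels_set, AA_ALPHABET)
    planted <- NULL
    if (spec$planted_pairs_per_class > 0L && spec$pair_signal_strength > 0) {
      planted <- do.call(rbind, lapply(labels_set, function(cl) {
        data.frame(class = cl,
                   a = sample(AA_ALPHABET, spec$planted_pairs_per_class,
                              replace = TRUE),
                   b = sample(AA_ALPHABET, spec$planted_pairs_per_class,
                              replace = TRUE),
                   k = sample(spec$k_range, spec$planted_pairs_per_class,
                              replace = TRUE),
                   stringsAsFactors = FALSE)
      }))
      planted$feature <- paste0("CKSAAP_k", planted$k, "_",
                                planted$a, planted$b)
    }
    ids <- character(0)
    seqs <- character(0)
    labels <- character(0)
    for (ci in seq_len(spec$n_classes)) {
      cl <- labels_set[ci]
      pp <- if (!is.null(planted)) planted[planted$class == cl, ] else NULL
      for (s in seq_len(spec$n_per_class)) {
        L <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
        chars <- sample(AA_ALPHABET, L, replace = TRUE,
                        prob = profiles[ci, ])
        if (!is.null(pp) && nrow(pp)) {
          for (r in seq_len(nrow(pp))) {
            gap <- pp$k[r] + 1L
            starts <- seq_len(L - gap)
            hit <- starts[stats::runif(length(starts)) <
                            spec$pair_signal_strength]
            if (length(hit)) {
              chars[hit] <- pp$a[r]
              chars[hit + gap] <- pp$b[r]
            }
          }
        }
        ids <- c(ids, sprintf("%s_%03d", cl, s))
        seqs <- c(seqs, paste(chars, collapse = ""))
        labels <- c(labels, cl)
      }
    }
    list(dataset = apo_dataset(ids, seqs, labels = labels,
                               label_set = labels_set),
         truth = list(profiles = profiles, planted_pairs = planted,
                      spec = spec))
  })
}

#' Generate the two-tier synthetic study set
#'
#' Mirrors the structure of the apolipoprotein benchmark: a positive set
#' with subfamily labels and a negative set, combined into a binary
#' (`apo` / `non-apo`) dataset, alongside the subfamily dataset of the
#' positives. The default sizes are the package's demonstration conditions:
#' seven subfamilies of 30 positives each and 200 negatives.
#'
#' @param spec_pos [synthetic_spec()] for the positives; its `n_classes`
#'   must equal `length(subfamily_labels)`. Default: 7 classes x 30.
#' @param spec_neg [synthetic_spec()] for the negatives (single class).
#'   Default: 200 sequences.
#' @param subfamily_labels Labels for the positive classes (default the
#'   seven apolipoprotein subfamilies ApoA, ApoB, ApoC, ApoD, ApoE, ApoL,
#'   Apoelse).
#' @return List with `binary` (pooled labelled dataset, labels `apo` /
#'   `non-apo`), `subfamily` (positives with subfamily labels), and `truth`
#'   (positive and negative ground truth).
#' @export
generate_two_tier <- function(
    spec_pos = synthetic_spec(n_classes = 7L, n_per_class = 30L,
                              label_prefix = "pos", seed = 101L),
    spec_neg = synthetic_spec(n_classes = 1L, n_per_class = 200L,
                              label_prefix = "neg", seed = 202L),
    subfamily_labels = c("ApoA", "ApoB", "ApoC", "ApoD", "ApoE", "ApoL",
                         "Apoelse")) {
  stopifnot(inherits(spec_pos, "synthetic_spec"),
            inherits(spec_neg, "synthetic_spec"))
  if (spec_pos$n_classes != length(subfamily_labels)) {
    stop_apofam("spec_pos$n_classes must equal length(subfamily_labels)")
  }
  pos <- generate(spec_pos)
  neg <- generate(spec_neg)
  sub_labels <- subfamily_labels[match(pos$dataset$labels,
                                       pos$dataset$label_set)]
  subfamily <- apo_dataset(pos$dataset$ids, pos$dataset$sequences,
                           labels = sub_labels,
                           label_set = subfamily_labels)
  binary <- apo_dataset(
    c(pos$dataset$ids, neg$dataset$ids),
    c(pos$dataset$sequences, neg$dataset$sequences),
    labels = c(rep("apo", length(pos$dataset)),
               rep("non-apo", length(neg$dataset))),
    label_set = c("apo", "non-apo"))
  list(binary = binary, subfamily = subfamily,
       truth = list(positive = pos$truth, negative = neg$truth))
}

#' Write a generated dataset with its ground truth
#'
#' FASTA + TSV label table + ground-truth JSON, the on-disk form used by the
#' command-line interface.
#'
#' @param generated Result of [generate()].
#' @param stem Output path stem; writes `<stem>.fasta`, `<stem>.labels.tsv`,
#'   `<stem>.truth.json`.
#' @export
write_synthetic <- function(generated, stem) {
  write_fasta(generated$dataset, paste0(stem, ".fasta"),
              label_table_path = paste0(stem, ".labels.tsv"))
  truth <- generated$truth
  jsonlite::write_json(
    list(profiles = as.data.frame(truth$profiles),
         planted_pairs = truth$planted_pairs,
         spec = unclass(truth$spec)),
    paste0(stem, ".truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(stem)
}
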