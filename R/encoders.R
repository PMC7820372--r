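# Sequence encoders: four fixed-length feature representations of a protein
# sequence. Each encoder is a pure function of (sequence, config); feature
# names are deterministic so matrices from different runs align by name.
#
#   DPC     400 dipeptide frequencies
#   CKSAAP  400 x (k_max + 1) k-spaced pair frequencies
#   188D    20 residue frequencies + 8 x (3 composition + 3 transition
#           + 15 distribution) CTD features
#   PseAAC  20 + 9 * gamma pseudo-amino-acid composition

.pair_names <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}

.check_residues <- function(chars, id = NULL) {
  bad <- unique(chars[!chars %in% AA_ALPHABET])
  if (length(bad)) {
    stop_apofam("sequence", if (!is.null(id)) paste0(" '", id, "'"),
                " contains non-standard residue(s): ",
                paste(bad, collapse = ", "))
  }
}

#' Dipeptide composition (DPC)
#'
#' Frequencies of the 400 ordered adjacent residue pairs: component (r, s) is
#' the count of dipeptide rs divided by L - 1, where L is the sequence
#' length. Pairs are ordered alphabetically, first residue major. The 400
#' components sum to 1.
#'
#' @param sequence A valid amino-acid sequence of length at least 2.
#' @return Named numeric vector of length 400 (names `DPC_<rs>`).
#' @examples
#' v <- encode_dpc("ACA")
#' v[v > 0]  # AC and CA each 0.5
#' @export
encode_dpc <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 2L) stop_apofam("DPC requires sequence length >= 2")
  .check_residues(chars)
  pairs <- paste0(chars[-L], chars[-1L])
  counts <- table(factor(pairs, levels = .pair_names()))
  stats::setNames(as.numeric(counts) / (L - 1L),
                  paste0("DPC_", .pair_names()))
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing k = 0..k_max, the frequency of every ordered residue pair
#' (a, b) with a at position i and b at position i + k + 1, normalized by the
#' number of such pairs in the sequence, N_total(k) = L - (k + 1). The k = 0
#' block equals the dipeptide composition; blocks are concatenated in
#' increasing k, 400 features each.
#'
#' @param sequence A valid amino-acid sequence with L >= k_max + 2.
#' @param k_max Maximum spacing, an integer in 0..5 (default 5).
#' @return Named numeric vector of length 400 * (k_max + 1)
#'   (names `CKSAAP_k<k>_<ab>`).
#' @export
encode_cksaap <- function(sequence, k_max = 5L) {
  if (!is.numeric(k_max) || k_max < 0 || k_max > 5 || k_max != round(k_max)) {
    stop_apofam("k_max must be an integer in 0..5")
  }
  k_max <- as.integer(k_max)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L <= k_max + 1L) {
    stop_apofam("CKSAAP with k_max = ", k_max,
                " requires sequence length >= ", k_max + 2L)
  }
  .check_residues(chars)
  pn <- .pair_names()
  out <- numeric(0)
  for (k in 0:k_max) {
    gap <- k + 1L
    n_total <- L - gap
    pairs <- paste0(chars[seq_len(n_total)], chars[seq_len(n_total) + gap])
    counts <- table(factor(pairs, levels = pn))
    block <- stats::setNames(as.numeric(counts) / n_total,
                             paste0("CKSAAP_k", k, "_", pn))
    out <- c(out, block)
  }
  out
}

#' 188-dimensional composition/transition/distribution (CTD) features
#'
#' 20 amino-acid frequencies (alphabetical), then for each of eight
#' physicochemical groupings that partition the alphabet into three groups:
#' three group-composition frequencies; three transition frequencies
#' (fraction of adjacent residue pairs whose members fall in two different
#' groups, unordered, normalized by L - 1); and fifteen distribution values
#' (for each group, the 1-based positions of its first, 25th-, 50th-,
#' 75th-percentile and last occurrence, each divided by L; all five are 0
#' when the group is absent). Total 20 + 8 * 21 = 188 features.
#'
#' The percentile position of group g with n occurrences is the position of
#' occurrence number `ceiling(q * n)`.
#'
#' @param sequence A valid amino-acid sequence of length at least 2.
#' @return Named numeric vector of length 188.
#' @export
encode_188d <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 2L) stop_apofam("188D requires sequence length >= 2")
  .check_residues(chars)
  freq <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  out <- stats::setNames(freq, paste0("AAC_", AA_ALPHABET))
  groupings <- ctd_groupings()
  for (prop in names(groupings)) {
    groups <- groupings[[prop]]
    gid <- integer(L)
    for (g in 1:3) gid[chars %in% groups[[g]]] <- g
    comp <- as.numeric(table(factor(gid, levels = 1:3))) / L
    names(comp) <- paste0("CTD_", prop, "_C", 1:3)
    a <- gid[-L]; b <- gid[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    trans <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
               sum(lo == 2 & hi == 3)) / (L - 1L)
    names(trans) <- paste0("CTD_", prop, "_T", c("12", "13", "23"))
    dist <- numeric(15)
    qs <- c(0, 0.25, 0.5, 0.75, 1)
    qn <- c("p0", "p25", "p50", "p75", "p100")
    for (g in 1:3) {
      pos <- which(gid == g)
      n_g <- length(pos)
      if (n_g > 0L) {
        idx <- pmax(1L, ceiling(qs * n_g))
        dist[(g - 1L) * 5L + 1:5] <- pos[idx] / L
      }
    }
    names(dist) <- paste0("CTD_", prop, "_D", rep(1:3, each = 5), "_",
                          rep(qn, 3))
    out <- c(out, comp, trans, dist)
  }
  out
}

#' Pseudo-amino-acid composition (PseAAC)
#'
#' Residue frequencies augmented with sequence-order correlation factors
#' computed from nine physicochemical property profiles (hydrophobicity,
#' hydrophilicity, side-chain mass, pK1, pK2, pI, rigidity, irreplaceability,
#' flexibility), each standardized to zero mean / unit variance over the 20
#' residues. For property p and tier j in 1..gamma the correlation factor is
#'
#'   tau(p, j) = (1 / (L - j)) * sum_i h_p(R_i) * h_p(R_(i+j))
#'
#' and the feature vector is the joint normalization of the 20 raw
#' frequencies f and the weighted factors w * tau, so that all 20 + 9 * gamma
#' components sum to 1. With gamma = 0 the encoder reduces to plain
#' amino-acid composition.
#'
#' @param sequence A valid amino-acid sequence with L >= gamma + 1.
#' @param gamma Number of correlation tiers (non-negative integer,
#'   default 10).
#' @param w Weight of the pseudo components (positive, default 0.05).
#' @return Named numeric vector of length 20 + 9 * gamma; names
#'   `PseAAC_f_<aa>` then `PseAAC_t<j>_<property>` (tier-major).
#' @export
encode_pseaac <- function(sequence, gamma = 10L, w = 0.05) {
  if (!is.numeric(gamma) || gamma < 0 || gamma != round(gamma)) {
    stop_apofam("gamma must be a non-negative integer")
  }
  if (!is.numeric(w) || w <= 0) stop_apofam("w must be positive")
  gamma <- as.integer(gamma)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L <= gamma) {
    stop_apofam("PseAAC with gamma = ", gamma,
                " requires sequence length >= ", gamma + 1L)
  }
  if (L < 2L && gamma == 0L) stop_apofam("PseAAC requires length >= 2")
  .check_residues(chars)
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  props <- pseaac_properties()
  out_names <- paste0("PseAAC_f_", AA_ALPHABET)
  if (gamma == 0L) {
    return(stats::setNames(f, out_names))
  }
  hseq <- props[, chars, drop = FALSE]  # 9 x L standardized property profile
  tau <- matrix(0, nrow(props), gamma)  # property x tier
  for (j in seq_len(gamma)) {
    i <- seq_len(L - j)
    tau[, j] <- rowSums(hseq[, i, drop = FALSE] *
                          hseq[, i + j, drop = FALSE]) / (L - j)
  }
  denom <- sum(f) + w * sum(tau)
  vec <- c(f / denom, w * as.vector(tau) / denom)  # tier-major, property-minor
  tier_names <- paste0("PseAAC_t", rep(seq_len(gamma), each = nrow(props)),
                       "_", rep(rownames(props), gamma))
  stats::setNames(vec, c(out_names, tier_names))
}

#' Encoder configuration
#'
#' Bundles the encoder choice and its parameters so a trained model can
#' re-encode query sequences exactly as its training data was encoded.
#'
#' @param encoder One of `"PseAAC"`, `"CKSAAP"`, `"DPC"`, `"D188"`.
#' @param gamma PseAAC tier count (default 10).
#' @param w PseAAC pseudo-component weight (default 0.05).
#' @param k_max CKSAAP maximum spacing in 0..5 (default 5).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(encoder = c("PseAAC", "CKSAAP", "DPC", "D188"),
                           gamma = 10L, w = 0.05, k_max = 5L) {
  encoder <- match.arg(encoder)
  if (!is.numeric(k_max) || k_max < 0 || k_max > 5) {
    stop_apofam("k_max must be in 0..5")
  }
  if (!is.numeric(gamma) || gamma < 0) stop_apofam("gamma must be >= 0")
  if (!is.numeric(w) || w <= 0) stop_apofam("w must be positive")
  structure(list(encoder = encoder, gamma = as.integer(gamma), w = w,
                 k_max = as.integer(k_max),
                 property_table_id = APOFAM_TABLE_VERSION),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("encoder_config:", x$encoder)
  if (x$encoder == "PseAAC") cat(" (gamma =", x$gamma, ", w =", x$w, ")")
  if (x$encoder == "CKSAAP") cat(" (k_max =", x$k_max, ")")
  cat("\n")
  invisible(x)
}

.encode_one <- function(sequence, config) {
  switch(config$encoder,
         PseAAC = encode_pseaac(sequence, config$gamma, config$w),
         CKSAAP = encode_cksaap(sequence, config$k_max),
         DPC = encode_dpc(sequence),
         D188 = encode_188d(sequence))
}

#' Encode a dataset into a feature matrix
#'
#' Applies the configured encoder to every record; row i is the encoding of
#' record i, rows named by record id and columns by the encoder's
#' deterministic feature names.
#'
#' @param dataset An [apo_dataset].
#' @param config An [encoder_config()], or an encoder name (parameters then
#'   taken from `...`).
#' @param ... Passed to [encoder_config()] when `config` is a name.
#' @return Numeric matrix, samples x features.
#' @examples
#' d <- apo_dataset(c("a", "b"), c("ACDEFGHIKLMN", "MNPQRSTVWYAC"))
#' dim(encode_dataset(d, "DPC"))
#' @export
encode_dataset <- function(dataset, config = encoder_config(), ...) {
  stopifnot(inherits(dataset, "apo_dataset"))
  if (is.character(config)) config <- encoder_config(config, ...)
  stopifnot(inherits(config, "encoder_config"))
  rows <- vector("list", length(dataset))
  for (i in seq_along(rows)) {
    rows[[i]] <- tryCatch(
      .encode_one(dataset$sequences[i], config),
      error = function(e) {
        stop_apofam("encoding record '", dataset$ids[i], "' failed: ",
                    conditionMessage(e))
      })
  }
  X <- do.call(rbind, rows)
  if (is.null(X)) {
    X <- matrix(numeric(0), 0L,
                length(.encode_one(strrep("A", 30L), config)))
    colnames(X) <- names(.encode_one(strrep("A", 30L), config))
  }
  rownames(X) <- dataset$ids
  X
}

#' Write / read a feature matrix as TSV
#'
#' Header = feature names; first column = sample id.
#'
#' @param X Numeric matrix with row and column names.
#' @param path TSV path.
#' @return `read_feature_matrix` returns the matrix; `write_feature_matrix`
#'   its path, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  X
}
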