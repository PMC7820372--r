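test_that("dipeptide composition matches hand-enumerated examples", {
  v <- encode_dpc("ACA")
  expect_length(v, 400L)
  expect_equal(unname(v["DPC_AC"]), 0.5)
  expect_equal(unname(v["DPC_CA"]), 0.5)
  expect_equal(sum(v), 1)
  expect_equal(unname(encode_dpc("AA")["DPC_AA"]), 1)
  expect_error(encode_dpc("A"), "length")
})

test_that("CKSAAP matches hand-enumerated examples and block contracts", {
  v0 <- encode_cksaap("AAAA", k_max = 0)
  expect_length(v0, 400L)
  expect_equal(unname(v0["CKSAAP_k0_AA"]), 1)
  v1 <- encode_cksaap("ACAC", k_max = 1)
  expect_length(v1, 800L)
  expect_equal(unname(v1["CKSAAP_k1_AA"]), 0.5)
  expect_equal(unname(v1["CKSAAP_k1_CC"]), 0.5)
  # denominator for the k-block of an L=10 sequence is L - (k+1)
  withr::local_seed(31)
  s <- random_sequence(10)
  v2 <- encode_cksaap(s, k_max = 2)
  k2 <- v2[grepl("^CKSAAP_k2_", names(v2))]
  counts <- naive_pair_counts(s, 2)
  expect_equal(sum(k2 * 7), sum(counts))
  expect_equal(unname(k2[paste0("CKSAAP_k2_", rownames(counts)[1],
                                colnames(counts)[3])]),
               counts[1, 3] / 7)
  expect_error(encode_cksaap("ACDEF", k_max = 5), "length")
  expect_error(encode_cksaap("ACDEF", k_max = 6), "k_max")
})

test_that("pair-count encoders agree exactly with a naive double loop", {
  withr::local_seed(32)
  for (rep in 1:25) {
    L <- sample(8:30, 1)
    s <- random_sequence(L)
    dpc <- encode_dpc(s)
    expect_equal(matrix(dpc * (L - 1), 20, 20, byrow = TRUE),
                 unname(naive_pair_counts(s, 0) + 0),
                 ignore_attr = TRUE)
    k_max <- sample(0:min(5, L - 2), 1)
    ck <- encode_cksaap(s, k_max)
    for (k in 0:k_max) {
      blk <- ck[grepl(paste0("^CKSAAP_k", k, "_"), names(ck))]
      expect_equal(matrix(blk * (L - k - 1), 20, 20, byrow = TRUE),
                   unname(naive_pair_counts(s, k) + 0),
                   ignore_attr = TRUE)
    }
  }
})

test_that("188D layout: frequencies, single-group degenerate, distribution", {
  withr::local_seed(33)
  s <- random_sequence(60)
  v <- encode_188d(s)
  expect_length(v, 188L)
  expect_equal(sum(v[1:20]), 1)
  # all residues in one hydrophobicity group: no transitions, composition
  # concentrated on one group
  hydro <- encode_188d(strrep("RKED", 10))  # all polar group
  tr <- hydro[grepl("^CTD_hydrophobicity_T", names(hydro))]
  expect_equal(unname(tr), c(0, 0, 0))
  comp <- hydro[grepl("^CTD_hydrophobicity_C", names(hydro))]
  expect_equal(sort(unname(comp)), c(0, 0, 1))
  # distribution of a group occupying the whole sequence
  d <- hydro[grepl("^CTD_hydrophobicity_D1_", names(hydro))]
  expect_equal(unname(d), c(1 / 40, 10 / 40, 20 / 40, 30 / 40, 1))
  # absent group contributes zeros
  d3 <- hydro[grepl("^CTD_hydrophobicity_D3_", names(hydro))]
  expect_equal(unname(d3), rep(0, 5))
})

test_that("PseAAC reduces to composition at gamma 0 and matches a naive
           re-coding", {
  withr::local_seed(34)
  s <- random_sequence(40)
  v0 <- encode_pseaac(s, gamma = 0)
  expect_length(v0, 20L)
  expect_equal(sum(v0), 1)
  chars <- strsplit(s, "")[[1]]
  expect_equal(unname(v0), as.numeric(table(factor(chars, AA_ALPHABET))) / 40)
  v10 <- encode_pseaac(s, gamma = 10)
  expect_length(v10, 110L)
  expect_equal(sum(v10), 1)
  for (rep in 1:5) {
    L <- sample(15:30, 1)
    gamma <- sample(1:8, 1)
    s <- random_sequence(L)
    expect_equal(unname(encode_pseaac(s, gamma, w = 0.05)),
                 naive_pseaac(s, gamma, w = 0.05), tolerance = 1e-12)
  }
  expect_error(encode_pseaac(random_sequence(8), gamma = 10), "length")
})

test_that("dimensional contracts and normalizations hold on random input", {
  withr::local_seed(35)
  for (rep in 1:10) {
    s <- random_sequence(sample(20:60, 1))
    expect_length(encode_dpc(s), 400L)
    expect_equal(sum(encode_dpc(s)), 1, tolerance = 1e-9)
    k <- sample(0:5, 1)
    ck <- encode_cksaap(s, k)
    expect_length(ck, 400L * (k + 1))
    for (kk in 0:k) {
      expect_equal(sum(ck[grepl(paste0("^CKSAAP_k", kk, "_"), names(ck))]),
                   1, tolerance = 1e-9)
    }
    g <- sample(0:10, 1)
    ps <- encode_pseaac(s, g)
    expect_length(ps, 20L + 9L * g)
    expect_equal(sum(ps), 1, tolerance = 1e-9)
    v <- encode_188d(s)
    expect_length(v, 188L)
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-9)
  }
})

test_that("dataset encoding is row-parallel, order-equivariant and pure", {
  withr::local_seed(36)
  d <- tiny_dataset(5, L = 50)
  X <- encode_dataset(d, "DPC")
  expect_identical(dim(X), c(5L, 400L))
  expect_identical(rownames(X), d$ids)
  expect_identical(X[3, ], encode_dpc(d$sequences[3]))
  perm <- c(4, 1, 5, 2, 3)
  expect_identical(encode_dataset(d[perm], "DPC"), X[perm, ])
  # identical records produce identical rows; same input twice is bitwise
  # identical
  dd <- apo_dataset(c("u", "v"), rep(d$sequences[1], 2))
  Xd <- encode_dataset(dd, encoder_config("PseAAC", gamma = 5))
  expect_identical(Xd["u", ], Xd["v", ], ignore_attr = TRUE)
  expect_identical(encode_dataset(d, "D188"), encode_dataset(d, "D188"))
  short <- apo_dataset(c("a", "tooshort"), c(strrep("AC", 20), "ACDEF"))
  expect_error(encode_dataset(short, encoder_config("PseAAC", gamma = 10)),
               "tooshort")
})

test_that("feature matrices survive a TSV round trip", {
  withr::local_seed(37)
  d <- tiny_dataset(3, L = 25)
  X <- encode_dataset(d, encoder_config("CKSAAP", k_max = 1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(X, tsv)
  back <- read_feature_matrix(tsv)
  expect_identical(colnames(back), colnames(X))
  expect_equal(back, X, tolerance = 1e-12)
})
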