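test_that("conjoint triads match hand-enumerated frequencies", {
  # all of A, G, V sit in class 1: the homopolymer-like case
  v <- conjoint_triad("AGVAGV")
  expect_length(v, 343L)
  expect_equal(unname(v["ct_111"]), 1.0)
  expect_equal(sum(v), 1.0)

  # ARNDC: classes 1,5,4,6,7 -> three distinct overlapping triads
  v <- conjoint_triad("ARNDC")
  nz <- v[v > 0]
  expect_equal(sort(names(nz)), sort(c("ct_154", "ct_467", "ct_546")))
  expect_equal(unname(nz), rep(1 / 3, 3))

  expect_error(conjoint_triad("MV"), class = "ppi_length_error")
  expect_error(conjoint_triad("AXXA"), class = "ppi_degenerate_error")
})

test_that("triads containing X are skipped and excluded from the denominator", {
  # AGXAG: windows AGX, GXA, XAG invalid; only none remain of length-3...
  # use a longer case with one interior X
  v <- conjoint_triad("AGVXAGV")  # valid windows: AGV, AGV (2 of 5)
  expect_equal(unname(v["ct_111"]), 1.0)
  v2 <- spaced_conjoint_triad("AAXAAAA")  # windows at i=1,2 hit X; i=3 ok
  expect_equal(sum(v2), 1.0)
  expect_equal(unname(v2["sct_AAA"]), 1.0)
})

test_that("spaced conjoint triads read the (i, i+2, i+4) pattern", {
  v <- spaced_conjoint_triad("MVICL")
  expect_length(v, 8000L)
  expect_equal(unname(v["sct_MIL"]), 1.0)
  expect_equal(sum(v > 0), 1L)

  v <- spaced_conjoint_triad("AAAAAA")  # two windows, both AAA
  expect_equal(unname(v["sct_AAA"]), 1.0)

  # class7 alphabet collapses to 343 dimensions
  v7 <- spaced_conjoint_triad("MVICL", encoder_config(sct_alphabet = "class7"))
  expect_length(v7, 343L)
  # M->3, I->2, L->2
  expect_equal(unname(v7["sct_322"]), 1.0)

  expect_error(spaced_conjoint_triad("MVIC"), class = "ppi_length_error")
})

test_that("CT and SCT agree with the brute-force enumeration oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    # sprinkle occasional X to exercise the skip rule
    letters <- c(amino_acids(), if (rep %% 3 == 0) "X")
    s <- random_seq(n, letters)
    ct_ok <- !inherits(try(conjoint_triad(s), silent = TRUE), "try-error")
    if (ct_ok) {
      v <- conjoint_triad(s)
      o <- oracle_ct(s)
      expect_equal(v, o[names(v)], tolerance = 1e-12)
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-9)
    }
    v <- spaced_conjoint_triad(s)
    o <- oracle_sct(s)
    expect_equal(v, o[names(v)], tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-9)
    v7 <- spaced_conjoint_triad(s, encoder_config(sct_alphabet = "class7"))
    o7 <- oracle_sct(s, "class7")
    expect_equal(v7, o7[names(v7)], tolerance = 1e-12)
  }
})

test_that("AAindex means average each retained index over non-X positions", {
  tab <- read_aaindex1(system.file("extdata", "aaindex1_sample.txt",
                                   package = "ppitriad"))
  v <- aaindex_means("IIII", tab)
  expect_length(v, 3L)
  expect_equal(unname(v["aaidx_KYTJ820101"]), 4.5)
  expect_equal(unname(aaindex_means("IV", tab)["aaidx_KYTJ820101"]), 4.35)
  # X positions are excluded from the mean
  expect_equal(aaindex_means("IXV", tab), aaindex_means("IV", tab))
  expect_error(aaindex_means("XXX", tab), class = "ppi_degenerate_error")

  # brute-force position-wise mean on random sequences
  set.seed(7)
  vals <- as.matrix(tab[, amino_acids()])
  for (i in 1:20) {
    s <- random_seq(sample(5:80, 1))
    chars <- strsplit(s, "")[[1]]
    manual <- rowMeans(vals[, match(chars, amino_acids()), drop = FALSE])
    expect_equal(unname(aaindex_means(s, tab)), unname(manual),
                 tolerance = 1e-12)
  }
})

test_that("hydropathy features are the scale means", {
  v <- hydropathy_features("IIII")
  expect_equal(unname(v), c(4.5, -1.8))
  expect_equal(unname(hydropathy_features("IV")["hydrophobicity"]), 4.35)
  # mean of a concatenation of equal-length halves = mean of the two means
  s1 <- "ACDEF"; s2 <- "GHIKL"
  both <- hydropathy_features(paste0(s1, s2))
  expect_equal(both,
               (hydropathy_features(s1) + hydropathy_features(s2)) / 2)
  expect_error(hydropathy_features("XX"), class = "ppi_degenerate_error")
})

test_that("AAPD matches hand enumeration and the brute-force oracle", {
  expect_equal(unname(aapd("AGA")), 2.0)
  expect_equal(unname(aapd("AAAA")), 10 / 6)
  expect_equal(unname(aapd("ARND")), 0.0)  # C = 0 convention
  set.seed(11)
  for (i in 1:40) {
    s <- random_seq(sample(2:120, 1), c(amino_acids(), "X"))
    expect_equal(unname(aapd(s)), oracle_aapd(s), tolerance = 1e-12)
  }
})

test_that("aapd is invariant under sequence reversal", {
  set.seed(3)
  for (i in 1:25) {
    s <- random_seq(sample(2:100, 1))
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(aapd(s), aapd(rs))
  }
})

test_that("encoders are pure: identical inputs give identical outputs", {
  s <- random_seq(60)
  expect_identical(conjoint_triad(s), conjoint_triad(s))
  expect_identical(spaced_conjoint_triad(s), spaced_conjoint_triad(s))
  expect_identical(aapd(s), aapd(s))
})

test_that("encode_proteins stacks blocks in order with a consistent schema", {
  tab <- read_aaindex1(system.file("extdata", "aaindex1_sample.txt",
                                   package = "ppitriad"))
  recs <- tibble::tibble(id = c("p1", "p2"),
                         seq = c("MVICLAGHKW", "ARNDCEQGHIKL"))
  cfg <- encoder_config(pssm_L_max = 15)
  pssm <- build_dataset_pssm(recs, cfg)
  x <- encode_proteins(recs, cfg, pssm = pssm, aaindex = tab)
  sch <- attr(x, "schema")
  expect_equal(sch$block,
               c("ct", "sct", "pssm", "aaindex", "hydropathy", "aapd"))
  expect_equal(sum(sch$dim), ncol(x))
  expect_equal(ncol(x), 343 + 8000 + 15 + 3 + 2 + 1)
  expect_true(all(is.finite(x)))

  # block flags shrink the matrix accordingly, in every combination tried
  for (off in list("sct", c("pssm", "aaindex"),
                   c("ct", "sct", "pssm", "aaindex", "hydropathy"))) {
    cfg2 <- disable_blocks(cfg, off)
    x2 <- encode_proteins(recs, cfg2, pssm = pssm, aaindex = tab)
    expect_equal(ncol(x2), sum(attr(x2, "schema")$dim))
    expect_false(any(off %in% attr(x2, "schema")$block))
  }

  # CT-only
  x3 <- encode_proteins(recs, disable_blocks(cfg, c("sct", "pssm", "aaindex",
                                                    "hydropathy", "aapd")))
  expect_equal(ncol(x3), 343L)
})

test_that("encoder errors are annotated with the protein id", {
  recs <- tibble::tibble(id = c("ok", "tiny"), seq = c("MVICLA", "MV"))
  cfg <- encoder_config(use_pssm = FALSE, use_aaindex = FALSE)
  expect_error(encode_proteins(recs, cfg), regexp = "tiny")
})

test_that("pair vectors concatenate A then B and detect mismatches", {
  cfg <- encoder_config(use_pssm = FALSE, use_aaindex = FALSE)
  ba <- encode_protein("MVICLW", cfg)
  bb <- encode_protein("ARNDCQH", cfg)
  v <- assemble_pair_vector(ba, bb)
  expect_length(v, 2 * (343 + 8000 + 2 + 1))
  expect_equal(unname(v[1:8346]), unname(unlist(ba)))
  # swapped order is a permutation of the same multiset of values
  v2 <- assemble_pair_vector(bb, ba)
  expect_equal(sort(unname(v)), sort(unname(v2)))

  bb7 <- encode_protein("ARNDCQH", encoder_config(sct_alphabet = "class7",
                                                  use_pssm = FALSE,
                                                  use_aaindex = FALSE))
  expect_error(assemble_pair_vector(ba, bb7), class = "ppi_dimension_error")
})

test_that("assemble_pair_features builds rows per pair with optional symmetry", {
  cfg <- encoder_config(use_pssm = FALSE, use_aaindex = FALSE)
  recs <- tibble::tibble(id = c("p1", "p2", "p3"),
                         seq = c("MVICLW", "ARNDCQH", "GGGGGGG"))
  ds <- pair_dataset(tibble::tibble(id_a = c("p1", "p2"),
                                    id_b = c("p2", "p3"),
                                    label = c(1L, 0L)), recs)
  feats <- encode_proteins(recs, cfg)
  pf <- assemble_pair_features(ds, feats)
  expect_equal(dim(pf$x), c(2L, 2L * ncol(feats)))
  expect_equal(pf$y, c(1L, 0L))
  sym <- assemble_pair_features(ds, feats, symmetric = TRUE)
  expect_equal(nrow(sym$x), 4L)
  expect_equal(sym$y, c(1L, 0L, 1L, 0L))
  expect_equal(unname(sym$x[3, ]),
               unname(c(feats["p2", ], feats["p1", ])))
})
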