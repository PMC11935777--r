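test_that("generate_sequence draws from the background distribution", {
  set.seed(1)
  s <- generate_sequence(10000)
  freq <- table(factor(strsplit(s, "")[[1]], levels = amino_acids())) / 10000
  expect_true(all(abs(freq - 0.05) < 0.01))

  # degenerate background gives a homopolymer
  bg <- stats::setNames(c(1, rep(0, 19)), amino_acids())
  expect_equal(generate_sequence(5, bg), "AAAAA")

  set.seed(42); a <- generate_sequence(50)
  set.seed(42); b <- generate_sequence(50)
  expect_identical(a, b)
  expect_error(generate_sequence(0), class = "ppi_input_error")
})

test_that("plant_spaced_motif overwrites exactly the spaced positions", {
  expect_equal(plant_spaced_motif("AAAAA", c("M", "I", "L"), 1), "MAIAL")
  out <- plant_spaced_motif(strrep("A", 10), c("M", "I", "L"), 6)
  expect_equal(substr(out, 1, 5), "AAAAA")
  expect_equal(substr(out, 6, 10), "MAIAL")
  v <- spaced_conjoint_triad(out)
  expect_gt(v["sct_MIL"], 0)
  expect_error(plant_spaced_motif("AAAAA", c("M", "I", "L"), 2),
               class = "ppi_input_error")
})

test_that("the generated dataset is balanced, valid and reproducible", {
  cfg <- synthetic_config(n_pairs = 40, seed = 11)
  ds <- generate_ppi_dataset(cfg)
  g <- glance(ds)
  expect_equal(g$n_positive, 20L)
  expect_equal(g$n_negative, 20L)
  expect_equal(g$n_sequences, 80L)
  expect_true(all(nchar(ds$sequences$seq) >= 50 &
                    nchar(ds$sequences$seq) <= 100))
  ds2 <- generate_ppi_dataset(cfg)
  expect_identical(ds, ds2)
  expect_error(synthetic_config(n_pairs = 7), class = "ppi_input_error")
})

test_that("written synthetic files are byte-identical across reruns", {
  cfg <- synthetic_config(n_pairs = 20, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_ppi_files(cfg, d1)
  p2 <- simulate_ppi_files(cfg, d2)
  expect_identical(readLines(p1$fasta), readLines(p2$fasta))
  expect_identical(readLines(p1$pairs), readLines(p2$pairs))
  # header + 20 rows
  expect_length(readLines(p1$pairs), 21L)
  # manifest carries the seed and a config hash
  man <- jsonlite::read_json(p1$manifest)
  expect_equal(man$seed, 5L)
  expect_true(nzchar(man$config_hash))
  # refuses to clobber without force
  expect_error(simulate_ppi_files(cfg, d1), class = "ppi_input_error")
  expect_silent(simulate_ppi_files(cfg, d1, force = TRUE))
})

test_that("round-tripping synthetic files through the readers preserves the dataset", {
  cfg <- synthetic_config(n_pairs = 30, seed = 9)
  dir <- withr::local_tempdir()
  paths <- simulate_ppi_files(cfg, dir)
  seqs <- read_fasta(paths$fasta)
  ds <- read_pair_table(paths$pairs, seqs)
  orig <- generate_ppi_dataset(cfg)
  expect_equal(ds$pairs, orig$pairs)
  expect_equal(dplyr::arrange(ds$sequences, id),
               dplyr::arrange(orig$sequences, id), ignore_attr = TRUE)
})

test_that("signal-carrying positives contain the motifs, scrubbed negatives do not", {
  cfg <- synthetic_config(n_pairs = 60, signal_strength = 1, seed = 3)
  ds <- generate_ppi_dataset(cfg)
  hits <- function(seq, motif) {
    length(ppitriad:::.motif_hits(strsplit(seq, "")[[1]], motif))
  }
  seq_of <- function(id) ds$sequences$seq[ds$sequences$id == id]
  pos <- ds$pairs[ds$pairs$label == 1L, ]
  neg <- ds$pairs[ds$pairs$label == 0L, ]
  expect_true(all(vapply(pos$id_a, function(i) hits(seq_of(i), cfg$motif_a) > 0,
                         logical(1))))
  expect_true(all(vapply(pos$id_b, function(i) hits(seq_of(i), cfg$motif_b) > 0,
                         logical(1))))
  expect_true(all(vapply(neg$id_a, function(i) hits(seq_of(i), cfg$motif_a) == 0,
                         logical(1))))
  expect_true(all(vapply(neg$id_b, function(i) hits(seq_of(i), cfg$motif_b) == 0,
                         logical(1))))
})
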