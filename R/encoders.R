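# Per-protein feature encoders: conjoint triads, spaced conjoint triads,
# AAindex property means, hydropathy means, and amino-acid pairwise distance.
# The dataset-level PSSM lives in pssm.R.

#' Encoder configuration
#'
#' Collects every tunable of the six per-protein feature encoders and which
#' blocks are enabled. The declared per-protein dimension is the sum of the
#' enabled block dimensions; a pair vector is twice that.
#'
#' @param sct_alphabet Alphabet for the spaced-conjoint-triad block:
#'   `"raw20"` (default; 20^3 = 8000 features over raw residues, matching
#'   the `MVICL -> MIL` reading of the spaced triad) or `"class7"`
#'   (7^3 = 343 features over the conjoint classes).
#' @param pssm_L_max Number of positions retained by the PSSM block;
#'   sequences are truncated / zero-padded to this length. Default 500.
#' @param pssm_pseudocount Laplace pseudocount added to positional and
#'   background counts. Default 1; with 0, zero-probability scores are
#'   floored at `pssm_floor` instead of `-Inf`.
#' @param pssm_mode `"observed_residue"` (default; one score per position,
#'   the log-odds of the residue actually observed there) or `"full20"`
#'   (all 20 scores per position, `20 * pssm_L_max` features).
#' @param pssm_floor Score used when `pssm_pseudocount = 0` meets a zero
#'   count. Default -20.
#' @param hydrophobicity,hydrophilicity Named 20-vectors used by the
#'   hydropathy block; defaults [kyte_doolittle()] and [hopp_woods()].
#' @param use_ct,use_sct,use_pssm,use_aaindex,use_hydropathy,use_aapd
#'   Logical flags enabling each feature block.
#' @return An object of class `encoder_config`.
#' @export
#' @examples
#' cfg <- encoder_config(use_pssm = FALSE, use_aaindex = FALSE)
encoder_config <- function(sct_alphabet = c("raw20", "class7"),
                           pssm_L_max = 500,
                           pssm_pseudocount = 1,
                           pssm_mode = c("observed_residue", "full20"),
                           pssm_floor = -20,
                           hydrophobicity = kyte_doolittle(),
                           hydrophilicity = hopp_woods(),
                           use_ct = TRUE, use_sct = TRUE, use_pssm = TRUE,
                           use_aaindex = TRUE, use_hydropathy = TRUE,
                           use_aapd = TRUE) {
  sct_alphabet <- match.arg(sct_alphabet)
  pssm_mode <- match.arg(pssm_mode)
  if (pssm_L_max < 1) stop_input("pssm_L_max must be >= 1")
  if (pssm_pseudocount < 0) stop_input("pssm_pseudocount must be >= 0")
  for (sc in list(hydrophobicity, hydrophilicity)) {
    if (!all(amino_acids() %in% names(sc))) {
      stop_input("hydropathy scales must name all 20 canonical residues")
    }
  }
  structure(list(sct_alphabet = sct_alphabet,
                 pssm_L_max = as.integer(pssm_L_max),
                 pssm_pseudocount = pssm_pseudocount,
                 pssm_mode = pssm_mode,
                 pssm_floor = pssm_floor,
                 hydrophobicity = hydrophobicity[amino_acids()],
                 hydrophilicity = hydrophilicity[amino_acids()],
                 use_ct = isTRUE(use_ct), use_sct = isTRUE(use_sct),
                 use_pssm = isTRUE(use_pssm),
                 use_aaindex = isTRUE(use_aaindex),
                 use_hydropathy = isTRUE(use_hydropathy),
                 use_aapd = isTRUE(use_aapd)),
            class = "encoder_config")
}

#' Disable feature blocks in an encoder configuration
#'
#' Convenience for ablation experiments: returns a copy of `config` with
#' the named blocks switched off.
#'
#' @param config An [encoder_config()].
#' @param blocks Character vector among
#'   `c("ct", "sct", "pssm", "aaindex", "hydropathy", "aapd")`.
#' @return The modified `encoder_config`.
#' @export
disable_blocks <- function(config, blocks) {
  known <- c("ct", "sct", "pssm", "aaindex", "hydropathy", "aapd")
  bad <- setdiff(blocks, known)
  if (length(bad) > 0L) {
    stop_input(paste0("unknown feature block(s): ", paste(bad, collapse = ", ")))
  }
  for (b in blocks) config[[paste0("use_", b)]] <- FALSE
  config
}

# Declared dimension of each enabled block. aaindex_n is the number of
# retained indices (needed because that block's width is data-dependent).
block_dims <- function(config, aaindex_n = NULL) {
  dims <- c(
    ct = if (config$use_ct) 343L else NA_integer_,
    sct = if (config$use_sct) {
      if (config$sct_alphabet == "raw20") 8000L else 343L
    } else NA_integer_,
    pssm = if (config$use_pssm) {
      if (config$pssm_mode == "full20") 20L * config$pssm_L_max
      else config$pssm_L_max
    } else NA_integer_,
    aaindex = if (config$use_aaindex) {
      if (is.null(aaindex_n)) {
        stop_input("AAindex table required when the AAindex block is enabled")
      }
      as.integer(aaindex_n)
    } else NA_integer_,
    hydropathy = if (config$use_hydropathy) 2L else NA_integer_,
    aapd = if (config$use_aapd) 1L else NA_integer_)
  dims[!is.na(dims)]
}

# lexicographic names for a k-letter alphabet cubed, e.g. "111".."777"
.triad_names <- function(letters_vec, prefix) {
  g <- expand.grid(c3 = letters_vec, c2 = letters_vec, c1 = letters_vec,
                   stringsAsFactors = FALSE)
  paste0(prefix, g$c1, g$c2, g$c3)
}

#' Conjoint-triad frequencies (343 features)
#'
#' Maps each residue to its conjoint class (see [conjoint_classes()]) and
#' counts every overlapping class triplet at positions (i, i+1, i+2). Counts
#' are divided by the number of valid triads, so with no `X` positions the
#' denominator is n - 2 and the vector sums to 1. Triads containing `X` are
#' skipped and excluded from the denominator.
#'
#' @param seq A single amino-acid sequence (character scalar).
#' @param classes Residue-to-class map; default [conjoint_classes()].
#' @return Named numeric vector of length 343 in lexicographic class order
#'   (`ct_111` ... `ct_777`).
#' @export
#' @examples
#' head(sort(conjoint_triad("ARNDC"), decreasing = TRUE), 3)
conjoint_triad <- function(seq, classes = conjoint_classes()) {
  ints <- .seq_ints(seq)
  n <- length(ints)
  if (n < 3L) stop_length(paste0("conjoint_triad needs length >= 3, got ", n))
  cls <- unname(classes[amino_acids()])[ints]  # NA at X positions
  c1 <- cls[1:(n - 2L)]; c2 <- cls[2:(n - 1L)]; c3 <- cls[3:n]
  ok <- !(is.na(c1) | is.na(c2) | is.na(c3))
  if (!any(ok)) stop_degenerate("no valid triad window (all contain X)")
  idx <- (c1[ok] - 1L) * 49L + (c2[ok] - 1L) * 7L + c3[ok]
  counts <- tabulate(idx, nbins = 343L)
  out <- counts / sum(ok)
  names(out) <- .triad_names(as.character(1:7), "ct_")
  out
}

#' Spaced-conjoint-triad frequencies
#'
#' Slides a window of width 5 along the sequence and reads the residues at
#' the first, third and fifth window positions, i.e. the spaced pattern
#' (i, i+2, i+4); in `MVICL` this yields the spaced triad `MIL`. Counts are
#' normalized by the number of valid windows, which with no `X` skips equals
#' n - 4 (the triad denominator n - 2 minus the total gap of 2). Under the
#' `"raw20"` alphabet the vector has 20^3 = 8000 entries; under `"class7"`
#' the triad is read in conjoint classes (343 entries).
#'
#' @inheritParams conjoint_triad
#' @param config An [encoder_config()]; only `sct_alphabet` is used.
#' @return Named numeric vector (8000 or 343) summing to 1 when at least
#'   one valid window exists.
#' @export
#' @examples
#' v <- spaced_conjoint_triad("MVICL")
#' v[v > 0]  # the single spaced triad MIL
spaced_conjoint_triad <- function(seq, config = encoder_config()) {
  ints <- .seq_ints(seq)
  n <- length(ints)
  if (n < 5L) {
    stop_length(paste0("spaced_conjoint_triad needs length >= 5, got ", n))
  }
  i <- 1:(n - 4L)
  a <- ints[i]; b <- ints[i + 2L]; d <- ints[i + 4L]
  if (config$sct_alphabet == "class7") {
    cls <- unname(conjoint_classes()[amino_acids()])
    a <- cls[a]; b <- cls[b]; d <- cls[d]
    k <- 7L
    nms <- .triad_names(as.character(1:7), "sct_")
  } else {
    k <- 20L
    nms <- .triad_names(amino_acids(), "sct_")
  }
  ok <- !(is.na(a) | is.na(b) | is.na(d))
  if (!any(ok)) stop_degenerate("no valid spaced window (all contain X)")
  idx <- (a[ok] - 1L) * k * k + (b[ok] - 1L) * k + d[ok]
  counts <- tabulate(idx, nbins = k^3)
  out <- counts / sum(ok)
  names(out) <- nms
  out
}

#' AAindex property means
#'
#' For each retained AAindex1 index, the mean of that index's per-residue
#' value over all non-`X` positions of the sequence, in table order.
#'
#' @inheritParams conjoint_triad
#' @param table An `aaindex_table` from [read_aaindex1()].
#' @return Named numeric vector of length `retained_count`
#'   (`aaidx_<accession>`).
#' @export
aaindex_means <- function(seq, table) {
  if (!inherits(table, "aaindex_table")) {
    stop_input("'table' must come from read_aaindex1()")
  }
  ints <- .seq_ints(seq)
  ints <- ints[!is.na(ints)]
  if (length(ints) == 0L) stop_degenerate("all-X sequence has no AAindex mean")
  freq <- tabulate(ints, nbins = 20L) / length(ints)
  vals <- as.matrix(table[, amino_acids(), drop = FALSE])
  out <- as.numeric(vals %*% freq)
  names(out) <- paste0("aaidx_", table$accession)
  out
}

#' Hydropathy means (2 features)
#'
#' Mean hydrophobicity and mean hydrophilicity of the sequence under the two
#' configured per-residue scales (defaults Kyte-Doolittle and Hopp-Woods),
#' averaging over non-`X` positions.
#'
#' @inheritParams spaced_conjoint_triad
#' @return Named numeric vector `c(hydrophobicity, hydrophilicity)`.
#' @export
#' @examples
#' hydropathy_features("IVIV")
hydropathy_features <- function(seq, config = encoder_config()) {
  ints <- .seq_ints(seq)
  ints <- ints[!is.na(ints)]
  if (length(ints) == 0L) stop_degenerate("all-X sequence has no hydropathy mean")
  c(hydrophobicity = mean(unname(config$hydrophobicity)[ints]),
    hydrophilicity = mean(unname(config$hydrophilicity)[ints]))
}

#' Amino-acid pairwise distance (1 feature)
#'
#' For every residue type, every unordered pair of its occurrences
#' contributes the absolute difference of their positions; the feature is
#' the pooled mean over all such pairs (`X` excluded). With no repeated
#' residue the pair count C is 0 and the value is 0 by convention.
#'
#' @inheritParams conjoint_triad
#' @return Named numeric vector of length 1 (`aapd`).
#' @export
#' @examples
#' aapd("AGA")   # one A-A pair at distance 2
#' aapd("AAAA")  # 10/6
aapd <- function(seq) {
  ints <- .seq_ints(seq)
  pos <- which(!is.na(ints))
  total <- 0
  C <- 0
  for (p in split(pos, ints[pos])) {
    k <- length(p)
    if (k < 2L) next
    # positions ascending: sum over i<j of (p_j - p_i) in closed form
    j <- seq_len(k)
    total <- total + sum(p * (2 * j - k - 1))
    C <- C + k * (k - 1) / 2
  }
  c(aapd = if (C == 0) 0 else total / C)
}

#' Encode one protein into its ordered feature blocks
#'
#' Runs every enabled encoder on one sequence and returns the blocks in the
#' fixed order CT, SCT, PSSM, AAindex, hydropathy, AAPD. Errors raised by a
#' block encoder are annotated with the protein id.
#'
#' @param seq A single amino-acid sequence.
#' @param config An [encoder_config()].
#' @param pssm A fitted [build_dataset_pssm()] (required when the PSSM block
#'   is enabled).
#' @param aaindex An `aaindex_table` (required when the AAindex block is
#'   enabled).
#' @param id Optional protein identifier used in error messages.
#' @return Named list of numeric feature vectors, one per enabled block.
#' @export
encode_protein <- function(seq, config = encoder_config(), pssm = NULL,
                           aaindex = NULL, id = NULL) {
  run <- function(f) {
    tryCatch(f, error = function(e) {
      if (!is.null(id) && inherits(e, "ppi_error")) {
        rlang::abort(paste0("protein '", id, "': ", conditionMessage(e)),
                     class = class(e)[1])
      }
      stop(e)
    })
  }
  blocks <- list()
  if (config$use_ct) blocks$ct <- run(conjoint_triad(seq))
  if (config$use_sct) blocks$sct <- run(spaced_conjoint_triad(seq, config))
  if (config$use_pssm) {
    if (is.null(pssm)) stop_input("PSSM block enabled but no fitted PSSM given")
    blocks$pssm <- run(pssm_features(seq, pssm, config))
  }
  if (config$use_aaindex) {
    if (is.null(aaindex)) {
      stop_input("AAindex block enabled but no AAindex table given")
    }
    blocks$aaindex <- run(aaindex_means(seq, aaindex))
  }
  if (config$use_hydropathy) {
    blocks$hydropathy <- run(hydropathy_features(seq, config))
  }
  if (config$use_aapd) blocks$aapd <- run(aapd(seq))
  blocks
}

#' Assemble a pair feature vector from two proteins' blocks
#'
#' Concatenates all blocks of protein A followed by all blocks of protein B
#' (prefixes `a_` and `b_`), giving a vector of twice the per-protein
#' dimension. Block names and per-block dimensions must agree between the
#' two lists (i.e. both must come from the same configuration).
#'
#' @param blocks_a,blocks_b Block lists from [encode_protein()].
#' @return Named numeric vector of length `2 * sum(block dims)`.
#' @export
assemble_pair_vector <- function(blocks_a, blocks_b) {
  if (!identical(names(blocks_a), names(blocks_b)) ||
      !identical(lengths(blocks_a), lengths(blocks_b))) {
    stop_dimension("protein feature blocks come from different configurations")
  }
  va <- unlist(blocks_a, use.names = TRUE)
  vb <- unlist(blocks_b, use.names = TRUE)
  stats::setNames(c(va, vb), c(paste0("a_", names(va)), paste0("b_", names(vb))))
}

# Encode a set of records into one matrix per enabled block.
# Returns list(blocks = named list of n x dim matrices, ids).
protein_feature_blocks <- function(records, config = encoder_config(),
                                   pssm = NULL, aaindex = NULL) {
  .check_records(records)
  n <- nrow(records)
  first <- encode_protein(records$seq[[1]], config, pssm, aaindex,
                          id = records$id[[1]])
  blocks <- lapply(first, function(v) {
    m <- matrix(0, nrow = n, ncol = length(v),
                dimnames = list(records$id, names(v)))
    m[1, ] <- v
    m
  })
  if (n > 1L) {
    for (i in 2:n) {
      bi <- encode_protein(records$seq[[i]], config, pssm, aaindex,
                           id = records$id[[i]])
      for (nm in names(blocks)) blocks[[nm]][i, ] <- bi[[nm]]
    }
  }
  list(blocks = blocks, ids = records$id)
}

#' Encode proteins into a feature matrix
#'
#' Data-frame-in surface over the per-protein encoders: every enabled block
#' is computed for every record and the blocks are bound column-wise in the
#' fixed order CT, SCT, PSSM, AAindex, hydropathy, AAPD.
#'
#' @param records Data frame with columns `id`, `seq` (e.g. from
#'   [read_fasta()]).
#' @inheritParams encode_protein
#' @return A numeric matrix (proteins x features) with rownames `id` and a
#'   `"schema"` attribute: a tibble of block names, dims and column offsets.
#' @export
#' @examples
#' recs <- tibble::tibble(id = c("p1", "p2"),
#'                        seq = c("MVICLAGHKW", "ARNDCEQGHI"))
#' x <- encode_proteins(recs, encoder_config(use_pssm = FALSE,
#'                                           use_aaindex = FALSE))
#' attr(x, "schema")
encode_proteins <- function(records, config = encoder_config(), pssm = NULL,
                            aaindex = NULL) {
  fb <- protein_feature_blocks(records, config, pssm, aaindex)
  dims <- vapply(fb$blocks, ncol, integer(1))
  x <- do.call(cbind, fb$blocks)
  rownames(x) <- fb$ids
  attr(x, "schema") <- tibble::tibble(
    block = names(dims), dim = as.integer(dims),
    offset = cumsum(c(0L, utils::head(as.integer(dims), -1))))
  x
}

#' Assemble the pair feature matrix for a dataset
#'
#' Builds one row per interaction pair by concatenating the feature vector
#' of protein A with that of protein B.
#'
#' @param dataset A [pair_dataset()].
#' @param features Per-protein feature matrix from [encode_proteins()]
#'   covering every id referenced by the pairs.
#' @param symmetric If `TRUE`, each pair additionally contributes the
#'   swapped (B, A) row (symmetric augmentation; labels duplicated).
#' @return A list with `x` (pairs x 2*dim matrix), `y` (integer labels) and
#'   `pairs` (the pair tibble, duplicated when `symmetric`); `x` carries the
#'   pair-level `"schema"` attribute.
#' @export
assemble_pair_features <- function(dataset, features, symmetric = FALSE) {
  if (!inherits(dataset, "pair_dataset")) {
    stop_input("'dataset' must be a pair_dataset")
  }
  missing_ids <- setdiff(unique(c(dataset$pairs$id_a, dataset$pairs$id_b)),
                         rownames(features))
  if (length(missing_ids) > 0L) {
    stop_resolution(paste0("pair id(s) missing from feature matrix: ",
                           paste(utils::head(missing_ids, 10), collapse = ", ")))
  }
  pairs <- dataset$pairs
  ia <- match(pairs$id_a, rownames(features))
  ib <- match(pairs$id_b, rownames(features))
  x <- cbind(features[ia, , drop = FALSE], features[ib, , drop = FALSE])
  colnames(x) <- c(paste0("a_", colnames(features)),
                   paste0("b_", colnames(features)))
  y <- pairs$label
  if (symmetric) {
    x2 <- cbind(features[ib, , drop = FALSE], features[ia, , drop = FALSE])
    colnames(x2) <- colnames(x)
    x <- rbind(x, x2)
    y <- c(y, y)
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      id_a = pairs$id_b, id_b = pairs$id_a, label = pairs$label))
  }
  rownames(x) <- paste(pairs$id_a, pairs$id_b, sep = "|")
  sch <- attr(features, "schema")
  if (!is.null(sch)) {
    d <- sum(sch$dim)
    attr(x, "schema") <- dplyr::bind_rows(
      dplyr::mutate(sch, side = "a"),
      dplyr::mutate(sch, side = "b", offset = .data$offset + d))
  }
  list(x = x, y = as.integer(y), pairs = pairs)
}
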