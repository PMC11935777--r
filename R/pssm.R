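# Dataset-level position-specific scoring matrix: positional residue
# log-odds against the overall residue background of the collection.

#' Fit a dataset-level position-specific scoring matrix
#'
#' Stacks all sequences of a collection by position (no alignment is
#' computed) and, for each position j <= `pssm_L_max` and residue a,
#' estimates `P(a at j) = (count_aj + alpha) / (N_j + 20 alpha)` where `N_j`
#' is the number of sequences of length >= j and `alpha` the Laplace
#' pseudocount. The background `P(a)` is the overall residue frequency under
#' the same pseudocount scheme, and the score is the natural-log odds
#' `ln(P(a at j) / P(a))`. `X` positions contribute to neither count.
#' Positions never covered by any sequence (`N_j = 0`) score 0; with
#' `alpha = 0` a zero positional count scores `pssm_floor` rather than
#' `-Inf`.
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param config An [encoder_config()]; uses `pssm_L_max`,
#'   `pssm_pseudocount` and `pssm_floor`.
#' @return An object of class `dataset_pssm`: list with `scores`
#'   (`pssm_L_max` x 20 matrix, residue columns in [amino_acids()] order),
#'   `background` (20 probabilities summing to 1), `pseudocount`, `L_max`.
#' @export
#' @examples
#' recs <- tibble::tibble(id = c("s1", "s2"), seq = c("AA", "AC"))
#' p <- build_dataset_pssm(recs, encoder_config(pssm_L_max = 2,
#'                                              pssm_pseudocount = 0))
#' p$scores["2", "A"]  # ln(0.5 / 0.75)
build_dataset_pssm <- function(records, config = encoder_config()) {
  .check_records(records)
  L <- config$pssm_L_max
  alpha <- config$pssm_pseudocount
  counts <- matrix(0, nrow = L, ncol = 20L,
                   dimnames = list(as.character(seq_len(L)), amino_acids()))
  lens <- integer(nrow(records))
  bg_counts <- numeric(20L)
  for (i in seq_len(nrow(records))) {
    ints <- .seq_ints(records$seq[[i]])
    lens[i] <- length(ints)
    keep <- which(!is.na(ints))
    bg_counts <- bg_counts + tabulate(ints[keep], nbins = 20L)
    keep <- keep[keep <= L]
    if (length(keep) > 0L) {
      idx <- cbind(keep, ints[keep])
      counts[idx] <- counts[idx] + 1
    }
  }
  n_j <- vapply(seq_len(L), function(j) sum(lens >= j), numeric(1))
  prob <- (counts + alpha) / (n_j + 20 * alpha)  # rows recycle n_j
  background <- (bg_counts + alpha) / (sum(bg_counts) + 20 * alpha)
  scores <- log(sweep(prob, 2, background, "/"))
  scores[!is.finite(scores)] <- config$pssm_floor
  scores[n_j == 0, ] <- 0
  structure(list(scores = scores,
                 background = stats::setNames(background, amino_acids()),
                 pseudocount = alpha, L_max = L),
            class = "dataset_pssm")
}

#' @export
print.dataset_pssm <- function(x, ...) {
  cat("<dataset_pssm> ", x$L_max, " positions x 20 residues, pseudocount ",
      x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' PSSM feature block for one protein
#'
#' Under `"observed_residue"` mode (default) the block has `pssm_L_max`
#' entries: entry j is the fitted score of the residue observed at position
#' j, for j up to the sequence length, and 0 beyond the sequence end or at
#' `X` positions; longer sequences are truncated at `pssm_L_max`. Under
#' `"full20"` mode all 20 positional scores are emitted per covered
#' position (`20 * pssm_L_max` entries) with the same zero padding.
#'
#' @inheritParams spaced_conjoint_triad
#' @param pssm A fitted [build_dataset_pssm()].
#' @return Named numeric vector (`pssm_p<j>` or `pssm_p<j>_<res>`).
#' @export
pssm_features <- function(seq, pssm, config = encoder_config()) {
  if (!inherits(pssm, "dataset_pssm")) {
    stop_input("'pssm' must come from build_dataset_pssm()")
  }
  L <- pssm$L_max
  ints <- .seq_ints(seq)
  n <- min(length(ints), L)
  if (config$pssm_mode == "full20") {
    out <- matrix(0, nrow = L, ncol = 20L)
    if (n > 0L) out[seq_len(n), ] <- pssm$scores[seq_len(n), ]
    v <- as.numeric(t(out))
    names(v) <- paste0("pssm_p", rep(seq_len(L), each = 20L), "_",
                       rep(amino_acids(), times = L))
    return(v)
  }
  v <- numeric(L)
  j <- seq_len(n)
  a <- ints[j]
  ok <- !is.na(a)
  v[j[ok]] <- pssm$scores[cbind(j[ok], a[ok])]
  names(v) <- paste0("pssm_p", seq_len(L))
  v
}

#' @exportS3Method ggplot2::autoplot
autoplot.dataset_pssm <- function(object, max_positions = 50, ...) {
  L <- min(object$L_max, max_positions)
  df <- tibble::tibble(
    position = rep(seq_len(L), times = 20L),
    residue = rep(amino_acids(), each = L),
    score = as.numeric(object$scores[seq_len(L), ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "Position", y = "Residue", fill = "log-odds",
                  title = "Dataset PSSM scores") +
    ggplot2::theme_minimal()
}
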