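# Independent brute-force oracles. These deliberately avoid the package's
# vectorized index arithmetic: they enumerate windows as strings and
# accumulate counts in a named table.

random_seq <- function(n, letters = amino_acids()) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# conjoint triad by direct enumeration over class strings
oracle_ct <- function(seq) {
  cls <- conjoint_classes()
  chars <- strsplit(seq, "")[[1]]
  out <- stats::setNames(numeric(343), {
    g <- expand.grid(1:7, 1:7, 1:7)
    paste0("ct_", g[, 3], g[, 2], g[, 1])
  })
  n_valid <- 0
  for (i in seq_len(nchar(seq) - 2)) {
    tri <- chars[i:(i + 2)]
    if (any(tri == "X")) next
    key <- paste0("ct_", paste(cls[tri], collapse = ""))
    out[key] <- out[key] + 1
    n_valid <- n_valid + 1
  }
  out / n_valid
}

# spaced triad by direct enumeration of (i, i+2, i+4) residue strings
oracle_sct <- function(seq, alphabet = "raw20") {
  chars <- strsplit(seq, "")[[1]]
  n <- nchar(seq)
  if (alphabet == "raw20") {
    g <- expand.grid(amino_acids(), amino_acids(), amino_acids(),
                     stringsAsFactors = FALSE)
    nms <- paste0("sct_", g[, 3], g[, 2], g[, 1])
  } else {
    g <- expand.grid(1:7, 1:7, 1:7)
    nms <- paste0("sct_", g[, 3], g[, 2], g[, 1])
  }
  out <- stats::setNames(numeric(length(nms)), nms)
  cls <- conjoint_classes()
  n_valid <- 0
  for (i in seq_len(n - 4)) {
    tri <- chars[c(i, i + 2, i + 4)]
    if (any(tri == "X")) next
    key <- if (alphabet == "raw20") {
      paste0("sct_", paste(tri, collapse = ""))
    } else {
      paste0("sct_", paste(cls[tri], collapse = ""))
    }
    out[key] <- out[key] + 1
    n_valid <- n_valid + 1
  }
  out / n_valid
}

# mean same-residue pairwise distance by explicit double loop
oracle_aapd <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  C <- 0
  for (aa in setdiff(unique(chars), "X")) {
    pos <- which(chars == aa)
    if (length(pos) < 2) next
    for (i in seq_len(length(pos) - 1)) {
      for (j in (i + 1):length(pos)) {
        total <- total + abs(pos[i] - pos[j])
        C <- C + 1
      }
    }
  }
  if (C == 0) 0 else total / C
}

# positional log-odds by direct probability computation
oracle_pssm_scores <- function(seqs, L, alpha) {
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  all_res <- setdiff(unlist(mats), "X")
  bg_n <- sum(lengths(mats)) - sum(unlist(mats) == "X")
  scores <- matrix(NA_real_, L, 20, dimnames = list(NULL, amino_acids()))
  for (a in amino_acids()) {
    p_bg <- (sum(unlist(mats) == a) + alpha) / (bg_n + 20 * alpha)
    for (j in seq_len(L)) {
      nj <- sum(lengths(mats) >= j)
      cnt <- sum(vapply(mats, function(m) length(m) >= j && m[j] == a,
                        logical(1)))
      if (nj == 0) {
        scores[j, a] <- 0
      } else {
        p <- (cnt + alpha) / (nj + 20 * alpha)
        scores[j, a] <- if (p == 0) -20 else log(p / p_bg)
      }
    }
  }
  scores
}

# the eight metrics recomputed directly from label vectors
oracle_metrics <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1); tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  list(accuracy = (tp + tn) / length(y_true), precision = prec,
       recall = rec, specificity = spec,
       f1 = div(2 * prec * rec, prec + rec),
       mcc = div(tp * tn - fp * fn,
                 sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)),
       fpr = 1 - spec, fnr = 1 - rec)
}

# tiny labelled Gaussian-cloud problem for model sanity checks
gaussian_clouds <- function(n, d = 10, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * d), n, d)
  x[y == 1, 1:3] <- x[y == 1, 1:3] + sep
  list(x = x, y = y)
}
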