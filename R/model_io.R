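# Save / load a trained classifier as a directory of plain-text files:
# one TSV per weight matrix plus a JSON metadata file (configuration,
# standardizer statistics, feature schema, training history).

#' Save a trained classifier to a directory
#'
#' @param model A trained `ppi_model`.
#' @param dir Output directory (created if absent).
#' @param force Overwrite an existing saved model.
#' @return `dir`, invisibly.
#' @export
save_ppi_model <- function(model, dir, force = FALSE) {
  if (!inherits(model, "ppi_model")) stop_input("not a trained ppi_model")
  meta_path <- file.path(dir, "model.json")
  if (file.exists(meta_path) && !force) {
    stop_input("model directory exists; use force = TRUE to overwrite")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(x, name) {
    write_feature_matrix(as.matrix(x), file.path(dir, paste0(name, ".tsv")),
                         ids = paste0("r", seq_len(nrow(as.matrix(x)))),
                         feature_names = paste0("c", seq_len(ncol(as.matrix(x)))))
  }
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    wm(ly$W, paste0("layer", l, "_W"))
    wm(rbind(ly$b, ly$gamma, ly$beta, ly$r_mean, ly$r_var),
       paste0("layer", l, "_vecs"))
  }
  wm(model$out$W, "out_W")
  wm(rbind(model$standardizer$mean, model$standardizer$sd), "standardizer")
  meta <- list(
    input_dim = model$input_dim,
    config = unclass(model$config),
    out_b = model$out$b,
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    history = model$history,
    schema = model$schema)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ppi_model
#' @export
load_ppi_model <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) {
    stop_input(paste0("no saved model at: ", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config)
  rm_ <- function(name) {
    unname(read_feature_matrix(file.path(dir, paste0(name, ".tsv"))))
  }
  layers <- lapply(seq_along(cfg$hidden_sizes), function(l) {
    vecs <- rm_(paste0("layer", l, "_vecs"))
    list(W = rm_(paste0("layer", l, "_W")),
         b = vecs[1, ], gamma = vecs[2, ], beta = vecs[3, ],
         r_mean = vecs[4, ], r_var = vecs[5, ])
  })
  stdm <- rm_("standardizer")
  std <- structure(list(mean = stdm[1, ], sd = stdm[2, ],
                        constant = stdm[2, ] <= 1e-8),
                   class = "standardizer")
  schema <- if (!is.null(meta$schema)) tibble::as_tibble(meta$schema) else NULL
  structure(list(layers = layers,
                 out = list(W = rm_("out_W"), b = meta$out_b),
                 input_dim = as.integer(meta$input_dim), config = cfg,
                 standardizer = std,
                 history = tibble::as_tibble(meta$history),
                 best_epoch = meta$best_epoch,
                 best_val_loss = meta$best_val_loss,
                 schema = schema, trained = TRUE),
            class = c("ppi_model", "ppi_mlp"))
}
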