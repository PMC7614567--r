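MODEL_FORMAT <- "orthopotts/potts_model"
MODEL_VERSION <- 1L

#' Save and load Potts models
#'
#' Models are stored as a single-file keyed container (RDS) holding the
#' format tag, version, alphabet order, all parameters, the boundary and any
#' training metadata. `load_model(save_model(m))` reproduces every parameter
#' bit-exactly.
#'
#' @param model A [potts_model()] or `potts_fit`.
#' @param path File path.
#' @param metadata Optional list stored alongside the parameters.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path, metadata = list()) {
  if (inherits(model, "potts_fit")) {
    metadata <- c(metadata, list(training = model$config))
    model <- model$model
  }
  stopifnot(inherits(model, "potts_model"))
  container <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
                    alphabet = aa_alphabet()[seq_len(model$q)],
                    L = model$L, q = model$q, boundary = model$boundary,
                    h = model$h, J = model$J, metadata = metadata)
  saveRDS(container, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  container <- tryCatch(readRDS(path), error = function(e) {
    stop("not a readable model file (", conditionMessage(e), "): ", path,
         call. = FALSE)
  })
  if (!is.list(container) || !identical(container$format, MODEL_FORMAT)) {
    stop("not an orthopotts model file: ", path, call. = FALSE)
  }
  if (!identical(container$version, MODEL_VERSION)) {
    stop("unsupported model format version ", container$version, call. = FALSE)
  }
  m <- potts_model(container$h, container$J, boundary = container$boundary,
                   q = container$q)
  attr(m, "metadata") <- container$metadata
  m
}

#' Write / read a repertoire as TSV
#'
#' Plain TSV with `#`-prefixed header comments recording the generation
#' settings; scores are dimensionless statistical energies, mutated positions
#' 1-based and protein-local.
#'
#' @param repertoire An `ois_repertoire` (or compatible tibble).
#' @param path File path.
#' @return `write_repertoire()` returns `path` invisibly;
#'   `read_repertoire()` the repertoire tibble.
#' @export
write_repertoire <- function(repertoire, path) {
  cfg <- attr(repertoire, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# orthopotts repertoire; scores are wild-type-normalized", con)
  writeLines("# statistical energies; positions are 1-based, protein-local", con)
  if (!is.null(cfg)) {
    keys <- c("mode", "k_a", "k_b", "temperature", "t2", "seed")
    for (k in intersect(keys, names(cfg))) {
      writeLines(paste0("# ", k, " = ", cfg[[k]]), con)
    }
  }
  utils::write.table(as.data.frame(repertoire), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(path) {
  tbl <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  for (col in intersect(c("positions_a", "positions_b"), names(tbl))) {
    tbl[[col]] <- as.character(tbl[[col]])
    tbl[[col]][is.na(tbl[[col]])] <- ""
  }
  new_repertoire(tibble::as_tibble(tbl))
}
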