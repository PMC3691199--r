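# Delimited-text persistence for all pipeline artifacts. Sequences travel as
# long tables (record_id, day, value) plus a separate (record_id, label)
# table; densities as (record_id, grid_day, mu, sigma); trained layers as a
# directory of weight tables plus a JSON manifest.

#' Write sequences to delimited text
#'
#' @param sequences list of [obs_sequence()]s.
#' @param path output file for the long table (`record_id`, `day`, `value`),
#'   tab-separated with a header.
#' @param labels_path optional path for the two-column label table.
#' @export
write_sequences <- function(sequences, path, labels_path = NULL) {
  tab <- do.call(rbind, lapply(sequences, function(s)
    data.frame(record_id = s$record_id, day = s$times, value = s$values)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path)) {
    lab <- data.frame(record_id = vapply(sequences, `[[`, "", "record_id"),
                      label = vapply(sequences, `[[`, "", "label"))
    utils::write.table(lab, labels_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Load sequences from delimited text
#'
#' Reads a long table with columns `record_id`, `day`, `value` (and an
#' optional separate label table), groups rows by record, sorts by time,
#' date-shifts each record so its first observation falls on day 0, perturbs
#' exact duplicate timestamps by +1e-6 day (keeping GP covariance matrices
#' well conditioned), and drops records with fewer than two observations
#' (count reported in a message and in the `"n_dropped"` attribute).
#'
#' @param path sequences file (tab- or comma-separated, with header).
#' @param labels_path optional label table path.
#' @return list of [obs_sequence()]s.
#' @export
load_sequences <- function(path, labels_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  need <- c("record_id", "day", "value")
  check_that(all(need %in% names(tab)),
             paste("sequences file must have columns", paste(need, collapse = ", ")))
  bad <- which(!is.finite(tab$day) | !is.finite(tab$value))
  if (length(bad))
    stop("malformed rows (non-finite day/value) at lines: ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  labels <- NULL
  if (!is.null(labels_path)) {
    lt <- utils::read.table(labels_path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE)
    labels <- stats::setNames(lt$label, lt$record_id)
  }
  groups <- split(tab, tab$record_id)
  n_dropped <- 0L
  out <- list()
  for (id in names(groups)) {
    g <- groups[[id]][order(groups[[id]]$day), ]
    if (nrow(g) < 2) {
      n_dropped <- n_dropped + 1L
      next
    }
    t <- g$day - g$day[1]
    # cumulative +1e-6 perturbation makes duplicate times strictly increasing
    dup <- duplicated(t)
    while (any(dup)) {
      t[dup] <- t[dup] + 1e-6
      t <- sort(t)
      dup <- duplicated(t)
    }
    lab <- if (!is.null(labels) && id %in% names(labels)) labels[[id]] else "unlabeled"
    out[[id]] <- obs_sequence(id, lab, t, g$value)
  }
  if (n_dropped > 0)
    message(n_dropped, " record(s) with < 2 observations dropped")
  out <- unname(out)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write longitudinal densities to delimited text
#'
#' @param densities list of [posterior_density()] results.
#' @param path output file (`record_id`, `grid_day`, `mu`, `sigma`).
#' @export
write_densities <- function(densities, path) {
  tab <- do.call(rbind, lapply(densities, function(d)
    data.frame(record_id = d$record_id, grid_day = d$grid_times,
               mu = d$mu, sigma = d$sigma)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read longitudinal densities written by [write_densities()]
#'
#' @param path densities file.
#' @return list of `longitudinal_density` objects (label `"unlabeled"`).
#' @export
read_densities <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  lapply(split(tab, tab$record_id), function(g) {
    g <- g[order(g$grid_day), ]
    structure(list(record_id = g$record_id[1], label = "unlabeled",
                   grid_times = g$grid_day, mu = g$mu, sigma = g$sigma),
              class = "longitudinal_density")
  })
}

#' Serialize a trained autoencoder layer to a directory
#'
#' Weight matrices and biases as tab-separated text plus a JSON manifest of
#' the layer configuration.
#'
#' @param layer an `autoencoder_layer`.
#' @param dir output directory (created if needed).
#' @export
write_layer <- function(layer, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, col.names = FALSE)
  wt(layer$W_enc, "W_enc.tsv"); wt(layer$b_enc, "b_enc.tsv")
  wt(layer$W_dec, "W_dec.tsv"); wt(layer$b_dec, "b_dec.tsv")
  jsonlite::write_json(unclass(layer$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a layer written by [write_layer()]
#'
#' @param dir layer directory.
#' @return an `autoencoder_layer`.
#' @export
read_layer <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- layer_config(cfg$n_input, cfg$n_hidden, cfg$rho, cfg$beta,
                         cfg$lambda, cfg$loss, cfg$sigma_power, cfg$tied)
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  structure(list(W_enc = unname(rd("W_enc.tsv")),
                 b_enc = drop(rd("b_enc.tsv")),
                 W_dec = unname(rd("W_dec.tsv")),
                 b_dec = drop(rd("b_dec.tsv")),
                 config = config),
            class = "autoencoder_layer")
}

#' Write a feature table to delimited text
#'
#' @param x feature matrix (rows = sequences).
#' @param record_id,label vectors aligned with rows.
#' @param path output file.
#' @export
write_feature_table <- function(x, record_id, label, path) {
  x <- as.matrix(x)
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  tab <- data.frame(record_id = record_id, label = label, x,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path feature table file.
#' @return list with `x` (matrix), `record_id`, `label`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  list(x = as.matrix(tab[, -(1:2), drop = FALSE]),
       record_id = tab$record_id, label = tab$label)
}
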