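#' @export
print.mgner <- function(x, ...) {
  ctl <- x$control
  cat("Matching-graph neural tagger (BiLSTM + BiGCN + ",
      if (ctl$use_crf) "CRF" else "softmax", ")\n", sep = "")
  cat(sprintf("  %d training sentences, vocab %d, tagset %d (%s)\n",
              x$n_train, length(x$vocab), length(x$tagset),
              paste(x$types, collapse = ", ")))
  cat(sprintf("  dictionary: %d entries; BiGCN layers T = %d%s\n",
              length(x$dictionary), ctl$layers,
              paste0(c(if (ctl$single_gcn) " [single GCN]",
                       if (ctl$no_residual) " [no residual]",
                       if (ctl$late_fusion) " [late fusion]",
                       if (ctl$no_bilstm) " [no BiLSTM]"),
                     collapse = "")))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  trained %d epoch(s); final mean loss %.4f; train F1 %s\n",
              nrow(x$log), last$loss,
              ifelse(is.na(last$train_f1), "-",
                     sprintf("%.4f", last$train_f1))))
  if (!all(is.na(x$log$dev_f1)))
    cat(sprintf("  best dev F1 %.4f at epoch %d (kept checkpoint)\n",
                max(x$log$dev_f1, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
summary.mgner <- function(object, ...) {
  structure(list(model = object,
                 n_params = sum(vapply(object$params, length, 0L)),
                 log = object$log), class = "summary.mgner")
}

#' @export
print.summary.mgner <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable scalars in %d parameter blocks\n",
              x$n_params, length(x$model$params)))
  cat("Training log (last rows):\n")
  print(utils::tail(x$log, 5L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mgner <- function(object, ...) object$params

#' Predict BIOES tags or entity spans for new sentences
#'
#' @param object a fitted [mgner()] model.
#' @param newdata a character vector of tokens (one sentence), a list of
#'   such vectors, or a [conll_document()].
#' @param type `"tags"` for BIOES tag vectors, `"spans"` for decoded
#'   entity span data frames.
#' @param dictionary dictionary to match against; defaults to the one the
#'   model was trained with.
#' @param ... unused.
#' @return A list (one element per sentence) of tag vectors or span data
#'   frames; a single sentence input returns the element directly.
#' @export
predict.mgner <- function(object, newdata, type = c("tags", "spans"),
                          dictionary = object$dictionary, ...) {
  type <- match.arg(type)
  single <- is.character(newdata)
  sents <- if (single) list(list(tokens = newdata, tags = NULL))
           else lapply(as_sentence_list(newdata), function(s)
             if (is.character(s)) list(tokens = s, tags = NULL) else s)
  ctl <- object$control
  out <- lapply(sents, function(s) {
    prep <- prepare_sentence(s$tokens, NULL, object$vocab, object$tagset,
                             dictionary, ctl, object$mask_symbols,
                             object$encoder)
    tags <- predict_sentence(object$params, prep, ctl, object$tagset)
    if (type == "spans") decode_bioes(tags) else tags
  })
  if (single) out[[1L]] else out
}

#' Plot the training curve of a fitted tagger
#'
#' Mean per-sentence loss (left axis) and train/dev entity F1 (right
#' axis scale, 0-1) against the epoch.
#'
#' @param x a fitted [mgner()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mgner <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(log$epoch, log$loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "mean sentence loss",
                 main = "training curve", ...)
  graphics::par(new = TRUE)
  graphics::plot(log$epoch, log$train_f1, type = "b", pch = 20,
                 col = "darkgreen", axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, 1))
  if (!all(is.na(log$dev_f1)))
    graphics::lines(log$epoch, log$dev_f1, type = "b", pch = 1,
                    col = "firebrick")
  graphics::axis(4)
  graphics::mtext("entity F1", side = 4, line = 2.5)
  graphics::legend("right", bty = "n",
                   legend = c("loss", "train F1",
                              if (!all(is.na(log$dev_f1))) "dev F1"),
                   col = c("black", "darkgreen",
                           if (!all(is.na(log$dev_f1))) "firebrick"),
                   lty = 1)
  invisible(x)
}

#' Save / load a fitted tagger checkpoint
#'
#' Single-file serialized parameters + control + tagset + vocabulary,
#' versioned with a format tag.
#'
#' @param model a fitted [mgner()] model.
#' @param path file path.
#' @return `load_mgner` returns the model; `save_mgner` the path,
#'   invisibly.
#' @export
save_mgner <- function(model, path) {
  stopifnot(inherits(model, "mgner"))
  obj <- unclass(model)
  obj$format <- "mgner-checkpoint-v1"
  obj$encoder <- NULL   # adapters are closures; not serialized
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_mgner
#' @export
load_mgner <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e)
                    stop("not an mgner checkpoint: ", path, call. = FALSE))
  if (!identical(obj$format, "mgner-checkpoint-v1"))
    stop("not an mgner checkpoint: ", path)
  obj$format <- NULL
  class(obj) <- "mgner"
  obj
}
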