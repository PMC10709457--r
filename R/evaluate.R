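#' Count exactly-matching entities
#'
#' A predicted entity is correct only if its start, end and type all equal
#' a gold entity's; each gold entity can be matched at most once. Counts
#' are returned pooled and per type: `c` correct, `p` predicted, `g` gold.
#'
#' @param pred,gold span data frames (see [entity_spans()]).
#' @return List with scalars `c`, `p`, `g` and a per-type data frame
#'   `by_type`.
#' @export
count_matches <- function(pred, gold) {
  key <- function(s) if (is.null(s) || nrow(s) == 0L) character() else
    paste(s$start, s$end, s$type, sep = "\r")
  kp <- key(pred); kg <- key(gold)
  correct <- kp[!is.na(match(kp, kg))]
  # each gold matched at most once: count min multiplicity per key
  ck <- table(kp)[intersect(unique(kp), unique(kg))]
  gk <- table(kg)[names(ck)]
  n_correct <- if (length(ck)) sum(pmin(as.integer(ck), as.integer(gk)))
               else 0L
  types <- sort(unique(c(if (length(kp)) pred$type, if (length(kg)) gold$type)))
  by_type <- do.call(rbind, lapply(types, function(t) {
    kpt <- kp[pred$type == t]; kgt <- kg[gold$type == t]
    ckt <- table(kpt)[intersect(unique(kpt), unique(kgt))]
    gkt <- table(kgt)[names(ckt)]
    data.frame(type = t,
               c = if (length(ckt)) sum(pmin(as.integer(ckt),
                                             as.integer(gkt))) else 0L,
               p = length(kpt), g = length(kgt),
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_type))
    by_type <- data.frame(type = character(), c = integer(),
                          p = integer(), g = integer())
  list(c = n_correct, p = length(kp), g = length(kg), by_type = by_type)
}

#' Precision, recall and F1 from pooled counts
#'
#' `P = sum(c) / sum(p)`, `R = sum(c) / sum(g)`, `F1 = 2PR / (P + R)`,
#' with counts pooled over all evaluated samples. A zero denominator gives
#' a score of 0 (and F1 = 0 when P + R = 0).
#'
#' @param c,p,g correct / predicted / gold entity counts.
#' @return Named numeric vector `precision`, `recall`, `f1`, each in
#'   `[0, 1]`.
#' @export
prf <- function(c, p, g) {
  P <- if (p > 0) c / p else 0
  R <- if (g > 0) c / g else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = F1)
}

#' Score predicted entities against gold over a corpus
#'
#' Inputs are parallel lists of span data frames (one per sentence), or
#' parallel lists of BIOES tag sequences which are decoded first. The
#' headline scores pool counts over all sentences and entity types (the
#' literal count-ratio formulas); a per-type table and the unweighted
#' cross-type macro average are reported alongside, clearly labeled.
#'
#' @param pred,gold lists of span data frames, or lists of character tag
#'   vectors.
#' @return Object of class `ner_eval`: pooled scores, per-type table,
#'   macro average, raw counts.
#' @export
evaluate_ner <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  as_spans <- function(x) if (is.character(x)) decode_bioes(x) else x
  tot <- list(c = 0L, p = 0L, g = 0L)
  type_tab <- new.env(parent = emptyenv())
  for (i in seq_along(pred)) {
    cm <- count_matches(as_spans(pred[[i]]), as_spans(gold[[i]]))
    tot$c <- tot$c + cm$c; tot$p <- tot$p + cm$p; tot$g <- tot$g + cm$g
    for (k in seq_len(nrow(cm$by_type))) {
      t <- cm$by_type$type[k]
      cur <- type_tab[[t]]
      if (is.null(cur)) cur <- c(0L, 0L, 0L)
      type_tab[[t]] <- cur + c(cm$by_type$c[k], cm$by_type$p[k],
                               cm$by_type$g[k])
    }
  }
  types <- sort(ls(type_tab))
  per_type <- do.call(rbind, lapply(types, function(t) {
    v <- type_tab[[t]]
    s <- prf(v[1L], v[2L], v[3L])
    data.frame(type = t, c = v[1L], p = v[2L], g = v[3L],
               precision = s["precision"], recall = s["recall"],
               f1 = s["f1"], row.names = NULL, stringsAsFactors = FALSE)
  }))
  pooled <- prf(tot$c, tot$p, tot$g)
  macro <- if (!is.null(per_type) && nrow(per_type) > 0L)
    c(precision = mean(per_type$precision), recall = mean(per_type$recall),
      f1 = mean(per_type$f1))
  else c(precision = 0, recall = 0, f1 = 0)
  structure(list(pooled = pooled, per_type = per_type, macro = macro,
                 counts = tot), class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, digits = 4, ...) {
  cat("Exact-match entity scores (pooled counts)\n")
  cat(sprintf("  P = %.*f  R = %.*f  F1 = %.*f   (c=%d p=%d g=%d)\n",
              digits, x$pooled["precision"], digits, x$pooled["recall"],
              digits, x$pooled["f1"], x$counts$c, x$counts$p, x$counts$g))
  if (!is.null(x$per_type) && nrow(x$per_type) > 0L) {
    cat("Per type:\n")
    print(x$per_type, digits = digits, row.names = FALSE)
    cat(sprintf("Macro average over types: P = %.*f  R = %.*f  F1 = %.*f\n",
                digits, x$macro["precision"], digits, x$macro["recall"],
                digits, x$macro["f1"]))
  }
  invisible(x)
}

# key/value lines for machine consumption
eval_report_lines <- function(x) {
  lines <- c(sprintf("pooled.precision\t%.6f", x$pooled["precision"]),
             sprintf("pooled.recall\t%.6f", x$pooled["recall"]),
             sprintf("pooled.f1\t%.6f", x$pooled["f1"]))
  if (!is.null(x$per_type) && nrow(x$per_type) > 0L) {
    for (k in seq_len(nrow(x$per_type)))
      lines <- c(lines, sprintf("%s.precision\t%.6f\n%s.recall\t%.6f\n%s.f1\t%.6f",
                                x$per_type$type[k], x$per_type$precision[k],
                                x$per_type$type[k], x$per_type$recall[k],
                                x$per_type$type[k], x$per_type$f1[k]))
    lines <- c(lines, sprintf("macro.f1\t%.6f", x$macro["f1"]))
  }
  lines
}
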