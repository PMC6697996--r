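# Scoring of predictions: tag-level macro-averaged precision/recall/F1
# (the primary metric) and exact-span entity-level scoring, plus span
# extraction and a comparison-table formatter.

#' Tag-level macro-averaged precision, recall and F1
#'
#' A predicted tag counts as correct only if it equals the ground-truth
#' tag.  Per-label precision, recall and F1 are computed over the non-O
#' labels; the macro average is the unweighted mean over labels that occur
#' in the gold standard.  A label with no predictions gets precision 0; a
#' label absent from gold is excluded from the macro mean.  All scores are
#' on the percent scale (0-100).
#'
#' @param pred,gold lists of character tag vectors (aligned, equal
#'   lengths), or single vectors.
#' @param scheme a [tag_scheme()].
#' @return object of class `metrics_report`: `per_label` data.frame
#'   (label, tp, fp, fn, precision, recall, f1), `macro` named vector,
#'   `level = "tag"`.
#' @export
tag_metrics <- function(pred, gold, scheme) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(gold)) gold <- list(gold)
  if (length(pred) != length(gold)) stop("pred/gold sentence counts differ")
  pl <- vapply(pred, length, integer(1)); gl <- vapply(gold, length, integer(1))
  if (any(pl != gl)) stop("pred/gold length mismatch in sentence(s) ",
                          paste(which(pl != gl), collapse = ", "))
  p <- unlist(pred, use.names = FALSE)
  g <- unlist(gold, use.names = FALSE)
  labels <- setdiff(scheme$labels, "O")
  per <- lapply(labels, function(lb) {
    tp <- sum(p == lb & g == lb)
    fp <- sum(p == lb & g != lb)
    fn <- sum(p != lb & g == lb)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(label = lb, tp = tp, fp = fp, fn = fn,
               precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
               in_gold = (tp + fn) > 0, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  macro_rows <- per[per$in_gold, , drop = FALSE]
  macro <- if (nrow(macro_rows))
    c(precision = mean(macro_rows$precision),
      recall = mean(macro_rows$recall), f1 = mean(macro_rows$f1))
  else c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  structure(list(per_label = per, macro = macro, level = "tag"),
            class = "metrics_report")
}

#' Extract entity spans from an IOB tag sequence
#'
#' Returns maximal same-type runs as half-open 0-based `[start, end)`
#' token spans with their category.  Illegal `I-` openings (an `I-` tag
#' with no compatible predecessor) are repaired as `B-` for extraction
#' only ("I-as-B"); the raw tags are never modified.
#'
#' @param tags character tag vector.
#' @param scheme a [tag_scheme()].
#' @return data.frame with columns `start`, `end`, `category`, `type`.
#' @export
extract_entities <- function(tags, scheme) {
  n <- length(tags)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  cur_type <- NULL; cur_start <- NA_integer_
  close_span <- function(i) {
    if (!is.null(cur_type)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, i)
      types <<- c(types, cur_type)
    }
    cur_type <<- NULL
  }
  for (i in seq_len(n)) {
    tg <- tags[i]
    if (tg == "O" || !grepl("^[BI]-", tg)) { close_span(i - 1L); next }
    typ <- sub("^[BI]-", "", tg)
    if (grepl("^B-", tg)) {
      close_span(i - 1L)
      cur_type <- typ; cur_start <- i - 1L   # 0-based
    } else {  # I-
      if (!is.null(cur_type) && cur_type == typ) {
        # continues current span
      } else {
        close_span(i - 1L)                    # I-as-B repair
        cur_type <- typ; cur_start <- i - 1L
      }
    }
  }
  close_span(n)
  cats <- unname(scheme$categories[types])
  cats[is.na(cats)] <- types[is.na(cats)]
  data.frame(start = starts, end = ends, category = cats,
             type = types, stringsAsFactors = FALSE)
}

#' Entity-level (exact span) precision, recall and F1
#'
#' An entity counts as correct only when its span boundaries and its
#' category both match a gold entity.  Scores are per category with the
#' same macro-averaging and undefined-value conventions as
#' [tag_metrics()].
#'
#' @inheritParams tag_metrics
#' @return `metrics_report` with `level = "entity"` and per-category rows.
#' @export
entity_metrics <- function(pred, gold, scheme) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(gold)) gold <- list(gold)
  if (length(pred) != length(gold)) stop("pred/gold sentence counts differ")
  key <- function(sid, sp) if (!nrow(sp)) character(0) else
    paste(sid, sp$start, sp$end, sp$category, sep = ":")
  cat_of <- function(k) vapply(strsplit(k, ":", fixed = TRUE),
                               function(x) x[4], character(1))
  pk <- character(0); gk <- character(0)
  for (i in seq_along(pred)) {
    pk <- c(pk, key(i, extract_entities(pred[[i]], scheme)))
    gk <- c(gk, key(i, extract_entities(gold[[i]], scheme)))
  }
  cats <- sort(unique(unname(scheme$categories)))
  per <- lapply(cats, function(cc) {
    pc <- pk[cat_of(pk) == cc]; gc_ <- gk[cat_of(gk) == cc]
    tp <- length(intersect(pc, gc_))
    fp <- length(setdiff(pc, gc_)); fn <- length(setdiff(gc_, pc))
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(label = cc, tp = tp, fp = fp, fn = fn,
               precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
               in_gold = length(gc_) > 0, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  macro_rows <- per[per$in_gold, , drop = FALSE]
  macro <- if (nrow(macro_rows))
    c(precision = mean(macro_rows$precision),
      recall = mean(macro_rows$recall), f1 = mean(macro_rows$f1))
  else c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  structure(list(per_label = per, macro = macro, level = "entity"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> level=", x$level, "\n", sep = "")
  df <- x$per_label
  df$precision <- sprintf("%.2f", df$precision)
  df$recall <- sprintf("%.2f", df$recall)
  df$f1 <- sprintf("%.2f", df$f1)
  print(df[, c("label", "tp", "fp", "fn", "precision", "recall", "f1")],
        row.names = FALSE)
  cat(sprintf("macro: P=%.2f R=%.2f F1=%.2f\n", x$macro["precision"],
              x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' Format a comparison table of metric reports
#'
#' One row per report, percent values with two decimals, deterministic
#' column order, best F1 flagged.
#'
#' @param reports named list of `metrics_report` objects (names become row
#'   labels, e.g. architecture names).
#' @return data.frame with columns `name`, `precision`, `recall`, `f1`,
#'   `best` (logical flag on the best F1).
#' @export
report_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  nms <- names(reports) %||% paste0("model", seq_along(reports))
  f1s <- vapply(reports, function(r) unname(r$macro["f1"]), numeric(1))
  data.frame(name = nms,
             precision = sprintf("%.2f", vapply(reports, function(r)
               unname(r$macro["precision"]), numeric(1))),
             recall = sprintf("%.2f", vapply(reports, function(r)
               unname(r$macro["recall"]), numeric(1))),
             f1 = sprintf("%.2f", f1s),
             best = f1s == max(f1s),
             stringsAsFactors = FALSE)
}
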