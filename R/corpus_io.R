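# Reading, validating, subsampling and summarizing IOB-tagged corpora.

DEFAULT_CATEGORY_MAP <- c(
  GENE = "Gene", DNA = "Gene", RNA = "Gene",
  PROTEIN = "Protein", GGP = "Protein", PROT = "Protein",
  DISEASE = "Disease", DISO = "Disease",
  CHEMICAL = "Chemical", CHEM = "Chemical", SIMPLE_CHEMICAL = "Chemical",
  SPECIES = "Species", ORGANISM = "Species",
  CELL = "Cell", CELL_LINE = "Cell", CELL_TYPE = "Cell"
)

#' Create a tag scheme
#'
#' A tag scheme fixes the legal tag inventory of a corpus, the IOB variant
#' used to interpret it, and a mapping from each entity type suffix to one
#' of the six biomedical entity categories (Cell, Chemical, Disease, Gene,
#' Protein, Species).
#'
#' @param labels character vector of tag strings, e.g. `c("O", "B-GENE",
#'   "I-GENE")`.  Every non-O label must have a `B-` or `I-` prefix.
#' @param variant `"IOB2"` (default; every entity starts with `B-`) or
#'   `"IOB1"` (`I-` may open an entity; `B-` only separates adjacent
#'   entities of the same type).
#' @param categories optional named character vector mapping type suffixes
#'   (e.g. `"GENE"`) to category names.  Unmapped suffixes fall back to a
#'   built-in table of common BioNER type names, then to the suffix itself.
#' @return an object of class `tag_scheme`.
#' @export
tag_scheme <- function(labels, variant = c("IOB2", "IOB1"), categories = NULL) {
  variant <- match.arg(variant)
  labels <- unique(as.character(labels))
  bad <- labels[labels != "O" & !grepl("^[BI]-.+", labels)]
  if (length(bad))
    stop("labels without B-/I- prefix and type suffix: ",
         paste(bad, collapse = ", "))
  suffixes <- unique(sub("^[BI]-", "", labels[labels != "O"]))
  cat_map <- vapply(suffixes, function(s) {
    if (!is.null(categories) && s %in% names(categories)) categories[[s]]
    else if (toupper(s) %in% names(DEFAULT_CATEGORY_MAP))
      DEFAULT_CATEGORY_MAP[[toupper(s)]]
    else s
  }, character(1))
  structure(list(variant = variant, labels = labels,
                 categories = cat_map), class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("<tag_scheme> ", x$variant, ": ", paste(x$labels, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

tagged_sentence <- function(tokens, tags) {
  stopifnot(length(tokens) == length(tags), length(tokens) >= 1L)
  list(tokens = as.character(tokens), tags = as.character(tags))
}

#' Assemble a tagged corpus
#'
#' @param name corpus name.
#' @param dataset_id `"D1"` or `"D2"`: which slot of a two-dataset
#'   multi-task pair this corpus occupies.
#' @param train,dev,test lists of sentences as returned by [read_conll()].
#' @param scheme the [tag_scheme()] all splits conform to.
#' @return an object of class `tagged_corpus` with `$splits$train`,
#'   `$splits$dev`, `$splits$test`.
#' @export
tagged_corpus <- function(name, dataset_id = c("D1", "D2"),
                          train = list(), dev = list(), test = list(),
                          scheme) {
  dataset_id <- match.arg(dataset_id)
  structure(list(name = name, dataset_id = dataset_id,
                 splits = list(train = train, dev = dev, test = test),
                 scheme = scheme),
            class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  ns <- vapply(x$splits, length, integer(1))
  cat("<tagged_corpus> ", x$name, " (", x$dataset_id, "): ",
      paste(names(ns), ns, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a CoNLL-style IOB file
#'
#' Parses token-per-line text where each non-blank line holds a surface
#' token and its tag separated by whitespace, and a blank line terminates a
#' sentence.  Tags are preserved verbatim.
#'
#' @param path file path.
#' @param scheme a [tag_scheme()]; every tag in the file must be in
#'   `scheme$labels`.
#' @return list of sentences, each `list(tokens=, tags=)`.
#' @export
read_conll <- function(path, scheme) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(0); tags <- character(0)
  flush <- function() {
    if (length(toks)) sentences[[length(sentences) + 1L]] <<-
        tagged_sentence(toks, tags)
    toks <<- character(0); tags <<- character(0)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(fields) != 2L)
      stop("parse error at line ", i, ": expected 'token tag', got ",
           length(fields), " field(s)")
    if (!fields[2] %in% scheme$labels)
      stop("validation error at line ", i, ": tag '", fields[2],
           "' not in scheme")
    toks <- c(toks, fields[1]); tags <- c(tags, fields[2])
  }
  flush()
  sentences
}

#' Write sentences in CoNLL format
#'
#' One `token<TAB>tag` line per token, one blank line after each sentence.
#' `read_conll()` followed by `write_conll()` round-trips such files
#' byte-identically.
#'
#' @param sentences list of sentences.
#' @param path output file path.
#' @export
write_conll <- function(sentences, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in sentences) {
    writeLines(paste(s$tokens, s$tags, sep = "\t"), con, sep = "\n")
    writeLines("", con, sep = "\n")
  }
  invisible(path)
}

#' Check a tag sequence against the IOB rules of a scheme
#'
#' Violations are data, not errors: downstream training accepts corpora
#' with mixed conventions, so validation is advisory.
#'
#' @param sentence a sentence (`list(tokens=, tags=)`).
#' @param scheme a [tag_scheme()].
#' @return data.frame with columns `position`, `reason`; zero rows when the
#'   sequence is legal under `scheme$variant`.
#' @export
validate_tags <- function(sentence, scheme) {
  tags <- sentence$tags
  pos <- integer(0); reason <- character(0)
  add <- function(p, r) { pos <<- c(pos, p); reason <<- c(reason, r) }
  prev <- "O"
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (!tg %in% scheme$labels) { add(i, paste0("tag '", tg, "' not in scheme")); prev <- tg; next }
    if (grepl("^I-", tg)) {
      typ <- sub("^I-", "", tg)
      prev_typ <- if (grepl("^[BI]-", prev)) sub("^[BI]-", "", prev) else NA
      cont <- !is.na(prev_typ) && prev_typ == typ
      if (!cont) {
        if (scheme$variant == "IOB2")
          add(i, if (is.na(prev_typ))
            "I- without preceding B- of same type"
            else "type switch inside entity")
        # IOB1 permits I- openings after O / start; a type switch is still
        # illegal mid-entity
        else if (!is.na(prev_typ))
          add(i, "type switch inside entity")
      }
    }
    prev <- tg
  }
  data.frame(position = pos, reason = reason, stringsAsFactors = FALSE)
}

#' Randomly subsample the training split of a corpus
#'
#' Reduced-size experiments remove training sentences at random; the
#' development and test splits are never modified.  The reduced size is
#' `round(fraction * n)` with round-half-up, so a 10% run over an odd count
#' is reproducible across platforms.
#'
#' @param corpus a [tagged_corpus()].
#' @param fraction proportion in (0, 1] of training sentences to keep.
#' @param seed integer seed making the selection reproducible.
#' @return the corpus with its train split reduced.
#' @export
subsample_corpus <- function(corpus, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- length(corpus$splits$train)
  keep <- floor(fraction * n + 0.5)  # round half up
  if (keep == n) return(corpus)
  idx <- with_local_seed(seed, sort(sample.int(n, keep)))
  corpus$splits$train <- corpus$splits$train[idx]
  corpus
}

#' Build word, character and per-dataset tag indices
#'
#' Index values start at 1 (R convention) and are contiguous; `PAD` is
#' index 1 and `UNK` index 2 in both the word and the character index.
#' Tag inventories are kept separate per dataset: tags are never renamed
#' or merged across corpora.
#'
#' @param corpora list of [tagged_corpus()] objects (at least one).
#' @param pretrained_words optional character vector of additional words to
#'   include (e.g. the keys of a pretrained embedding file).
#' @return an object of class `vocabulary` with `word_index`, `char_index`
#'   and `tag_index` (a named list, one integer vector per dataset name).
#' @export
build_vocab <- function(corpora, pretrained_words = NULL) {
  if (length(corpora) == 0L) stop("need at least one corpus")
  words <- character(0); chars <- character(0)
  tag_index <- list()
  for (corpus in corpora) {
    surf <- unlist(lapply(corpus$splits$train, `[[`, "tokens"),
                   use.names = FALSE)
    words <- c(words, surf)
    chars <- c(chars, unlist(strsplit(unique(surf), ""), use.names = FALSE))
    tags <- corpus$scheme$labels
    tag_index[[corpus$name]] <- stats::setNames(seq_along(tags), tags)
  }
  if (!is.null(pretrained_words)) words <- c(words, pretrained_words)
  words <- unique(words)
  chars <- unique(chars)
  word_index <- stats::setNames(seq_len(length(words) + 2L),
                                c("<PAD>", "<UNK>", words))
  char_index <- stats::setNames(seq_len(length(chars) + 2L),
                                c("<PAD>", "<UNK>", chars))
  structure(list(word_index = word_index, char_index = char_index,
                 tag_index = tag_index),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> words=", length(x$word_index),
      " chars=", length(x$char_index),
      " tagsets={", paste(names(x$tag_index),
                          vapply(x$tag_index, length, integer(1)),
                          sep = ":", collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Word lookup with lowercase fallback before UNK (pretrained vectors are
# typically lowercase-keyed; surfaces are stored verbatim).
lookup_words <- function(words, word_index) {
  idx <- unname(word_index[words])
  miss <- is.na(idx)
  if (any(miss)) {
    idx[miss] <- unname(word_index[tolower(words[miss])])
    idx[is.na(idx)] <- word_index[["<UNK>"]]
  }
  as.integer(idx)
}

lookup_chars <- function(word, char_index) {
  cs <- strsplit(word, "")[[1]]
  idx <- unname(char_index[cs])
  idx[is.na(idx)] <- char_index[["<UNK>"]]
  as.integer(idx)
}

#' Summarize a corpus: sentence counts and entity counts per category
#'
#' An entity is a maximal `B...I` run of one type; counts are reported per
#' category and per split, since distributed corpora differ in whether
#' published totals include all splits.
#'
#' @param corpus a [tagged_corpus()].
#' @return data.frame with columns `split`, `sentences`, then one column
#'   per entity category.
#' @export
corpus_stats <- function(corpus) {
  cats <- sort(unique(unname(corpus$scheme$categories)))
  rows <- lapply(names(corpus$splits), function(sp) {
    sents <- corpus$splits[[sp]]
    counts <- stats::setNames(rep(0L, length(cats)), cats)
    for (s in sents) {
      spans <- extract_entities(s$tags, corpus$scheme)
      if (nrow(spans))
        for (cc in spans$category) counts[[cc]] <- counts[[cc]] + 1L
    }
    cbind(data.frame(split = sp, sentences = length(sents),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE))
  })
  do.call(rbind, rows)
}
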