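# Synthetic IOB corpus pairs with controllable lexical overlap and
# category composition.  The generator targets the statistical structure
# of biomedical NER corpus pairs (single-category main dataset,
# multi-category auxiliary, partially shared entity lexicons,
# category-specific surface morphology) rather than fluent language, so
# every architecture and the turn-based training loop are testable without
# downloads.

# filler vocabulary for entity contexts (shared across both datasets)
SYN_FILLERS <- c(
  "the", "a", "of", "in", "with", "by", "was", "were", "is", "are",
  "expression", "levels", "activity", "binding", "observed", "measured",
  "increased", "decreased", "induced", "inhibited", "treatment",
  "patients", "samples", "analysis", "results", "showed", "study",
  "cells", "tissue", "role", "effect", "response", "pathway", "during",
  "after", "significant", "associated", "expression", "regulation", "and")

# single-slot context templates; "<ENT>" marks the entity slot
SYN_TEMPLATES <- c(
  "the <ENT> was observed in samples",
  "expression of <ENT> increased after treatment",
  "analysis showed <ENT> activity in cells",
  "<ENT> levels were measured in patients",
  "treatment with <ENT> induced a response",
  "binding of <ENT> was significant",
  "the role of <ENT> in regulation",
  "results associated <ENT> with the pathway",
  "<ENT> expression decreased during the study",
  "the effect of <ENT> on tissue was showed")

SYN_FILLER_TEMPLATE <- "the results of the analysis were significant"

#' Specification of a synthetic corpus pair
#'
#' Defines the shapes of the main and auxiliary corpora: split sizes,
#' entity categories with lexicon sizes, entity density (a Poisson mean
#' for entities per sentence), the sentence-length range used for filler
#' padding, the cross-dataset lexicon overlap fraction `rho` applied per
#' shared category, and the seed.  Tag names deliberately differ between
#' the datasets for shared categories (e.g. `B-GENE` in the main corpus,
#' `B-DNA` in the auxiliary), since real corpus pairs keep their native
#' tag inventories.
#'
#' @param main,aux per-dataset settings: lists with `n_train`, `n_dev`,
#'   `n_test`, and `categories` (named integer vector: category ->
#'   lexicon size).
#' @param rho lexicon overlap fraction in `[0, 1]`: for each category
#'   present in both datasets, the auxiliary lexicon shares exactly
#'   `round(rho * size)` surfaces with the main lexicon.
#' @param density Poisson mean of entities per sentence.
#' @param len_range sentence length range targeted by filler padding.
#' @param templates character vector of single-slot context templates
#'   (each must contain `"<ENT>"` when `density > 0`).
#' @param seed mandatory integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(main = list(n_train = 2000L, n_dev = 500L,
                                       n_test = 500L,
                                       categories = c(Gene = 300L)),
                           aux = list(n_train = 2000L, n_dev = 250L,
                                      n_test = 250L,
                                      categories = c(Gene = 300L,
                                                     Chemical = 150L)),
                           rho = 0.8, density = 1.5,
                           len_range = c(6L, 14L),
                           templates = SYN_TEMPLATES, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  for (ds in list(main, aux)) {
    stopifnot(ds$n_train >= 1, ds$n_dev >= 1, ds$n_test >= 1,
              all(ds$categories >= 1))
  }
  if (density > 0 && !any(grepl("<ENT>", templates, fixed = TRUE)))
    stop("spec error: density > 0 but no template has an <ENT> slot")
  structure(list(main = main, aux = aux, rho = rho, density = density,
                 len_range = len_range, templates = templates,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# category-specific morphology so the character CNN has signal
syn_surface <- function(category, k) {
  syll <- c("ba", "ce", "di", "fo", "gu", "ka", "lo", "mi", "ne", "po",
            "ra", "su", "ti", "vu", "za")
  stem <- paste0(sample(syll, 2L, replace = TRUE), collapse = "")
  switch(category,
    Gene = paste0(stem, sample(LETTERS, 1), sample(0:9, 1), sample(0:9, 1)),
    Protein = paste0(stem, sample(c("ase", "in", "gen"), 1)),
    Chemical = paste0(stem, sample(c("ol", "ine", "ate", "ide"), 1)),
    Disease = paste0(stem, sample(c("itis", "oma", "osis"), 1)),
    Species = paste0(toupper(substr(stem, 1, 1)), ". ", stem,
                     sample(c("us", "a", "ii"), 1)),
    Cell = paste0(stem, sample(c("cyte", "blast"), 1)),
    paste0(stem, k))
}

# one entity surface: 1-3 tokens so B/I transitions are exercised
syn_entity <- function(category) {
  ntok <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
  base <- syn_surface(category, sample(1e6, 1))
  toks <- strsplit(base, " ", fixed = TRUE)[[1]]
  extra <- c("alpha", "beta", "type", "factor", "ii")
  while (length(toks) < ntok) toks <- c(toks, sample(extra, 1))
  toks[seq_len(max(ntok, length(toks)))]
}

#' Generate per-category entity lexicons for both datasets
#'
#' The auxiliary lexicon of a category present in both datasets shares
#' exactly `round(rho * size)` surfaces with the main lexicon (the
#' remainder is fresh); categories private to one dataset get fully fresh
#' lexicons.
#'
#' @param spec a [synthetic_spec()].
#' @param seed seed (defaults to `spec$seed`).
#' @return list with `main` and `aux`, each a named list mapping category
#'   to a list of token vectors (one per entity surface).
#' @export
generate_lexicons <- function(spec, seed = spec$seed) {
  with_local_seed(seed, {
    draw <- function(category, n) {
      out <- list(); seen <- character(0)
      while (length(out) < n) {
        e <- syn_entity(category)
        k <- paste(e, collapse = " ")
        if (!k %in% seen) { seen <- c(seen, k); out[[length(out) + 1L]] <- e }
      }
      out
    }
    main_lex <- lapply(names(spec$main$categories), function(cc)
      draw(cc, spec$main$categories[[cc]]))
    names(main_lex) <- names(spec$main$categories)
    aux_lex <- lapply(names(spec$aux$categories), function(cc) {
      n <- spec$aux$categories[[cc]]
      if (cc %in% names(main_lex)) {
        n_shared <- round(spec$rho * n)
        n_shared <- min(n_shared, length(main_lex[[cc]]))
        shared <- main_lex[[cc]][seq_len(n_shared)]
        c(shared, draw(cc, n - n_shared))
      } else draw(cc, n)
    })
    names(aux_lex) <- names(spec$aux$categories)
    list(main = main_lex, aux = aux_lex)
  })
}

# default tag naming: shared categories get different tag names per dataset
syn_tag_names <- function(category, dataset) {
  tbl <- list(
    Gene = c("GENE", "DNA"), Protein = c("PROTEIN", "GGP"),
    Chemical = c("CHEMICAL", "CHEM"), Disease = c("DISEASE", "DISO"),
    Species = c("SPECIES", "ORGANISM"), Cell = c("CELL", "CELL_TYPE"))
  nm <- tbl[[category]] %||% c(toupper(category), toupper(category))
  nm[dataset]
}

# build one dataset's sentences
syn_sentences <- function(n, categories, lexicons, dataset_index, spec) {
  templates <- spec$templates
  slot_templates <- templates[grepl("<ENT>", templates, fixed = TRUE)]
  cat_names <- names(categories)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    k <- stats::rpois(1, spec$density)
    toks <- character(0); tags <- character(0)
    if (k == 0) {
      seg <- strsplit(SYN_FILLER_TEMPLATE, " ", fixed = TRUE)[[1]]
      toks <- seg; tags <- rep("O", length(seg))
    } else for (j in seq_len(k)) {
      tpl <- sample(slot_templates, 1)
      seg <- strsplit(tpl, " ", fixed = TRUE)[[1]]
      cc <- if (length(cat_names) == 1L) cat_names else sample(cat_names, 1)
      ent <- lexicons[[cc]][[sample(length(lexicons[[cc]]), 1)]]
      tagn <- syn_tag_names(cc, dataset_index)
      pos <- which(seg == "<ENT>")
      pre <- if (pos > 1) seg[seq_len(pos - 1L)] else character(0)
      post <- if (pos < length(seg)) seg[(pos + 1L):length(seg)] else character(0)
      toks <- c(toks, pre, ent, post)
      tags <- c(tags, rep("O", length(pre)),
                paste0("B-", tagn),
                if (length(ent) > 1) rep(paste0("I-", tagn),
                                         length(ent) - 1L),
                rep("O", length(post)))
    }
    # filler padding toward the target length range
    want <- sample(spec$len_range[1]:spec$len_range[2], 1)
    while (length(toks) < want) {
      f <- sample(SYN_FILLERS, 1)
      toks <- c(toks, f); tags <- c(tags, "O")
    }
    out[[s]] <- tagged_sentence(toks, tags)
  }
  out
}

#' Generate a (main, auxiliary) pair of tagged corpora
#'
#' Sentences are built from single-slot context templates with entity
#' slots filled from the generated lexicons; the number of entities per
#' sentence is Poisson with mean `spec$density` (a sentence concatenates
#' that many slotted segments); filler tokens pad toward the length
#' range.  Tags are emitted in IOB2.  Fully reproducible from
#' `(spec, spec$seed)`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `main` and `aux` [tagged_corpus()] objects and
#'   `lexicons`.
#' @export
generate_corpus_pair <- function(spec) {
  lex <- generate_lexicons(spec)
  build <- function(ds, lexicons, dataset_index, name, id, seed) {
    cats <- ds$categories
    tag_names <- vapply(names(cats), syn_tag_names, character(1),
                        dataset = dataset_index)
    labels <- c("O", as.vector(rbind(paste0("B-", tag_names),
                                     paste0("I-", tag_names))))
    cat_map <- stats::setNames(names(cats), tag_names)
    scheme <- tag_scheme(labels, variant = "IOB2", categories = cat_map)
    n_tot <- ds$n_train + ds$n_dev + ds$n_test
    sents <- with_local_seed(seed,
      syn_sentences(n_tot, cats, lexicons, dataset_index, spec))
    tagged_corpus(name, id,
                  train = sents[seq_len(ds$n_train)],
                  dev = sents[ds$n_train + seq_len(ds$n_dev)],
                  test = sents[ds$n_train + ds$n_dev + seq_len(ds$n_test)],
                  scheme = scheme)
  }
  list(main = build(spec$main, lex$main, 1L, "synthetic-main", "D1",
                    spec$seed + 101L),
       aux = build(spec$aux, lex$aux, 2L, "synthetic-aux", "D2",
                   spec$seed + 202L),
       lexicons = lex)
}

#' Generate synthetic word vectors with category structure
#'
#' Draws a vector for every entity token around a per-category centroid
#' (`signal` scales the centroid, i.e. the cluster separation) plus unit
#' isotropic noise, and vectors for filler tokens around the origin.  With
#' `signal = 0` all vectors are exchangeable.  Reproducible under the
#' seed.
#'
#' @param lexicons the `lexicons` element of [generate_corpus_pair()]
#'   output (or any list of per-category token-vector lists).
#' @param dim embedding dimension (>= 2).
#' @param seed integer seed.
#' @param signal non-negative category-cluster strength.
#' @return named list word -> numeric vector, usable as the `pretrained`
#'   argument of [build_model()]/[train()].
#' @export
generate_embeddings <- function(lexicons, dim, seed, signal = 2) {
  stopifnot(dim >= 2, signal >= 0)
  with_local_seed(seed, {
    cats <- sort(unique(unlist(lapply(lexicons, names))))
    centroids <- lapply(cats, function(cc) stats::rnorm(dim))
    names(centroids) <- cats
    out <- list()
    for (side in lexicons) for (cc in names(side)) {
      for (ent in side[[cc]]) for (tok in ent) {
        if (is.null(out[[tok]]))
          out[[tok]] <- signal * centroids[[cc]] + stats::rnorm(dim, sd = 1)
      }
    }
    for (f in unique(c(SYN_FILLERS,
                       strsplit(paste(c(SYN_TEMPLATES, SYN_FILLER_TEMPLATE),
                                      collapse = " "), " ")[[1]])))
      if (is.null(out[[f]]) && f != "<ENT>")
        out[[f]] <- stats::rnorm(dim, sd = 1)
    out
  })
}
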