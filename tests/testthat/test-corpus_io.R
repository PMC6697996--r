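test_that("read_conll parses token-per-line sentences and preserves tags", {
  path <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("Nef\tB-GENE", "protein\tO", "", "the O", "gene B-GENE",
               "", ""), path)
  sents <- read_conll(path, gene_scheme())
  expect_length(sents, 2)               # trailing blank lines ignored
  expect_equal(sents[[1]]$tokens, c("Nef", "protein"))
  expect_equal(sents[[1]]$tags, c("B-GENE", "O"))
  expect_equal(sents[[2]]$tags, c("O", "B-GENE"))  # space-separated accepted
})

test_that("read_conll reports malformed lines and unknown tags by line number", {
  path <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("ok\tO", "bad line here\textra", ""), path)
  expect_error(read_conll(path, gene_scheme()), "line 2")
  writeLines(c("ok\tO", "x\tB-UNKNOWN", ""), path)
  expect_error(read_conll(path, gene_scheme()), "line 2.*B-UNKNOWN")
})

test_that("read/write round-trips normalized files byte-identically", {
  path <- withr::local_tempfile(fileext = ".conll")
  content <- c("a\tO", "geneX\tB-GENE", "", "b\tO", "")
  writeLines(content, path, sep = "\n")
  sents <- read_conll(path, gene_scheme())
  out <- withr::local_tempfile(fileext = ".conll")
  write_conll(sents, out)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(path, "raw", file.size(path)))
})

test_that("validate_tags enforces the scheme variant", {
  sch <- two_type_scheme()
  ok <- sent(c("a", "b"), c("B-GENE", "I-GENE"))
  expect_equal(nrow(validate_tags(ok, sch)), 0)
  orphan <- sent(c("a", "b"), c("O", "I-GENE"))
  v <- validate_tags(orphan, sch)
  expect_equal(v$position, 2)
  expect_match(v$reason, "I- without preceding B-")
  # type switch inside an entity is illegal under both variants
  switch_ <- sent(c("a", "b"), c("B-GENE", "I-DISEASE"))
  expect_equal(validate_tags(switch_, sch)$position, 2)
  sch1 <- tag_scheme(c("O", "B-GENE", "I-GENE", "B-DISEASE", "I-DISEASE"),
                     variant = "IOB1")
  expect_equal(nrow(validate_tags(orphan, sch1)), 0)  # IOB1 allows I- openings
  expect_equal(validate_tags(switch_, sch1)$position, 2)
})

test_that("subsample_corpus reduces only the train split, reproducibly", {
  corpus <- tiny_corpus(n_train = 10)
  expect_identical(subsample_corpus(corpus, 1.0, 1), corpus)
  half <- subsample_corpus(corpus, 0.5, 42)
  expect_length(half$splits$train, 5)
  expect_true(all(vapply(half$splits$train, function(s)
    any(vapply(corpus$splits$train, identical, logical(1), s)),
    logical(1))))
  expect_identical(half$splits$dev, corpus$splits$dev)
  expect_identical(half$splits$test, corpus$splits$test)
  expect_identical(subsample_corpus(corpus, 0.5, 42), half)
  other <- subsample_corpus(corpus, 0.5, 43)
  expect_false(identical(other$splits$train, half$splits$train))
  # round-half-up: 0.25 * 10 = 2.5 -> 3
  expect_length(subsample_corpus(corpus, 0.25, 1)$splits$train, 3)
  expect_error(subsample_corpus(corpus, 0, 1), "fraction")
  expect_error(subsample_corpus(corpus, 1.2, 1), "fraction")
})

test_that("build_vocab indexes words, chars and per-dataset tags", {
  c1 <- tagged_corpus("d1", "D1",
                      train = list(sent(c("a", "b"), c("O", "O"))),
                      scheme = tag_scheme(c("O", "B-GENE")))
  c2 <- tagged_corpus("d2", "D2",
                      train = list(sent(c("b", "c"), c("O", "O"))),
                      scheme = tag_scheme(c("O", "B-Disease")))
  v <- build_vocab(list(c1, c2))
  expect_length(v$word_index, 5)  # PAD UNK a b c
  expect_equal(unname(v$word_index[c("<PAD>", "<UNK>")]), c(1L, 2L))
  expect_equal(unname(diff(sort(v$word_index))), rep(1L, 4))
  expect_equal(vapply(v$tag_index, length, integer(1)),
               c(d1 = 2L, d2 = 2L))
  # unseen word falls back to lowercase, then UNK
  expect_equal(crossner:::lookup_words("A", v$word_index),
               unname(v$word_index[["a"]]))
  expect_equal(crossner:::lookup_words("zzz", v$word_index), 2L)
  expect_error(build_vocab(list()), "at least one")
})

test_that("corpus_stats counts maximal B..I runs and matches a linear-scan oracle", {
  sch <- two_type_scheme()
  corpus <- tagged_corpus("t", "D1", train = list(
    sent(letters[1:4], c("B-GENE", "I-GENE", "O", "B-GENE")),
    sent(letters[1:3], c("O", "O", "O"))), scheme = sch)
  st <- corpus_stats(corpus)
  expect_equal(st$Gene[st$split == "train"], 2L)
  # independent run-length oracle on random corpora
  set.seed(31)
  oracle_count <- function(tags) {
    n <- 0; inside <- FALSE; cur <- ""
    for (tg in tags) {
      if (grepl("^B-", tg)) { n <- n + 1; inside <- TRUE; cur <- sub("^B-", "", tg) }
      else if (grepl("^I-", tg)) {
        if (!inside || cur != sub("^I-", "", tg)) {
          n <- n + 1; inside <- TRUE; cur <- sub("^I-", "", tg)
        }
      } else inside <- FALSE
    }
    n
  }
  labels <- sch$labels
  for (rep in 1:10) {
    sents <- lapply(1:5, function(i) {
      tags <- sample(labels, sample(1:8, 1), replace = TRUE)
      sent(rep("w", length(tags)), tags)
    })
    corpus <- tagged_corpus("r", "D1", train = sents, scheme = sch)
    st <- corpus_stats(corpus)
    total <- sum(st[st$split == "train", c("Gene", "Disease")])
    expect_equal(total, sum(vapply(sents, function(s)
      oracle_count(s$tags), numeric(1))))
    # invariant to sentence order
    corpus2 <- tagged_corpus("r", "D1", train = rev(sents), scheme = sch)
    expect_equal(corpus_stats(corpus2)[1, -1], st[1, -1])
  }
})
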