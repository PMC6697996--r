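# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

gene_scheme <- function(variant = "IOB2")
  tag_scheme(c("O", "B-GENE", "I-GENE"), variant = variant)

two_type_scheme <- function()
  tag_scheme(c("O", "B-GENE", "I-GENE", "B-DISEASE", "I-DISEASE"))

sent <- function(tokens, tags) list(tokens = tokens, tags = tags)

# a tiny deterministic corpus over the gene scheme
tiny_corpus <- function(n_train = 6, name = "tiny", id = "D1",
                        scheme = gene_scheme()) {
  mk <- function(i) sent(c("the", paste0("gene", i), "binds"),
                         c("O", "B-GENE", "O"))
  tagged_corpus(name, id,
                train = lapply(seq_len(n_train), mk),
                dev = lapply(seq_len(2) + 100, mk),
                test = lapply(seq_len(2) + 200, mk),
                scheme = scheme)
}

# micro model configuration: small dims so unit tests run in milliseconds
micro_config <- function(seed = 1L, dropout = 0.5)
  model_config(d_w = 6, d_c = 4, n_filters = 5, l_f = 3, hidden = 5,
               proj = 4, dropout = dropout, seed = seed)

# small synthetic pair shared by model/training tests
small_pair <- function(seed = 5, rho = 0.5, n_main = 30, n_aux = 30) {
  spec <- synthetic_spec(
    main = list(n_train = n_main, n_dev = 10L, n_test = 10L,
                categories = c(Gene = 20L)),
    aux = list(n_train = n_aux, n_dev = 10L, n_test = 10L,
               categories = c(Gene = 20L, Chemical = 10L)),
    rho = rho, seed = seed)
  generate_corpus_pair(spec)
}

# reduced-dimension configuration used by the learnability runs
reduced_config <- function(seed)
  model_config(d_w = 25, d_c = 10, n_filters = 10, l_f = 3, hidden = 32,
               proj = 32, seed = seed)

# tag-level macro F1 of a fit on a sentence list (percent scale)
macro_f1_on <- function(fit, sentences, labels) {
  pred <- predict_tags(fit$model, sentences, d = 1)
  gold <- lapply(sentences, `[[`, "tags")
  unname(tag_metrics(pred, gold, tag_scheme(labels))$macro["f1"])
}

# whole-model numeric gradient of a scalar loss at one parameter entry
numeric_grad_entry <- function(model, batch, path, ii, d = 1,
                               alpha = 0, beta = 0, eps = 1e-5,
                               component = "total") {
  val <- function(m) {
    r <- crossner:::compute_batch(m, batch, d = d, train = FALSE,
                                  grad = FALSE, alpha = alpha, beta = beta)
    switch(component, total = r$loss, task = r$breakdown$L_task,
           adv = r$breakdown$L_adv, diff = r$breakdown$L_diff)
  }
  m2 <- model; m2$params[[path]][ii] <- m2$params[[path]][ii] + eps
  f1 <- val(m2)
  m2$params[[path]][ii] <- m2$params[[path]][ii] - 2 * eps
  f0 <- val(m2)
  (f1 - f0) / (2 * eps)
}
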