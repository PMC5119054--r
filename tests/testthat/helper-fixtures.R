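# Shared fixtures: the printed two-sentence worked-example treebank
# ("This is an example" / "This example is very convincing") built in
# code, plus paths to its file transcriptions.

example_treebank <- function() {
  treebank(data.frame(
    sent = c(rep("s1", 4), rep("s2", 5)),
    id = c(1:4, 1:5),
    form = c("This", "Is", "An", "Example",
             "This", "Example", "Is", "Very", "Convincing"),
    pos = c("pro", "v", "det", "n", "pro", "n", "v", "adv", "adj"),
    head = c(2L, 0L, 4L, 2L, 2L, 3L, 0L, 5L, 2L),
    deprel = c("subj", "root", "atr", "obj",
               "atr", "subj", "root", "adva", "obj"),
    stringsAsFactors = FALSE
  ), name = "example")
}

example_table_path <- function() {
  system.file("extdata", "table1_treebank.tsv", package = "depnet")
}

example_conllu_path <- function() {
  system.file("extdata", "table1.conllu", package = "depnet")
}

# small treebank with two sentences sharing no word types
disjoint_treebank <- function() {
  treebank(data.frame(
    sent = c("s1", "s1", "s2", "s2"),
    id = c(1:2, 1:2),
    form = c("a", "b", "c", "d"),
    pos = "n",
    head = c(0L, 1L, 0L, 1L),
    deprel = c("root", "obj", "root", "obj"),
    stringsAsFactors = FALSE
  ), name = "disjoint")
}

small_preset_pair <- function(seed = 7, n_sentences = c(150, 158)) {
  seeds <- withr::with_seed(seed, sample.int(1e6, 2))
  list(
    a = generate_treebank(generator_config(
      n_sentences = n_sentences[1], mean_sentence_length = 17.61,
      content_vocab_size = 600, function_rate = 0.17, seed = seeds[1]),
      name = "small_a"),
    b = generate_treebank(generator_config(
      n_sentences = n_sentences[2], mean_sentence_length = 16.67,
      content_vocab_size = 1100, function_rate = 0.23, seed = seeds[2]),
      name = "small_b")
  )
}
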