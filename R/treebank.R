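# Treebank container and corpus-level lexical statistics.
#
# A treebank is stored as a flat token table (one row per word token) plus a
# name. Within a sentence, tokens are indexed 1..n and `head` points at the
# governor's index, with 0 marking the sentence root.

#' Construct a treebank object
#'
#' @param tokens data.frame with columns `sent` (sentence id, character),
#'   `id` (1-based token index within sentence), `form` (word form), `pos`
#'   (part-of-speech tag), `head` (governor index, 0 for the root) and
#'   `deprel` (dependency-type label).
#' @param name corpus name used in reports.
#' @param validate run [validate_treebank()] on the result.
#' @return An object of class `treebank`.
#' @examples
#' tb <- treebank(data.frame(
#'   sent = "s1", id = 1:2, form = c("A", "B"), pos = c("n", "v"),
#'   head = c(2L, 0L), deprel = c("subj", "root")))
#' n_tokens(tb)
#' @export
treebank <- function(tokens, name = "treebank", validate = TRUE) {
  needed <- c("sent", "id", "form", "pos", "head", "deprel")
  missing <- setdiff(needed, names(tokens))
  if (length(missing) > 0) {
    stop("treebank tokens lack column(s): ", paste(missing, collapse = ", "))
  }
  tokens <- as.data.frame(tokens)[needed]
  tokens$sent <- as.character(tokens$sent)
  tokens$id <- as.integer(tokens$id)
  tokens$head <- as.integer(tokens$head)
  tokens$form <- as.character(tokens$form)
  tokens$pos <- as.character(tokens$pos)
  tokens$deprel <- as.character(tokens$deprel)
  tb <- structure(list(tokens = tokens, name = as.character(name)),
                  class = "treebank")
  if (validate) validate_treebank(tb)
  tb
}

#' Validate treebank invariants
#'
#' Checks, per sentence: token indices run 1..n, exactly one root
#' (`head == 0`), every head lies in `[0, n]` and differs from the token's
#' own index, and head links form a tree (no cycles). A sentence of n tokens
#' therefore carries exactly n - 1 dependencies.
#'
#' @param tb a `treebank`.
#' @return `tb`, invisibly; stops with an informative error naming the
#'   offending sentence otherwise.
#' @export
validate_treebank <- function(tb) {
  stopifnot(inherits(tb, "treebank"))
  if (nrow(tb$tokens) == 0) stop("treebank is empty")
  for (sid in unique(tb$tokens$sent)) {
    s <- tb$tokens[tb$tokens$sent == sid, ]
    n <- nrow(s)
    s <- s[order(s$id), ]
    if (!identical(s$id, seq_len(n))) {
      stop("sentence '", sid, "': token indices are not 1..", n)
    }
    if (sum(s$head == 0) != 1) {
      stop("sentence '", sid, "': expected exactly one root token, found ",
           sum(s$head == 0))
    }
    if (any(s$head < 0 | s$head > n)) {
      stop("sentence '", sid, "': head index out of range 0..", n)
    }
    if (any(s$head == s$id)) {
      stop("sentence '", sid, "': token is its own governor")
    }
    # cycle check: repeatedly follow heads; a tree reaches 0 within n steps
    for (i in seq_len(n)) {
      cur <- i
      for (step in seq_len(n)) {
        cur <- s$head[cur]
        if (cur == 0) break
      }
      if (cur != 0) stop("sentence '", sid, "': head links contain a cycle")
    }
  }
  invisible(tb)
}

#' @export
print.treebank <- function(x, ...) {
  cat("<treebank> ", x$name, ": ", length(unique(x$tokens$sent)),
      " sentences, ", nrow(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

#' Number of tokens / sentences in a treebank
#' @param tb a `treebank`.
#' @return integer count.
#' @export
n_tokens <- function(tb) nrow(tb$tokens)

#' @rdname n_tokens
#' @export
n_sentences <- function(tb) length(unique(tb$tokens$sent))

#' Default part-of-speech tags treated as punctuation
#'
#' Tokens with these tags are dropped from networks and counts when
#' `exclude_punct = TRUE` (the default throughout), mirroring corpus counts
#' reported without punctuation.
#' @return character vector of tags.
#' @export
punctuation_tags <- function() c("punct", "PUNCT", "w", "wp", "PU")

#' Function-word lexicon
#'
#' A function word is recognised either by its part-of-speech tag or by an
#' explicit word-form list. The default tag set covers conjunctions (`c`),
#' adverbs (`d`), prepositions (`p`), the passive preposition (`pbei`) and
#' the relative marker (`ude1`).
#'
#' @param pos_tags POS tags counted as function words.
#' @param forms explicit word forms counted as function words regardless of
#'   their tag.
#' @return An object of class `function_word_lexicon`.
#' @export
function_word_lexicon <- function(pos_tags = c("c", "d", "p", "pbei", "ude1"),
                                  forms = character()) {
  pos_tags <- unique(as.character(pos_tags))
  forms <- unique(as.character(forms))
  if (length(pos_tags) + length(forms) == 0) {
    stop("function-word lexicon needs at least one POS tag or word form")
  }
  structure(list(pos_tags = pos_tags, forms = forms),
            class = "function_word_lexicon")
}

#' @export
print.function_word_lexicon <- function(x, ...) {
  cat("<function_word_lexicon> tags: {",
      paste(x$pos_tags, collapse = ", "), "}",
      if (length(x$forms) > 0) paste0("; ", length(x$forms), " explicit forms"),
      "\n", sep = "")
  invisible(x)
}

#' Is a token a function word?
#'
#' Vectorised over `form`/`pos`: TRUE iff the POS tag is in the lexicon's tag
#' set or the form is in its explicit form list.
#'
#' @param form word form(s).
#' @param pos part-of-speech tag(s), recycled against `form`.
#' @param lex a [function_word_lexicon()].
#' @return logical vector.
#' @export
is_function_word <- function(form, pos, lex = function_word_lexicon()) {
  stopifnot(inherits(lex, "function_word_lexicon"))
  (pos %in% lex$pos_tags) | (form %in% lex$forms)
}

#' Type/token ratio
#'
#' Vocabulary richness as distinct word types over word tokens.
#' @param n_types,n_tokens counts.
#' @return ratio in (0, 1].
#' @export
ttr <- function(n_types, n_tokens) {
  if (any(n_tokens <= 0)) stop("token count must be positive")
  n_types / n_tokens
}

#' Corpus-level lexical statistics
#'
#' Token/type/sentence counts, mean sentence length, type/token ratio and
#' the function-word token count under a lexicon. Word-type identity is the
#' exact surface form string by default; set `key = "form_pos"` to key types
#' on (form, POS) pairs.
#'
#' @param tb a `treebank`.
#' @param lex a [function_word_lexicon()].
#' @param exclude_punct drop tokens whose POS is in `punct_pos` before
#'   counting.
#' @param punct_pos POS tags treated as punctuation.
#' @param key word-type identity: surface form, or form plus POS.
#' @return An object of class `corpus_stats`: a list with `token_count`,
#'   `type_count`, `sentence_count`, `mean_sentence_length`, `ttr`,
#'   `function_token_count` and `function_word_pct`.
#' @export
corpus_stats <- function(tb, lex = function_word_lexicon(),
                         exclude_punct = TRUE,
                         punct_pos = punctuation_tags(),
                         key = c("form", "form_pos")) {
  stopifnot(inherits(tb, "treebank"))
  key <- match.arg(key)
  tok <- tb$tokens
  if (exclude_punct) tok <- tok[!(tok$pos %in% punct_pos), ]
  if (nrow(tok) == 0) stop("no tokens left after punctuation exclusion")
  keys <- if (key == "form") tok$form else paste(tok$form, tok$pos, sep = "\r")
  n_tok <- nrow(tok)
  n_typ <- length(unique(keys))
  n_sent <- length(unique(tb$tokens$sent))
  n_fun <- sum(is_function_word(tok$form, tok$pos, lex))
  structure(list(
    token_count = n_tok,
    type_count = n_typ,
    sentence_count = n_sent,
    mean_sentence_length = n_tok / n_sent,
    ttr = ttr(n_typ, n_tok),
    function_token_count = n_fun,
    function_word_pct = function_word_percentage(n_fun, n_tok)
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats>\n",
      "  tokens: ", x$token_count, "   types: ", x$type_count,
      "   sentences: ", x$sentence_count, "\n",
      "  mean sentence length: ", round(x$mean_sentence_length, 2), "\n",
      "  TTR: ", round(x$ttr, 4),
      "   function-word tokens: ", x$function_token_count,
      " (", round(x$function_word_pct, 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.corpus_stats <- function(x, ...) {
  as.data.frame(unclass(x))
}
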