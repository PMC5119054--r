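# Synthetic dependency treebank generator.
#
# The generator produces corpora with the statistical structure the
# pipeline assumes: a Zipfian rank-frequency lexicon split into a shared
# high-frequency function-word sub-lexicon and a content lexicon, sentence
# lengths around a target mean, and random tree-shaped dependency
# structures. It makes no claim to linguistic realism; it exists so that
# every pipeline stage is testable without external corpora.

#' Zipf rank-frequency probabilities
#'
#' @param n number of ranks.
#' @param s Zipf exponent (> 0).
#' @return probability vector proportional to `rank^(-s)`.
#' @export
zipf_probs <- function(n, s = 1) {
  if (n < 1) stop("n must be >= 1")
  if (s <= 0) stop("Zipf exponent must be > 0")
  p <- seq_len(n)^(-s)
  p / sum(p)
}

#' Shared function-word sub-lexicon
#'
#' A fixed lexicon of function-word forms (`fw001`, `fw002`, ...) with POS
#' tags cycling over the function-word tag set; both group presets share
#' it, mirroring a closed function-word class.
#'
#' @param size number of function-word types (default 128).
#' @return data.frame with columns `form`, `pos`.
#' @export
function_sublexicon <- function(size = 128) {
  data.frame(form = sprintf("fw%03d", seq_len(size)),
             pos = rep_len(c("ude1", "p", "d", "c", "pbei"), size),
             stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' @param n_sentences number of sentences.
#' @param mean_sentence_length target mean tokens per sentence (>= 1).
#' @param length_family sentence-length distribution:
#'   `"poisson_shifted"` (1 + Poisson) or `"lognormal_rounded"`.
#' @param content_vocab_size content-word vocabulary size.
#' @param zipf_exponent Zipf exponent for content-word frequencies.
#' @param function_lexicon_size size of the shared function sub-lexicon.
#' @param function_rate probability in `[0, 1)` that a token is a function
#'   word.
#' @param attachment governor-choice rule for non-root tokens:
#'   `"uniform"` (uniform random recursive tree) or `"degree_biased"`
#'   (governor probability proportional to the current corpus-wide degree
#'   of the candidate's word type + 1, strengthening hubs).
#' @param seed integer seed; generation is reproducible given the seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_sentences = 1200,
                             mean_sentence_length = 17.6,
                             length_family = c("poisson_shifted",
                                               "lognormal_rounded"),
                             content_vocab_size = 3500,
                             zipf_exponent = 1,
                             function_lexicon_size = 128,
                             function_rate = 0.2,
                             attachment = c("uniform", "degree_biased"),
                             seed = 1) {
  length_family <- match.arg(length_family)
  attachment <- match.arg(attachment)
  if (n_sentences < 1) stop("n_sentences must be >= 1")
  if (mean_sentence_length < 1) stop("mean sentence length must be >= 1")
  if (content_vocab_size < 1) stop("content vocabulary must be >= 1 type")
  if (function_lexicon_size < 1) stop("function lexicon must be >= 1 type")
  if (function_rate < 0 || function_rate >= 1) {
    stop("function_rate must lie in [0, 1)")
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 mean_sentence_length = mean_sentence_length,
                 length_family = length_family,
                 content_vocab_size = as.integer(content_vocab_size),
                 zipf_exponent = zipf_exponent,
                 function_lexicon_size = as.integer(function_lexicon_size),
                 function_rate = function_rate,
                 attachment = attachment,
                 seed = as.integer(seed)),
            class = "generator_config")
}

draw_lengths <- function(cfg) {
  m <- cfg$mean_sentence_length
  switch(cfg$length_family,
         poisson_shifted = 1L + rpois(cfg$n_sentences, m - 1),
         lognormal_rounded = {
           sdlog <- 0.6
           meanlog <- log(m) - sdlog^2 / 2
           pmax(1L, as.integer(round(rlnorm(cfg$n_sentences, meanlog, sdlog))))
         })
}

# random tree over n positions: returns head vector (0 = root). Uniform
# attachment joins each position to a uniformly chosen earlier position of
# a random insertion order (a uniform random recursive tree). Degree-biased
# attachment weights candidate governors by the current corpus-wide degree
# of their word type (+1), so frequent types accumulate extra arcs and the
# degree tail grows heavier than under the uniform rule.
draw_tree <- function(n, attachment, type_idx = NULL, type_deg = NULL) {
  head_ <- integer(n)
  if (n == 1) return(list(head = head_, type_deg = type_deg))
  perm <- sample.int(n)
  if (attachment == "uniform") {
    for (j in 2:n) head_[perm[j]] <- perm[sample.int(j - 1, 1)]
  } else {
    for (j in 2:n) {
      cand <- perm[seq_len(j - 1)]
      w <- type_deg[type_idx[cand]] + 1
      pick <- cand[sample.int(j - 1, 1, prob = w)]
      head_[perm[j]] <- pick
      type_deg[type_idx[pick]] <- type_deg[type_idx[pick]] + 1L
      type_deg[type_idx[perm[j]]] <- type_deg[type_idx[perm[j]]] + 1L
    }
  }
  list(head = head_, type_deg = type_deg)
}

#' Generate a synthetic dependency treebank
#'
#' Each sentence draws its length, then each token is a function word with
#' probability `function_rate` (form drawn Zipf(1) from the shared
#' function sub-lexicon) or a content word (form drawn Zipf(s) from the
#' content lexicon). Heads form a random tree over the sentence positions
#' under the configured attachment rule; one position is the root.
#' Dependency labels are drawn from a small fixed set and carried through
#' but never used by the measures.
#'
#' @param cfg a [generator_config()].
#' @param name treebank name.
#' @return a validated `treebank`.
#' @export
generate_treebank <- function(cfg, name = "synthetic") {
  stopifnot(inherits(cfg, "generator_config"))
  fw <- function_sublexicon(cfg$function_lexicon_size)
  cw <- data.frame(form = sprintf("w%05d", seq_len(cfg$content_vocab_size)),
                   pos = rep_len(c("n", "v", "adj", "nr", "m"),
                                 cfg$content_vocab_size),
                   stringsAsFactors = FALSE)
  fw_p <- zipf_probs(nrow(fw), 1)
  cw_p <- zipf_probs(nrow(cw), cfg$zipf_exponent)
  rels <- c("subj", "obj", "atr", "adva", "comp", "de")
  withr::with_seed(cfg$seed, {
    lens <- draw_lengths(cfg)
    total <- sum(lens)
    sent <- rep.int(seq_along(lens), lens)
    is_fun <- runif(total) < cfg$function_rate
    form <- character(total)
    pos <- character(total)
    n_fun <- sum(is_fun)
    if (n_fun > 0) {
      idx <- sample.int(nrow(fw), n_fun, replace = TRUE, prob = fw_p)
      form[is_fun] <- fw$form[idx]
      pos[is_fun] <- fw$pos[idx]
    }
    if (n_fun < total) {
      idx <- sample.int(nrow(cw), total - n_fun, replace = TRUE, prob = cw_p)
      form[!is_fun] <- cw$form[idx]
      pos[!is_fun] <- cw$pos[idx]
    }
    # corpus-wide type index (function types first, then content types)
    type_idx <- integer(total)
    if (n_fun > 0) type_idx[is_fun] <- match(form[is_fun], fw$form)
    if (n_fun < total) {
      type_idx[!is_fun] <- nrow(fw) + match(form[!is_fun], cw$form)
    }
    type_deg <- integer(nrow(fw) + nrow(cw))
    head_ <- integer(total)
    off <- 0L
    for (i in seq_along(lens)) {
      sel <- off + seq_len(lens[i])
      tr <- draw_tree(lens[i], cfg$attachment, type_idx[sel], type_deg)
      head_[sel] <- tr$head
      if (cfg$attachment == "degree_biased") type_deg <- tr$type_deg
      off <- off + lens[i]
    }
    deprel <- sample(rels, total, replace = TRUE)
    deprel[head_ == 0] <- "root"
    tok <- data.frame(sent = sprintf("s%d", sent),
                      id = unlist(lapply(lens, seq_len)),
                      form = form, pos = pos, head = head_, deprel = deprel,
                      stringsAsFactors = FALSE)
    treebank(tok, name = name, validate = FALSE)
  })
}

#' Two-group synthetic corpus presets
#'
#' Emulates two corpora of roughly 21,000 word tokens each with a shared
#' 128-type function-word lexicon: the `dhh_like` preset has the smaller
#' content vocabulary and the lower function-word rate (0.17), the
#' `nh_like` preset the larger vocabulary and the higher rate (0.23).
#' Vocabulary sizes are calibrated so the realised type counts land near
#' 2,600 and 3,700 word types.
#'
#' @param master_seed integer seed from which both group seeds derive.
#' @return list with elements `dhh_like` and `nh_like` (treebanks) and
#'   `configs` (the two `generator_config` objects).
#' @export
two_group_presets <- function(master_seed = 1) {
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max, 2))
  cfg_a <- generator_config(n_sentences = 1200,
                            mean_sentence_length = 17.61,
                            content_vocab_size = 3500,
                            function_rate = 0.17,
                            seed = seeds[1])
  cfg_b <- generator_config(n_sentences = 1260,
                            mean_sentence_length = 16.67,
                            content_vocab_size = 8000,
                            function_rate = 0.23,
                            seed = seeds[2])
  list(dhh_like = generate_treebank(cfg_a, name = "dhh_like"),
       nh_like = generate_treebank(cfg_b, name = "nh_like"),
       configs = list(dhh_like = cfg_a, nh_like = cfg_b))
}
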