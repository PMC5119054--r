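# Readers and writers for dependency treebank files.

#' Read a CoNLL-X / CoNLL-U treebank
#'
#' Parses the ten-column CoNLL format. Sentences are separated by blank
#' lines; comment lines (starting with `#`) are ignored. CoNLL-U multiword
#' token ranges (`1-2`) and empty nodes (`1.1`) are skipped, so only the
#' basic dependency layer is read. The POS tag is taken from column 4
#' (UPOS/CPOSTAG), falling back to column 5 when column 4 is `_`.
#'
#' @param path file path.
#' @param dialect `"conllu"` or `"conllx"` (parsed identically at the column
#'   level; the flag is kept for interface clarity).
#' @param name corpus name; defaults to the file name.
#' @return a validated `treebank`.
#' @export
read_conll <- function(path, dialect = c("conllu", "conllx"),
                       name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- grepl("^\\s*$", lines)
  tokline <- !blank & !startsWith(lines, "#")
  if (!any(tokline)) stop("no tokens found in ", path)
  # sentences are maximal runs of token lines separated by blank lines
  grp <- cumsum(blank)[tokline]
  grp <- match(grp, unique(grp))
  lineno <- which(tokline)
  fields <- strsplit(lines[tokline], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    bad <- which(nf < 8)[1]
    stop("malformed CoNLL line ", lineno[bad], " in ", path,
         ": expected >= 8 tab-separated fields, got ", nf[bad])
  }
  m <- t(vapply(fields, function(f) f[1:8], character(8)))
  keep <- !grepl("[-.]", m[, 1])  # drop multiword ranges and empty nodes
  m <- m[keep, , drop = FALSE]
  grp <- grp[keep]
  lineno <- lineno[keep]
  if (nrow(m) == 0) stop("no tokens found in ", path)
  idx <- suppressWarnings(as.integer(m[, 1]))
  hd <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(idx) || anyNA(hd)) {
    bad <- which(is.na(idx) | is.na(hd))[1]
    stop("malformed CoNLL line ", lineno[bad], " in ", path,
         ": non-integer ID or HEAD")
  }
  pos <- ifelse(m[, 4] != "_", m[, 4], m[, 5])
  treebank(data.frame(sent = sprintf("s%d", grp), id = idx, form = m[, 2],
                      pos = pos, head = hd, deprel = m[, 8],
                      stringsAsFactors = FALSE),
           name = name)
}

#' Write a treebank as CoNLL-U
#'
#' Ten-column output with `# sent_id` comments and blank-line sentence
#' separators; unused columns are written as `_`. A [read_conll()] of the
#' result reproduces forms, POS tags, heads and dependency labels exactly.
#'
#' @param tb a `treebank`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(tb, path) {
  stopifnot(inherits(tb, "treebank"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (sid in unique(tb$tokens$sent)) {
    s <- tb$tokens[tb$tokens$sent == sid, ]
    s <- s[order(s$id), ]
    writeLines(paste0("# sent_id = ", sid), con)
    writeLines(sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                       s$id, s$form, s$pos, s$head, s$deprel), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a tabular dependency-list treebank
#'
#' Reads the dependency-list dialect in which each row is one token of the
#' corpus with columns: sentence number, dependent order number / word /
#' POS, governor order number / word / POS, and dependency type. Root rows
#' leave the governor columns empty. Order numbers may run corpus-globally
#' (continuing across sentences); they are renumbered 1..n per sentence.
#' When a row's governor word string disagrees with the word actually found
#' at the governor's order number, the order number wins and a warning is
#' issued.
#'
#' @param path CSV (`.csv`) or TSV file with a header row and eight columns
#'   in the order above.
#' @param sep field separator; guessed from the extension by default.
#' @param name corpus name; defaults to the file name.
#' @return a validated `treebank`.
#' @export
read_dependency_table <- function(path, sep = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, sep = sep, header = TRUE, quote = "\"",
                    colClasses = "character", fill = TRUE,
                    fileEncoding = "UTF-8", check.names = FALSE)
  if (ncol(raw) < 8) stop("dependency table needs 8 columns, found ", ncol(raw))
  names(raw)[1:8] <- c("sentence", "dep_order", "dep_word", "dep_pos",
                       "gov_order", "gov_word", "gov_pos", "deprel")
  for (col in c("sentence", "dep_word", "dep_pos", "gov_word", "gov_pos",
                "deprel")) {
    raw[[col]] <- trimws(raw[[col]])
  }
  raw$dep_order <- suppressWarnings(as.integer(trimws(raw$dep_order)))
  raw$gov_order <- suppressWarnings(as.integer(trimws(raw$gov_order)))
  if (any(is.na(raw$dep_order))) stop("non-integer dependent order number")
  out <- vector("list", length(unique(raw$sentence)))
  for (i in seq_along(out)) {
    sid <- unique(raw$sentence)[i]
    s <- raw[raw$sentence == sid, ]
    ord <- sort(s$dep_order)
    if (anyDuplicated(ord)) stop("sentence '", sid, "': duplicated order numbers")
    remap <- setNames(seq_along(ord), ord)  # global order -> 1..n
    id <- unname(remap[as.character(s$dep_order)])
    head_ <- integer(nrow(s))
    for (r in seq_len(nrow(s))) {
      go <- s$gov_order[r]
      if (is.na(go)) { head_[r] <- 0L; next }
      hit <- remap[as.character(go)]
      if (is.na(hit)) {
        stop("sentence '", sid, "': governor order number ", go,
             " not found among the sentence's dependent rows")
      }
      actual <- s$dep_word[s$dep_order == go]
      if (nzchar(trimws(s$gov_word[r])) && !identical(actual, s$gov_word[r])) {
        warning("sentence '", sid, "', token '", s$dep_word[r],
                "': governor word listed as '", s$gov_word[r],
                "' but order number ", go, " holds '", actual,
                "'; resolving by order number", call. = FALSE)
      }
      head_[r] <- unname(hit)
    }
    out[[i]] <- data.frame(sent = sid, id = id, form = s$dep_word,
                           pos = s$dep_pos, head = head_, deprel = s$deprel,
                           stringsAsFactors = FALSE)
  }
  tok <- do.call(rbind, out)
  tok$deprel[tok$head == 0 & !nzchar(trimws(tok$deprel))] <- "root"
  treebank(tok, name = name)
}

#' Write corpus statistics as JSON
#'
#' @param stats a `corpus_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_stats <- function(stats, path) {
  stopifnot(inherits(stats, "corpus_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
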