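#' Read a DDI-corpus-style XML file
#'
#' The dialect follows the drug-drug interaction corpus layout: `<corpus>`
#' containing `<document id=...>` elements, each containing `<sentence id=...
#' text=...>` elements; a sentence holds `<entity id=... charOffset="s-e"
#' text=.../>` mentions (inclusive character offsets, converted here to
#' 0-based half-open) and `<pair id=... e1=... e2=... interaction="true|
#' false"/>` candidate pairs referencing entity ids.
#'
#' @param path path to the corpus XML file.
#' @return a data structure of class `ddi_corpus`: list of documents, each a
#'   list of sentences with `doc_id`, `sentence_id`, `text`, `entities`
#'   (data.frame id/char_start/char_end/text) and `pairs` (data.frame
#'   id/e1/e2/interaction).
#' @export
read_ddi_corpus <- function(path) {
  doc <- xml2::read_xml(path)
  sentences <- list()
  for (dnode in xml2::xml_find_all(doc, ".//document")) {
    doc_id <- xml2::xml_attr(dnode, "id")
    for (snode in xml2::xml_find_all(dnode, "./sentence")) {
      sid <- xml2::xml_attr(snode, "id")
      text <- xml2::xml_attr(snode, "text")
      ents <- xml2::xml_find_all(snode, "./entity")
      ent_df <- data.frame(
        id = xml2::xml_attr(ents, "id"),
        char_start = integer(length(ents)),
        char_end = integer(length(ents)),
        text = xml2::xml_attr(ents, "text"),
        stringsAsFactors = FALSE
      )
      if (length(ents)) {
        off <- xml2::xml_attr(ents, "charOffset")
        parts <- regmatches(off, regexec("^(\\d+)-(\\d+)$", off))
        bad <- vapply(parts, length, integer(1)) != 3L
        if (any(bad)) {
          stop(sprintf("sentence %s: malformed charOffset '%s'",
                       sid, off[bad][1]))
        }
        # corpus offsets are inclusive; convert to 0-based half-open
        ent_df$char_start <- vapply(parts, function(p) as.integer(p[2]),
                                    integer(1))
        ent_df$char_end <- vapply(parts, function(p) as.integer(p[3]),
                                  integer(1)) + 1L
        span_text <- substring(text, ent_df$char_start + 1L, ent_df$char_end)
        mism <- span_text != ent_df$text
        if (any(mism)) {
          stop(sprintf(
            "sentence %s: entity %s text '%s' does not match span '%s'",
            sid, ent_df$id[mism][1], ent_df$text[mism][1],
            span_text[mism][1]))
        }
      }
      if (anyDuplicated(ent_df$id)) {
        stop(sprintf("sentence %s: duplicate entity ids", sid))
      }
      prs <- xml2::xml_find_all(snode, "./pair")
      pair_df <- data.frame(
        id = xml2::xml_attr(prs, "id"),
        e1 = xml2::xml_attr(prs, "e1"),
        e2 = xml2::xml_attr(prs, "e2"),
        interaction = tolower(xml2::xml_attr(prs, "interaction")) == "true",
        stringsAsFactors = FALSE
      )
      dangling <- setdiff(c(pair_df$e1, pair_df$e2), ent_df$id)
      if (length(dangling)) {
        stop(sprintf("sentence %s: pair references unknown entity id(s) %s",
                     sid, paste(dangling, collapse = ",")))
      }
      sentences[[length(sentences) + 1L]] <- list(
        doc_id = doc_id, sentence_id = sid, text = text,
        entities = ent_df, pairs = pair_df
      )
    }
  }
  structure(list(sentences = sentences), class = "ddi_corpus")
}

#' @export
print.ddi_corpus <- function(x, ...) {
  np <- sum(vapply(x$sentences, function(s) nrow(s$pairs), integer(1)))
  npos <- sum(vapply(x$sentences, function(s) sum(s$pairs$interaction),
                     integer(1)))
  cat(sprintf("ddi_corpus: %d sentences, %d candidate pairs (%d positive)\n",
              length(x$sentences), np, npos))
  invisible(x)
}

#' Write a corpus back to XML (round-trip of the dialect read by
#' [read_ddi_corpus()]).
#'
#' @param corpus a `ddi_corpus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ddi_corpus <- function(corpus, path) {
  xesc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<corpus>")
  by_doc <- split(corpus$sentences,
                  vapply(corpus$sentences, `[[`, "", "doc_id"))
  for (doc_id in names(by_doc)) {
    out <- c(out, sprintf("  <document id=\"%s\">", xesc(doc_id)))
    for (s in by_doc[[doc_id]]) {
      out <- c(out, sprintf("    <sentence id=\"%s\" text=\"%s\">",
                            xesc(s$sentence_id), xesc(s$text)))
      for (i in seq_len(nrow(s$entities))) {
        e <- s$entities[i, ]
        out <- c(out, sprintf(
          "      <entity id=\"%s\" charOffset=\"%d-%d\" text=\"%s\"/>",
          xesc(e$id), e$char_start, e$char_end - 1L, xesc(e$text)))
      }
      for (i in seq_len(nrow(s$pairs))) {
        p <- s$pairs[i, ]
        out <- c(out, sprintf(
          "      <pair id=\"%s\" e1=\"%s\" e2=\"%s\" interaction=\"%s\"/>",
          xesc(p$id), xesc(p$e1), xesc(p$e2),
          if (p$interaction) "true" else "false"))
      }
      out <- c(out, "    </sentence>")
    }
    out <- c(out, "  </document>")
  }
  out <- c(out, "</corpus>")
  writeLines(out, path)
  invisible(path)
}

#' Read CoNLL-style dependency parses
#'
#' One block per sentence, blank-line separated, preceded by a comment line
#' `# <sentence id>`. Each token row has five tab-separated columns: 1-based
#' token index, surface form, POS tag, head index (0 = root) and dependency
#' relation. Root attachments are kept as metadata (`root` indices) but do
#' not become graph edges. Non-tree parses (cycles, multiple heads) are
#' accepted verbatim: the downstream method operates on general directed
#' graphs.
#'
#' @param path path to the parse file.
#' @return named list of parses keyed by sentence id; each parse is a list
#'   with `tokens` (data.frame form/pos), `deps` (data.frame head/dep/rel,
#'   1-based indices, root rows excluded) and `root` (integer vector).
#' @export
read_conll_parses <- function(path) {
  lines <- readLines(path)
  parses <- list()
  cur_id <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(cur_id)) return()
    if (!length(rows)) stop(sprintf("sentence %s: empty parse block", cur_id))
    m <- do.call(rbind, rows)
    idx <- as.integer(m[, 1])
    n <- length(idx)
    if (!identical(idx, seq_len(n))) {
      stop(sprintf("sentence %s: token indices not contiguous from 1", cur_id))
    }
    head_ <- as.integer(m[, 4])
    if (any(is.na(head_)) || any(head_ < 0L) || any(head_ > n)) {
      stop(sprintf("sentence %s: head index out of range", cur_id))
    }
    if (any(head_ == idx)) {
      stop(sprintf("sentence %s: token is its own head", cur_id))
    }
    tokens <- data.frame(form = m[, 2], pos = m[, 3],
                         stringsAsFactors = FALSE)
    is_root <- head_ == 0L
    deps <- data.frame(head = head_[!is_root], dep = idx[!is_root],
                       rel = m[!is_root, 5], stringsAsFactors = FALSE)
    parses[[cur_id]] <<- list(tokens = tokens, deps = deps,
                              root = idx[is_root])
  }
  for (ln in c(lines, "")) {
    if (grepl("^#", ln)) {
      flush()
      cur_id <- sub("^#\\s*", "", ln)
      rows <- list()
    } else if (!nzchar(trimws(ln))) {
      flush()
      cur_id <- NULL
      rows <- list()
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 5L) {
        stop(sprintf("parse row with %d fields (expected 5): '%s'",
                     length(f), ln))
      }
      rows[[length(rows) + 1L]] <- f
    }
  }
  parses
}

# Greedy left-to-right alignment of token forms to the sentence text;
# returns 0-based half-open char offsets per token.
align_tokens <- function(text, forms) {
  n <- length(forms)
  starts <- integer(n)
  ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    hit <- regexpr(forms[i], substring(text, pos), fixed = TRUE)
    if (hit == -1L) {
      stop(sprintf("token '%s' not found in sentence text after position %d",
                   forms[i], pos - 1L))
    }
    starts[i] <- pos + hit - 2L            # 0-based
    ends[i] <- starts[i] + nchar(forms[i])
    pos <- ends[i] + 1L
  }
  data.frame(char_start = starts, char_end = ends)
}

#' Assemble candidate instances from a corpus and its parses
#'
#' Pairs every `<pair>` element with the sentence's dependency parse and
#' entity table. Token character offsets are recovered by greedy left-to-
#' right alignment of the parse's surface forms against the sentence text.
#' Within an instance `e1` is the mention with the smaller start offset.
#'
#' @param corpus a `ddi_corpus` from [read_ddi_corpus()].
#' @param parses named parse list from [read_conll_parses()].
#' @return list of `candidate_instance` objects: `doc_id`, `sentence_id`,
#'   `pair_id`, `label` (logical), `e1`, `e2` (rows of the entity table),
#'   `entities` (all sentence mentions), `tokens` (form/pos/char_start/
#'   char_end), `deps`, `root`.
#' @export
make_instances <- function(corpus, parses) {
  out <- list()
  for (s in corpus$sentences) {
    if (!nrow(s$pairs)) next
    p <- parses[[s$sentence_id]]
    if (is.null(p)) {
      stop(sprintf("sentence %s: no parse found", s$sentence_id))
    }
    offs <- align_tokens(s$text, p$tokens$form)
    tokens <- cbind(p$tokens, offs)
    for (i in seq_len(nrow(s$pairs))) {
      pr <- s$pairs[i, ]
      ents <- s$entities
      e1 <- ents[ents$id == pr$e1, ]
      e2 <- ents[ents$id == pr$e2, ]
      if (e2$char_start < e1$char_start) { tmp <- e1; e1 <- e2; e2 <- tmp }
      inst <- structure(list(
        doc_id = s$doc_id, sentence_id = s$sentence_id, pair_id = pr$id,
        label = pr$interaction, e1 = e1, e2 = e2, entities = ents,
        tokens = tokens, deps = p$deps, root = p$root
      ), class = "candidate_instance")
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}

# token indices (1-based) overlapping a 0-based half-open char span
tokens_in_span <- function(tokens, start, end) {
  which(tokens$char_start < end & tokens$char_end > start)
}

#' Entity blinding plan
#'
#' Replaces the candidate mentions with the placeholders DRUG1 and DRUG2 and
#' every other annotated drug mention in the sentence with DRUG, so the
#' classifier learns sentence structure rather than memorizing drug names.
#' A multi-token mention collapses to a single blinded token at the span's
#' dependency head (the span token whose head lies outside the span, if
#' resolvable; otherwise the first span token); the other span tokens are
#' dropped and dependencies re-attached to the anchor.
#'
#' @param instance a `candidate_instance` from [make_instances()].
#' @return a `blinding_plan`: list with per-token vectors `blind` (NA or
#'   "DRUG1"/"DRUG2"/"DRUG"), `keep` (logical), `anchor` (for every token,
#'   the index of the token it collapses into; identity if kept) and
#'   `warnings` (character).
#' @export
blind_entities <- function(instance) {
  tokens <- instance$tokens
  n <- nrow(tokens)
  blind <- rep(NA_character_, n)
  keep <- rep(TRUE, n)
  anchor <- seq_len(n)
  warnings <- character(0)

  spans <- list(list(e = instance$e1, tag = "DRUG1"),
                list(e = instance$e2, tag = "DRUG2"))
  other <- instance$entities[!instance$entities$id %in%
                               c(instance$e1$id, instance$e2$id), ,
                             drop = FALSE]
  for (i in seq_len(nrow(other))) {
    spans[[length(spans) + 1L]] <- list(e = other[i, ], tag = "DRUG")
  }

  for (sp in spans) {
    cov <- tokens_in_span(tokens, sp$e$char_start, sp$e$char_end)
    if (!length(cov)) {
      stop(sprintf("sentence %s: entity %s covers no token",
                   instance$sentence_id, sp$e$id))
    }
    exact <- any(tokens$char_start[cov] == sp$e$char_start) &&
      any(tokens$char_end[cov] == sp$e$char_end)
    if (!exact) {
      warnings <- c(warnings, sprintf(
        "entity %s span crosses token boundaries; aligned by maximal overlap",
        sp$e$id))
    }
    if (!is.na(blind[cov[1]]) && blind[cov[1]] != sp$tag) {
      # overlapping mentions: candidates take precedence over DRUG
      if (sp$tag == "DRUG") next
    }
    head_tok <- cov[1]
    if (length(cov) > 1L) {
      # dependency head of the span: token whose head is outside the span
      hd <- instance$deps
      ext <- cov[vapply(cov, function(t) {
        h <- hd$head[hd$dep == t]
        length(h) == 0L || !all(h %in% cov)
      }, logical(1))]
      if (length(ext) >= 1L) head_tok <- ext[1]
      drop <- setdiff(cov, head_tok)
      keep[drop] <- FALSE
      anchor[drop] <- head_tok
    }
    blind[head_tok] <- sp$tag
  }
  structure(list(blind = blind, keep = keep, anchor = anchor,
                 warnings = warnings),
            class = "blinding_plan")
}
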