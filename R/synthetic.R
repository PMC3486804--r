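#' Seeded random labeled graph
#'
#' Draws a directed vertex-labeled graph for property testing: `n` token
#' nodes in the dependency component, each ordered pair joined independently
#' with probability `edge_prob`, labels drawn uniformly from an alphabet of
#' `n_labels` symbols. With `two_component = TRUE` a linear chain over the
#' same token sequence is added, mirroring the sentence-graph layout.
#' Deterministic for a given seed.
#'
#' @param seed RNG seed.
#' @param n number of token nodes (>= 1).
#' @param edge_prob edge probability in `[0, 1]`.
#' @param n_labels label alphabet size.
#' @param two_component also generate the linear chain component.
#' @param w uniform edge weight.
#' @return a valid [sentence_graph()] (without candidate annotations).
#' @export
random_sentence_graph <- function(seed, n, edge_prob, n_labels = 5L,
                                  two_component = FALSE, w = 1.0) {
  stopifnot(n >= 1L, edge_prob >= 0, edge_prob <= 1)
  set.seed(seed)
  labs <- paste0("tok", sample.int(n_labels, n, replace = TRUE))
  nodes <- data.frame(
    id = seq_len(n), label = labs, kind = "token", component = "dependency",
    token_index = seq_len(n) - 1L, stringsAsFactors = FALSE
  )
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  # fixed iteration order so the draw is reproducible
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < edge_prob
  edges <- pairs[keep, , drop = FALSE]
  if (two_component) {
    lin <- data.frame(
      id = n + seq_len(n), label = labs, kind = "token",
      component = "linear", token_index = seq_len(n) - 1L,
      stringsAsFactors = FALSE
    )
    nodes <- rbind(nodes, lin)
    if (n > 1L) {
      edges <- rbind(edges,
                     data.frame(from = n + seq_len(n - 1L),
                                to = n + 1L + seq_len(n - 1L)))
    }
  }
  g <- sentence_graph(nodes, edges, w = w)
  stop_if_invalid(g)
  g
}

# ---- toy corpus ------------------------------------------------------------

# sentence frames: tokens with @D1@/@D2@/@D3@ drug slots and @V*@ verb
# slots, 1-based heads (0 = root), dependency relations. "distractor"
# frames carry a leading clause outside the candidate span that pruning
# removes.
toy_frames <- function() {
  f <- function(name, positive, distractor, tokens, pos, heads, rels,
                entities, pairs) {
    stopifnot(length(tokens) == length(pos),
              length(tokens) == length(heads),
              length(tokens) == length(rels))
    list(name = name, positive = positive, distractor = distractor,
         tokens = tokens, pos = pos, heads = heads, rels = rels,
         entities = entities, pairs = pairs)
  }
  list(
    f("P1", TRUE, FALSE,
      c("@D1@", "@Vz@", "@D2@", "."),
      c("nn", "vbz", "nn", "."),
      c(2L, 0L, 2L, 2L),
      c("nsubj", "root", "dobj", "punct"),
      entities = list(D1 = 1L, D2 = 3L),
      pairs = list(list(e = c("D1", "D2"), label = TRUE))),
    f("P2", TRUE, FALSE,
      c("@D1@", "may", "@Vb@", "the", "effect", "of", "@D2@", "."),
      c("nn", "md", "vb", "dt", "nn", "in", "nn", "."),
      c(3L, 3L, 0L, 5L, 3L, 5L, 6L, 3L),
      c("nsubj", "aux", "root", "det", "dobj", "prep", "pobj", "punct"),
      entities = list(D1 = 1L, D2 = 7L),
      pairs = list(list(e = c("D1", "D2"), label = TRUE))),
    f("P3", TRUE, TRUE,
      c("however", ",", "caution", "is", "required", ",", "because",
        "@D1@", "@Vz@", "@D2@", "."),
      c("rb", ",", "nn", "vbz", "vbn", ",", "in", "nn", "vbz", "nn", "."),
      c(5L, 5L, 5L, 5L, 0L, 5L, 9L, 9L, 5L, 9L, 5L),
      c("advmod", "punct", "nsubjpass", "auxpass", "root", "punct", "mark",
        "nsubj", "advcl", "dobj", "punct"),
      entities = list(D1 = 8L, D2 = 10L),
      pairs = list(list(e = c("D1", "D2"), label = TRUE))),
    f("P4", TRUE, FALSE,
      c("vitamin", "k", "@Vz@", "the", "absorption", "of", "@D2@", "."),
      c("nn", "nn", "vbz", "dt", "nn", "in", "nn", "."),
      c(2L, 3L, 0L, 5L, 3L, 5L, 6L, 3L),
      c("nn", "nsubj", "root", "det", "dobj", "prep", "pobj", "punct"),
      entities = list(D1 = c(1L, 2L), D2 = 7L),
      pairs = list(list(e = c("D1", "D2"), label = TRUE))),
    f("P5", TRUE, FALSE,
      c("@D1@", "levels", "are", "@Vn@", "by", "@D2@", "."),
      c("nn", "nns", "vbp", "vbn", "in", "nn", "."),
      c(2L, 4L, 4L, 0L, 4L, 5L, 4L),
      c("nn", "nsubjpass", "auxpass", "root", "prep", "pobj", "punct"),
      entities = list(D1 = 1L, D2 = 6L),
      pairs = list(list(e = c("D1", "D2"), label = TRUE))),
    f("N1", FALSE, FALSE,
      c("@D1@", "and", "@D2@", "were", "administered", "."),
      c("nn", "cc", "nn", "vbd", "vbn", "."),
      c(5L, 1L, 1L, 5L, 0L, 5L),
      c("nsubjpass", "cc", "conj", "auxpass", "root", "punct"),
      entities = list(D1 = 1L, D2 = 3L),
      pairs = list(list(e = c("D1", "D2"), label = FALSE))),
    f("N2", FALSE, FALSE,
      c("patients", "received", "@D1@", "and", "@D2@", "."),
      c("nns", "vbd", "nn", "cc", "nn", "."),
      c(2L, 0L, 2L, 3L, 3L, 2L),
      c("nsubj", "root", "dobj", "cc", "conj", "punct"),
      entities = list(D1 = 3L, D2 = 5L),
      pairs = list(list(e = c("D1", "D2"), label = FALSE))),
    f("N3", FALSE, TRUE,
      c("however", ",", "caution", "is", "required", ",", "because",
        "patients", "received", "@D1@", "and", "@D2@", "."),
      c("rb", ",", "nn", "vbz", "vbn", ",", "in", "nns", "vbd", "nn",
        "cc", "nn", "."),
      c(5L, 5L, 5L, 5L, 0L, 5L, 9L, 9L, 5L, 9L, 10L, 10L, 5L),
      c("advmod", "punct", "nsubjpass", "auxpass", "root", "punct", "mark",
        "nsubj", "advcl", "dobj", "cc", "conj", "punct"),
      entities = list(D1 = 10L, D2 = 12L),
      pairs = list(list(e = c("D1", "D2"), label = FALSE))),
    f("N4", FALSE, FALSE,
      c("no", "interaction", "between", "@D1@", "and", "@D2@", "was",
        "observed", "."),
      c("dt", "nn", "in", "nn", "cc", "nn", "vbd", "vbn", "."),
      c(2L, 8L, 2L, 3L, 4L, 4L, 8L, 0L, 8L),
      c("det", "nsubjpass", "prep", "pobj", "cc", "conj", "auxpass",
        "root", "punct"),
      entities = list(D1 = 4L, D2 = 6L),
      pairs = list(list(e = c("D1", "D2"), label = FALSE))),
    f("N5", FALSE, FALSE,
      c("vitamin", "k", "and", "@D2@", "were", "administered", "."),
      c("nn", "nn", "cc", "nn", "vbd", "vbn", "."),
      c(2L, 6L, 2L, 2L, 6L, 0L, 6L),
      c("nn", "nsubjpass", "cc", "conj", "auxpass", "root", "punct"),
      entities = list(D1 = c(1L, 2L), D2 = 4L),
      pairs = list(list(e = c("D1", "D2"), label = FALSE))),
    f("T3", TRUE, FALSE,
      c("@D1@", "@Vz@", "@D2@", ";", "@D3@", "was", "administered",
        "separately", "."),
      c("nn", "vbz", "nn", ",", "nn", "vbd", "vbn", "rb", "."),
      c(2L, 0L, 2L, 2L, 7L, 7L, 2L, 7L, 2L),
      c("nsubj", "root", "dobj", "punct", "nsubjpass", "auxpass",
        "parataxis", "advmod", "punct"),
      entities = list(D1 = 1L, D2 = 3L, D3 = 5L),
      pairs = list(list(e = c("D1", "D2"), label = TRUE),
                   list(e = c("D1", "D3"), label = FALSE),
                   list(e = c("D2", "D3"), label = FALSE)))
  )
}

toy_drugs <- c("warfarin", "digoxin", "phenytoin", "cimetidine", "rifampin",
               "ketoconazole", "theophylline", "erythromycin", "quinidine",
               "amiodarone", "lithium", "methotrexate")
toy_verbs_z <- c("inhibits", "potentiates", "increases", "decreases",
                 "enhances")
toy_verbs_b <- c("inhibit", "potentiate", "increase", "decrease", "enhance")
toy_verbs_n <- c("inhibited", "potentiated", "increased", "decreased",
                 "enhanced")

# instantiate one frame: substitute drug names / trigger verbs into slots
instantiate_frame <- function(frame, drugs, vz, vb, vn) {
  tokens <- frame$tokens
  slot_drug <- c(D1 = drugs[1], D2 = drugs[2], D3 = drugs[3])
  for (slot in names(frame$entities)) {
    idx <- frame$entities[[slot]]
    if (length(idx) == 1L && grepl("^@D", tokens[idx])) {
      tokens[idx] <- slot_drug[[slot]]
    }
    # multi-token slots ("vitamin k") keep their literal tokens
  }
  tokens[tokens == "@Vz@"] <- vz
  tokens[tokens == "@Vb@"] <- vb
  tokens[tokens == "@Vn@"] <- vn
  tokens
}

#' Generate a planted-signal toy corpus on disk
#'
#' Builds a seeded corpus in the XML and CoNLL-style dialects read by
#' [read_ddi_corpus()] and [read_conll_parses()]. Sentences are drawn from
#' ~11 template frames: in positive frames an interaction trigger verb
#' (inhibits, potentiates, ...) governs the candidate pair on its dependency
#' path; negative frames express co-administration or explicit
#' non-interaction without a trigger on the path. Two frames carry a
#' distractor leading clause ("however, caution is required, ...") attached
#' outside the candidate span, which pruning removes; one frame has three
#' entities (three candidate pairs, one positive); two frames use the
#' multi-token mention "vitamin k". Sentences are grouped five per document
#' for document-level cross-validation. Regeneration with the same arguments
#' is byte-identical.
#'
#' @param seed RNG seed.
#' @param n number of candidate-pair instances to generate (>= 1).
#' @param positive_rate expected fraction of positive instances.
#' @param dir output directory (created if missing).
#' @return list: `xml` and `conll` file paths, `n_instances`, and `meta`
#'   (data.frame sentence_id, frame, distractor).
#' @export
toy_corpus <- function(seed, n = 200L, positive_rate = 0.3, dir = tempdir()) {
  stopifnot(n >= 1L, positive_rate >= 0, positive_rate <= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames <- toy_frames()
  pos_frames <- frames[vapply(frames, function(f)
    f$positive && f$name != "T3", logical(1))]
  neg_frames <- frames[vapply(frames, function(f) !f$positive, logical(1))]
  t3 <- frames[[which(vapply(frames, function(f) f$name == "T3",
                             logical(1)))]]
  # T3 contributes 1 positive of 3 pairs; solve the 2-entity positive-frame
  # probability so the expected overall positive rate hits the target
  p_t3 <- if (positive_rate > 0) 0.12 else 0
  p_pos <- if (p_t3 > 0) {
    min(1, max(0, (positive_rate * (3 * p_t3 + (1 - p_t3)) - p_t3) /
                 (1 - p_t3)))
  } else positive_rate

  set.seed(seed)
  sentences <- list()
  meta <- list()
  total <- 0L
  s_idx <- 0L
  while (total < n) {
    s_idx <- s_idx + 1L
    remaining <- n - total
    use_t3 <- positive_rate > 0 && remaining >= 3L &&
      stats::runif(1) < p_t3
    frame <- if (use_t3) {
      t3
    } else if (stats::runif(1) < p_pos) {
      pos_frames[[sample.int(length(pos_frames), 1L)]]
    } else {
      neg_frames[[sample.int(length(neg_frames), 1L)]]
    }
    drugs <- sample(toy_drugs, 3L)
    tokens <- instantiate_frame(frame, drugs,
                                vz = sample(toy_verbs_z, 1L),
                                vb = sample(toy_verbs_b, 1L),
                                vn = sample(toy_verbs_n, 1L))
    text <- paste(tokens, collapse = " ")
    starts <- cumsum(c(0L, nchar(tokens[-length(tokens)]) + 1L))
    ends <- starts + nchar(tokens)
    doc_id <- sprintf("d%03d", (s_idx - 1L) %/% 5L + 1L)
    sid <- sprintf("%s.s%d.%s", doc_id, s_idx, frame$name)
    ents <- data.frame(id = character(0), char_start = integer(0),
                       char_end = integer(0), text = character(0),
                       stringsAsFactors = FALSE)
    for (slot in names(frame$entities)) {
      idx <- frame$entities[[slot]]
      cs <- starts[min(idx)]
      ce <- ends[max(idx)]
      ents <- rbind(ents, data.frame(
        id = paste0(sid, ".", tolower(slot)),
        char_start = cs, char_end = ce,
        text = substring(text, cs + 1L, ce), stringsAsFactors = FALSE))
    }
    prs <- data.frame(id = character(0), e1 = character(0),
                      e2 = character(0), interaction = logical(0),
                      stringsAsFactors = FALSE)
    for (pi in seq_along(frame$pairs)) {
      pr <- frame$pairs[[pi]]
      prs <- rbind(prs, data.frame(
        id = paste0(sid, ".p", pi),
        e1 = paste0(sid, ".", tolower(pr$e[1])),
        e2 = paste0(sid, ".", tolower(pr$e[2])),
        interaction = pr$label, stringsAsFactors = FALSE))
    }
    sentences[[length(sentences) + 1L]] <- list(
      doc_id = doc_id, sentence_id = sid, text = text,
      entities = ents, pairs = prs,
      tokens = tokens, pos = frame$pos, heads = frame$heads,
      rels = frame$rels
    )
    meta[[length(meta) + 1L]] <- data.frame(
      sentence_id = sid, frame = frame$name,
      distractor = frame$distractor, stringsAsFactors = FALSE)
    total <- total + nrow(prs)
  }

  corpus <- structure(list(sentences = lapply(sentences, function(s) {
    s[c("doc_id", "sentence_id", "text", "entities", "pairs")]
  })), class = "ddi_corpus")
  xml_path <- file.path(dir, "corpus.xml")
  write_ddi_corpus(corpus, xml_path)

  conll_path <- file.path(dir, "parses.conll")
  lines <- character(0)
  for (s in sentences) {
    lines <- c(lines, paste0("# ", s$sentence_id))
    lines <- c(lines, sprintf("%d\t%s\t%s\t%d\t%s",
                              seq_along(s$tokens), s$tokens, s$pos,
                              s$heads, s$rels))
    lines <- c(lines, "")
  }
  writeLines(lines, conll_path)

  list(xml = xml_path, conll = conll_path, n_instances = total,
       meta = do.call(rbind, meta))
}
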