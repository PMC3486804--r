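# inline corpus fixture: 1 sentence, 3 entities, 3 pairs (1 positive)
h_fixture_xml <- function(path,
                          text = "aspirin increases warfarin and digoxin",
                          drop_entity = FALSE, break_offset = FALSE) {
  ents <- c(
    '<entity id="s1.e1" charOffset="0-6" text="aspirin"/>',
    '<entity id="s1.e2" charOffset="18-25" text="warfarin"/>',
    '<entity id="s1.e3" charOffset="31-37" text="digoxin"/>'
  )
  if (break_offset) {
    ents[1] <- '<entity id="s1.e1" charOffset="0-6" text="aspirim"/>'
  }
  if (drop_entity) ents <- ents[-3]
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<corpus>",
    '<document id="d1">',
    sprintf('<sentence id="s1" text="%s">', text),
    ents,
    '<pair id="s1.p1" e1="s1.e1" e2="s1.e2" interaction="true"/>',
    '<pair id="s1.p2" e1="s1.e1" e2="s1.e3" interaction="false"/>',
    '<pair id="s1.p3" e1="s1.e2" e2="s1.e3" interaction="false"/>',
    "</sentence>", "</document>", "</corpus>"
  ), path)
  path
}

test_that("read_ddi_corpus parses pairs, labels and offsets", {
  path <- h_fixture_xml(withr::local_tempfile(fileext = ".xml"))
  corpus <- read_ddi_corpus(path)
  expect_length(corpus$sentences, 1L)
  s <- corpus$sentences[[1]]
  expect_equal(nrow(s$entities), 3L)
  expect_equal(nrow(s$pairs), 3L)
  expect_equal(sum(s$pairs$interaction), 1L)
  # inclusive corpus offsets become 0-based half-open
  expect_equal(s$entities$char_start[1], 0L)
  expect_equal(s$entities$char_end[1], 7L)
  expect_identical(substring(s$text, 1, 7), "aspirin")
})

test_that("corpus reader raises distinct, named errors", {
  dangling <- h_fixture_xml(withr::local_tempfile(fileext = ".xml"),
                            drop_entity = TRUE)
  expect_error(read_ddi_corpus(dangling), "s1.*unknown entity")
  mismatch <- h_fixture_xml(withr::local_tempfile(fileext = ".xml"),
                            break_offset = TRUE)
  expect_error(read_ddi_corpus(mismatch), "s1.*does not match span")
  malformed <- withr::local_tempfile(fileext = ".xml")
  writeLines("<corpus><document>", malformed)
  expect_error(read_ddi_corpus(malformed))
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines("<corpus></corpus>", empty)
  expect_length(read_ddi_corpus(empty)$sentences, 0L)
})

test_that("corpus round-trips through write_ddi_corpus", {
  path <- h_fixture_xml(withr::local_tempfile(fileext = ".xml"))
  corpus <- read_ddi_corpus(path)
  out <- withr::local_tempfile(fileext = ".xml")
  write_ddi_corpus(corpus, out)
  again <- read_ddi_corpus(out)
  expect_equal(again$sentences, corpus$sentences)
})

test_that("read_conll_parses handles roots, cycles and bad input", {
  path <- withr::local_tempfile(fileext = ".conll")
  writeLines(c(
    "# s1",
    "1\tA\tnn\t2\tnsubj",
    "2\tB\tvbz\t0\troot",
    "",
    "# s2",
    "1\tx\tnn\t2\tdep",
    "2\ty\tnn\t1\tdep"
  ), path)
  parses <- read_conll_parses(path)
  expect_named(parses, c("s1", "s2"))
  # root attachment is metadata, not a dependency edge
  expect_equal(nrow(parses$s1$deps), 1L)
  expect_equal(parses$s1$deps$head, 2L)
  expect_equal(parses$s1$deps$dep, 1L)
  expect_equal(parses$s1$root, 2L)
  # cyclic head assignment accepted verbatim
  expect_equal(nrow(parses$s2$deps), 2L)

  bad1 <- withr::local_tempfile()
  writeLines(c("# s1", "1\tA\tnn\t2\tnsubj", "3\tB\tvbz\t0\troot"), bad1)
  expect_error(read_conll_parses(bad1), "not contiguous")
  bad2 <- withr::local_tempfile()
  writeLines(c("# s1", "1\tA\tnn\t5\tnsubj"), bad2)
  expect_error(read_conll_parses(bad2), "out of range")
})

test_that("blinding maps candidates, bystander drugs and multi-token spans", {
  inst <- h_instance(
    tokens = c("aspirin", "inhibits", "warfarin", "and", "digoxin"),
    pos = c("nn", "vbz", "nn", "cc", "nn"),
    heads = c(2L, 0L, 2L, 3L, 3L),
    rels = c("nsubj", "root", "dobj", "cc", "conj"),
    e1_tokens = 1L, e2_tokens = 3L, other_entities = list(5L)
  )
  plan <- blind_entities(inst)
  expect_equal(plan$blind, c("DRUG1", NA, "DRUG2", NA, "DRUG"))
  expect_true(all(plan$keep))
  expect_length(plan$warnings, 0L)
})

test_that("multi-token mention collapses to its dependency head and keeps
           external dependencies", {
  inst <- h_instance(
    tokens = c("vitamin", "k", "inhibits", "warfarin", "."),
    pos = c("nn", "nn", "vbz", "nn", "."),
    heads = c(2L, 3L, 0L, 3L, 3L),
    rels = c("nn", "nsubj", "root", "dobj", "punct"),
    e1_tokens = c(1L, 2L), e2_tokens = 4L
  )
  plan <- blind_entities(inst)
  # head of the span is token 2 ("k"): its head (3) lies outside the span
  expect_equal(plan$keep, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(plan$blind[2], "DRUG1")
  expect_equal(plan$anchor[1], 2L)

  g <- build_sentence_graph(inst, plan)
  dep_tokens <- g$nodes[g$nodes$kind == "token" &
                          g$nodes$component == "dependency", ]
  expect_setequal(dep_tokens$label,
                  c("DRUG1", "inhibits/vbz", "DRUG2", "./."))
  # enumeration: every external dependency of the original span survives,
  # re-attached to the collapsed DRUG1 node; the internal "nn" is gone
  rels <- g$nodes$label[g$nodes$kind == "dependency_relation"]
  expect_setequal(rels, c("nsubj", "dobj", "punct"))
  rel_id <- g$nodes$id[g$nodes$label == "nsubj"]
  d1 <- intersect(g$drug1, g$nodes$id[g$nodes$component == "dependency"])
  expect_equal(g$edges$to[g$edges$from == rel_id], d1)
})

test_that("span crossing token boundaries aligns by overlap with a warning", {
  inst <- h_instance(
    tokens = c("cowarfarin", "helps", "digoxin"),
    pos = c("nn", "vbz", "nn"),
    heads = c(2L, 0L, 2L),
    rels = c("nsubj", "root", "dobj"),
    e1_tokens = 1L, e2_tokens = 3L
  )
  # shift e1 to cover only part of the first token
  inst$e1$char_start <- 2L
  inst$entities$char_start[1] <- 2L
  inst$e1$text <- "warfarin"
  inst$entities$text[1] <- "warfarin"
  plan <- blind_entities(inst)
  expect_equal(plan$blind[1], "DRUG1")
  expect_true(any(grepl("maximal overlap", plan$warnings)))
})

test_that("make_instances yields one instance per pair, e1 before e2", {
  path <- h_fixture_xml(withr::local_tempfile(fileext = ".xml"))
  corpus <- read_ddi_corpus(path)
  conll <- withr::local_tempfile(fileext = ".conll")
  writeLines(c(
    "# s1",
    "1\taspirin\tnn\t2\tnsubj",
    "2\tincreases\tvbz\t0\troot",
    "3\twarfarin\tnn\t2\tdobj",
    "4\tand\tcc\t3\tcc",
    "5\tdigoxin\tnn\t3\tconj"
  ), conll)
  parses <- read_conll_parses(conll)
  inst <- make_instances(corpus, parses)
  expect_length(inst, 3L)
  expect_equal(vapply(inst, function(x) x$label, NA),
               c(TRUE, FALSE, FALSE))
  for (x in inst) expect_lt(x$e1$char_start, x$e2$char_start)
})
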