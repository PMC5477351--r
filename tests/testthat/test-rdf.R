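vocab <- rfm_vocabulary()

test_that("minimal ontology emits exactly the contracted triples", {
  o <- disease_ontology(
    states = list(abnormal_state("s1", "state one", level = 1)),
    diseases = list(disease("d1", "disease one", core_states = "s1")))
  tr <- to_rdf(o, vocab)
  expect_identical(nrow(tr), 5L)  # 2 types + 2 labels + 1 hasCoreState
  expect_identical(sum(tr$predicate == riverflow:::RDF_TYPE), 2L)
  expect_identical(sum(tr$predicate == riverflow:::RDFS_LABEL), 2L)
  expect_identical(sum(tr$predicate == vocab$terms$hasCoreState), 1L)

  expect_identical(nrow(to_rdf(disease_ontology(), vocab)), 0L)
})

test_that("every hasCause triple has its hasResult mirror", {
  for (o in list(fixture_diabetes(),
                 generate_ontology(generator_config(n_diseases = 8,
                                                    seed = 2))$ontology)) {
    tr <- to_rdf(o, vocab)
    for (pair in list(c("hasCause", "hasResult"),
                      c("hasProbableCause", "hasProbableResult"))) {
      a <- tr[tr$predicate == vocab$terms[[pair[1]]], ]
      b <- tr[tr$predicate == vocab$terms[[pair[2]]], ]
      expect_setequal(paste(a$subject, a$object), paste(b$object, b$subject))
    }
  }
})

test_that("to_rdf refuses invalid ontologies with the report attached", {
  bad <- disease_ontology(
    diseases = list(disease("d", core_states = "ghost")))
  err <- tryCatch(to_rdf(bad, vocab), error = identity)
  expect_s3_class(err, "riverflow_validation_error")
  expect_s3_class(err$report, "rf_validation")
  expect_true(nrow(err$report) >= 1L)
})

test_that("round-trip is the identity and serialization is byte-stable", {
  fixtures <- list(fixture_diabetes(), fixture_stenosis_hierarchy())
  for (o in fixtures) {
    text1 <- write_turtle(to_rdf(o, vocab), NULL, vocab)
    text2 <- write_turtle(to_rdf(o, vocab), NULL, vocab)
    expect_identical(text1, text2)
    expect_true(ontology_equal(o, from_rdf(read_turtle(text1), vocab)))
  }
  for (seed in 1:5) {
    g <- generate_ontology(generator_config(n_diseases = 6, seed = seed))
    o <- g$ontology
    back <- from_rdf(read_turtle(write_turtle(to_rdf(o, vocab), NULL, vocab)),
                     vocab)
    expect_true(ontology_equal(o, back))
    expect_identical(nrow(attr(back, "findings")), 0L)
  }
})

test_that("round-trip works under the flipped cause-direction convention", {
  v2 <- rfm_vocabulary(cause_direction = "cause_to_effect")
  o <- fixture_diabetes()
  back <- from_rdf(read_turtle(write_turtle(to_rdf(o, v2), NULL, v2)), v2)
  expect_true(ontology_equal(o, back))
})

test_that("a single inverse member reconstructs the full link", {
  iri <- function(x) paste0(vocab$ns, x)
  tr <- riverflow:::triples_df(
    subject = c(iri("a"), iri("b"), iri("b")),
    predicate = c(riverflow:::RDF_TYPE, riverflow:::RDF_TYPE,
                  vocab$terms$hasCause),
    object = c(vocab$terms$Abnormal_State, vocab$terms$Abnormal_State,
               iri("a")),
    object_type = "iri")
  o <- from_rdf(tr, vocab)  # (b hasCause a) means a -> b
  expect_identical(o$links$cause, "a")
  expect_identical(o$links$effect, "b")
  both <- to_rdf(o, vocab)
  expect_true(vocab$terms$hasResult %in% both$predicate)
})

test_that("format errors and dangling arcs are reported", {
  iri <- function(x) paste0(vocab$ns, x)
  both_types <- riverflow:::triples_df(
    subject = c(iri("x"), iri("x")),
    predicate = riverflow:::RDF_TYPE,
    object = c(vocab$terms$Disease, vocab$terms$Abnormal_State),
    object_type = "iri")
  expect_error(from_rdf(both_types, vocab), class = "riverflow_format_error")

  dangling <- riverflow:::triples_df(
    subject = c(iri("s1"), iri("dX")),
    predicate = c(riverflow:::RDF_TYPE, vocab$terms$hasCoreState),
    object = c(vocab$terms$Abnormal_State, iri("s1")),
    object_type = "iri")
  o <- from_rdf(dangling, vocab)
  f <- attr(o, "findings")
  expect_true(any(f$type == "dangling_reference" & f$entity == "dX"))
})

test_that("unknown predicates survive the round trip in the side channel", {
  o <- fixture_diabetes()
  text <- write_turtle(to_rdf(o, vocab), NULL, vocab)
  extra <- paste0("<", vocab$ns, "diabetes> <http://example.org/seeAlso> ",
                  "\"kept\" .")
  o2 <- from_rdf(read_turtle(paste0(text, extra, "\n")), vocab)
  expect_true(ontology_equal(o, o2))
  side <- attr(o2, "extra_triples")
  expect_identical(side$predicate, "http://example.org/seeAlso")
  re <- to_rdf(o2, vocab)
  expect_true("http://example.org/seeAlso" %in% re$predicate)
})

test_that("AND-branch annotations serialize through the extension namespace", {
  o <- fixture_diabetes()
  attr(o, "branch_mode") <- c(deficiency_of_insulin = "AND")
  tr <- to_rdf(o, vocab)
  expect_true(vocab$ext_terms$andBranch %in% tr$predicate)
  o2 <- from_rdf(read_turtle(write_turtle(tr, NULL, vocab)), vocab)
  expect_identical(attr(o2, "branch_mode"),
                   c(deficiency_of_insulin = "AND"))
})

test_that("turtle reader handles continuations, comments and escapes", {
  txt <- paste0('@prefix ex: <http://e/> .\n',
                '# a comment line\n',
                'ex:a ex:p ex:b ; ex:q "li\\"t\\\\x"@en , "y" . # trailing\n',
                '<http://e/z> a ex:T .\n')
  tr <- read_turtle(txt)
  expect_identical(nrow(tr), 4L)
  expect_setequal(tr$object[tr$predicate == "http://e/q"], c('li"t\\x', "y"))
  expect_identical(tr$predicate[tr$subject == "http://e/z"],
                   riverflow:::RDF_TYPE)
})
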