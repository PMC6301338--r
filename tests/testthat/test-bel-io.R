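test_that("statements inherit citation, evidence and annotation context", {
  doc <- parse_bel_document(rb1_e2f4_text)
  expect_s3_class(doc, "bel_document")
  expect_equal(nrow(doc$statements), 2L)
  expect_equal(sum(doc$issues$severity == "error"), 0L)
  expect_equal(doc$statements$citation_db, c("PubMed", "PubMed"))
  expect_equal(doc$statements$citation_ref, c("1", "1"))
  expect_equal(doc$statements$evidence, c("e", "e"))
  expect_true(all(doc$statements$object_activity))
  expect_false(any(doc$statements$subject_activity))
  expect_equal(node_id(doc$statements$object[[1]]), "p(HGNC:E2F4)")
})

test_that("SET and UNSET manage statement context", {
  txt <- paste(
    'DEFINE NAMESPACE NS AS LIST {"A", "B"}',
    'DEFINE ANNOTATION Tissue AS LIST {"cortex", "plasma"}',
    'SET Citation = {"PubMed", "ref", "11"}',
    'SET Evidence = "first"',
    'SET Tissue = {"cortex", "plasma"}',
    "p(NS:A) increases p(NS:B)",
    "UNSET Tissue",
    'SET Evidence = "second"',
    "p(NS:B) decreases p(NS:A)",
    "UNSET ALL",
    "p(NS:A) association p(NS:B)",
    sep = "\n"
  )
  doc <- parse_bel_document(txt)
  expect_equal(nrow(doc$statements), 2L)
  expect_equal(doc$statements$annotations[[1]]$Tissue, c("cortex", "plasma"))
  expect_length(doc$statements$annotations[[2]], 0L)
  expect_equal(doc$statements$evidence, c("first", "second"))
  # after UNSET ALL the citation is gone, so the last line is rejected
  missing <- doc$issues[doc$issues$code == "MISSING_CITATION", ]
  expect_equal(missing$line_number, 11L)
})

test_that("empty input yields an empty document with no issues", {
  doc <- parse_bel_document("")
  expect_equal(nrow(doc$statements), 0L)
  expect_equal(nrow(doc$issues), 0L)
  expect_equal(nrow(compile_network(doc)$nodes), 0L)
})

test_that("malformed lines are flagged with their line numbers, one issue each", {
  bad_lines <- c(
    "p(HGNC:RB1) increases E2F4",          # bare token object
    "p(HGNC:RB1) frobnicates p(HGNC:E2F4)", # unknown relation
    "q(HGNC:RB1) increases p(HGNC:E2F4)",  # unknown function
    "p(HGNC:RB1 increases p(HGNC:E2F4)",   # unbalanced parens
    "p(HGNC:RB1) increases p(E2F4)",       # namespace-less argument
    "p(HGNC:RB1) increases act(act(p(HGNC:E2F4)))", # nested modifiers
    "p(HGNC:RB1) increases p(HGNC:E2F4) trailing",  # trailing content
    'p(HGNC:"RB1) increases p(HGNC:E2F4)', # unterminated quote
    "RB1 increases E2F4",                  # naked subject
    "p(HGNC:RB1) increases complex(p(HGNC:A), p(HGNC:B))" # nested members
  )
  txt <- paste(c(
    'DEFINE NAMESPACE HGNC AS LIST {"RB1", "E2F4", "A", "B"}',
    'SET Citation = {"PubMed", "x", "1"}',
    bad_lines
  ), collapse = "\n")
  doc <- parse_bel_document(txt)
  expect_equal(nrow(doc$statements), 0L)
  expect_equal(nrow(doc$issues), length(bad_lines))
  expect_true(all(doc$issues$category == "syntactic"))
  expect_equal(doc$issues$line_number, 2L + seq_along(bad_lines))
  # every issue quotes its own input line at a valid column
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(doc$issues$line_text, lines[doc$issues$line_number])
  expect_true(all(doc$issues$position >= 1L))
  expect_true(all(doc$issues$position <= nchar(doc$issues$line_text) + 1L))
})

test_that("semantic validation flags undefined and out-of-namespace names", {
  txt <- paste(
    'DEFINE NAMESPACE HGNC AS LIST {"RB1"}',
    'SET Citation = {"PubMed", "x", "1"}',
    "p(HGNC:RB1) increases p(HGNC:NOTINNS)",
    "p(MISSING:RB1) increases p(HGNC:RB1)",
    'SET Undeclared = "v"',
    sep = "\n"
  )
  doc <- parse_bel_document(txt)
  expect_equal(nrow(doc$statements), 0L)
  expect_setequal(doc$issues$code,
                  c("NAME_NOT_IN_NAMESPACE", "UNDEFINED_NAMESPACE",
                    "UNDEFINED_ANNOTATION"))
  expect_true(all(doc$issues$category == "semantic"))
  expect_equal(doc$issues$token[doc$issues$code == "NAME_NOT_IN_NAMESPACE"],
               "NOTINNS")
})

test_that("URL namespaces resolve through resources or stay unresolved with a warning", {
  txt <- paste(
    'DEFINE NAMESPACE HGNC AS URL "http://example.org/hgnc.belns"',
    'SET Citation = {"PubMed", "x", "1"}',
    "p(HGNC:ANYNAME) increases p(HGNC:OTHER)",
    sep = "\n"
  )
  unresolved <- parse_bel_document(txt)
  expect_equal(nrow(unresolved$statements), 1L)
  expect_equal(unresolved$issues$code, "UNRESOLVED_NAMESPACE")
  expect_equal(unresolved$issues$severity, "warning")

  resolved <- parse_bel_document(txt, resources = list(HGNC = c("ANYNAME")))
  expect_equal(nrow(resolved$statements), 0L)
  expect_true("NAME_NOT_IN_NAMESPACE" %in% resolved$issues$code)
})

test_that("namespace term files are read one term per line with comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "RB1", "", "  E2F4  "), path)
  expect_equal(read_namespace_file(path), c("RB1", "E2F4"))
  txt <- paste(
    sprintf('DEFINE NAMESPACE HGNC AS URL "%s"', path),
    'SET Citation = {"PubMed", "x", "1"}',
    "p(HGNC:RB1) increases p(HGNC:E2F4)",
    sep = "\n"
  )
  doc <- parse_bel_document(txt)
  expect_equal(nrow(doc$statements), 1L)
  expect_equal(nrow(doc$issues), 0L)
})

test_that("parser is total on fuzzed input", {
  fuzz_chars <- c(letters, LETTERS, 0:9, " ", "\t", "(", ")", "{", "}",
                  '"', "\\", ",", ":", "#", "=", "-", ">", "|", "\n", ".")
  withr::with_seed(42, {
    for (i in 1:60) {
      txt <- paste(sample(fuzz_chars, sample(0:300, 1), replace = TRUE),
                   collapse = "")
      doc <- parse_bel_document(txt)
      expect_s3_class(doc, "bel_document")
    }
  })
})

test_that("recurring issues group by code and token with descending counts", {
  expect_equal(nrow(group_recurring_issues(parse_bel_document("")$issues)), 0L)

  txt <- paste(
    'SET Citation = {"PubMed", "x", "1"}',
    "NAKED increases NAKED",
    "p(X:A) increases p(X:B)",
    "NAKED increases NAKED",
    sep = "\n"
  )
  doc <- parse_bel_document(txt)
  groups <- group_recurring_issues(doc$issues)
  expect_equal(sum(groups$count), nrow(doc$issues))
  expect_equal(groups$count, sort(groups$count, decreasing = TRUE))
  naked <- groups[groups$code == "NAKED_NAME", ]
  expect_equal(naked$count, 2L)
  expect_equal(naked$line_numbers[[1]], c(2L, 4L))

  # 100 random issues over 5 codes match a plain tally
  withr::with_seed(7, {
    codes <- sample(c("A", "B", "C", "D", "E"), 100, replace = TRUE)
    issues <- tibble::tibble(
      severity = "error", category = "syntactic", code = codes,
      line_number = seq_along(codes), position = 1L,
      line_text = paste("line", seq_along(codes)), token = ""
    )
  })
  groups <- group_recurring_issues(issues)
  tallied <- table(codes)
  expect_equal(sum(groups$count), 100L)
  expect_equal(setNames(groups$count, groups$code)[names(tallied)],
               setNames(as.integer(tallied), names(tallied)))
})

test_that("serialization round-trips the statement multiset", {
  doc <- parse_bel_document(rb1_e2f4_text)
  redoc <- parse_bel_document(serialize_bel(doc))
  expect_equal(sum(redoc$issues$severity == "error"), 0L)
  expect_setequal(belkit:::statement_fingerprints(redoc$statements),
                  belkit:::statement_fingerprints(doc$statements))
  # single relational line per statement
  expect_equal(
    sum(grepl(" increases | decreases ", strsplit(serialize_bel(doc), "\n")[[1]])),
    2L
  )
})

test_that("annotation SET lines are emitted in lexicographic key order", {
  txt <- paste(
    'DEFINE NAMESPACE NS AS LIST {"A", "B"}',
    'DEFINE ANNOTATION Zeta AS LIST {"z"}',
    'DEFINE ANNOTATION Alpha AS LIST {"a"}',
    'SET Citation = {"PubMed", "x", "1"}',
    'SET Zeta = "z"',
    'SET Alpha = "a"',
    "p(NS:A) increases p(NS:B)",
    sep = "\n"
  )
  out <- strsplit(serialize_bel(parse_bel_document(txt)), "\n")[[1]]
  set_lines <- grep("^SET (Alpha|Zeta)", out, value = TRUE)
  expect_equal(set_lines, c('SET Alpha = "a"', 'SET Zeta = "z"'))
})

test_that("documents with error-severity issues refuse to serialize", {
  doc <- parse_bel_document("p(HGNC:RB1) increases p(HGNC:E2F4)")
  expect_gt(sum(doc$issues$severity == "error"), 0)
  expect_error(serialize_bel(doc), "error-severity")
})

test_that("quoted names with spaces survive a round trip", {
  txt <- paste(
    'DEFINE NAMESPACE GOBP AS LIST {"response to stress"}',
    'DEFINE NAMESPACE HGNC AS LIST {"RB1"}',
    'SET Citation = {"PubMed", "x", "1"}',
    'p(HGNC:RB1) increases bp(GOBP:"response to stress")',
    sep = "\n"
  )
  doc <- parse_bel_document(txt)
  expect_equal(nrow(doc$statements), 1L)
  expect_equal(doc$statements$object[[1]]$name, "response to stress")
  redoc <- parse_bel_document(serialize_bel(doc))
  expect_setequal(belkit:::statement_fingerprints(redoc$statements),
                  belkit:::statement_fingerprints(doc$statements))
})
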