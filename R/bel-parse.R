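# Line-oriented BEL 1.0-style parser.
#
# The parser is total: any byte string yields a bel_document in which
# every line is either consumed (metadata, definitions, statements) or
# produces at least one ParseIssue carrying the verbatim line, its
# 1-based line number and a 1-based column position. Problems never
# raise; they are collected and categorized as syntactic or semantic.

ISSUE_CODES <- c(
  "MALFORMED_STATEMENT", "MALFORMED_DIRECTIVE", "NAKED_NAME",
  "UNDEFINED_NAMESPACE", "NAME_NOT_IN_NAMESPACE", "UNDEFINED_ANNOTATION",
  "INVALID_ANNOTATION_VALUE", "MISSING_CITATION", "INVALID_CITATION",
  "UNRESOLVED_NAMESPACE", "UNRESOLVED_ANNOTATION", "DUPLICATE_DEFINITION"
)

empty_issues <- function() {
  tibble(
    severity = character(), category = character(), code = character(),
    line_number = integer(), position = integer(),
    line_text = character(), token = character()
  )
}

empty_statements <- function() {
  tibble(
    line_number = integer(), subject = list(), relation = character(),
    object = list(), subject_activity = logical(), object_activity = logical(),
    citation_db = character(), citation_name = character(),
    citation_ref = character(), citation_date = character(),
    citation_authors = list(), evidence = character(), annotations = list()
  )
}

# --- low-level scanning helpers ---------------------------------------

bel_parse_error <- function(code, message, pos, token = "") {
  errorCondition(message, code = code, pos = pos,
                 token = if (is.null(token) || length(token) == 0) "" else token,
                 class = "bel_parse_error")
}

new_scanner <- function(s) {
  env <- new.env(parent = emptyenv())
  env$s <- s
  env$n <- nchar(s)
  env$pos <- 1L
  env
}

sc_rest <- function(sc) substring(sc$s, sc$pos)

sc_skip_ws <- function(sc) {
  m <- regexpr("^[ \t]+", sc_rest(sc))
  if (m == 1L) sc$pos <- sc$pos + attr(m, "match.length")
  invisible(sc)
}

sc_eof <- function(sc) sc$pos > sc$n

sc_peek <- function(sc, k = 1L) substr(sc$s, sc$pos, sc$pos + k - 1L)

sc_take_regex <- function(sc, pattern) {
  m <- regexpr(paste0("^(?:", pattern, ")"), sc_rest(sc), perl = TRUE)
  if (m != 1L) return(NULL)
  len <- attr(m, "match.length")
  out <- substr(sc$s, sc$pos, sc$pos + len - 1L)
  sc$pos <- sc$pos + len
  out
}

sc_expect_char <- function(sc, ch, code = "MALFORMED_STATEMENT") {
  if (sc_peek(sc) != ch) {
    stop(bel_parse_error(code, paste0("expected '", ch, "'"), sc$pos,
                         token = sc_peek(sc)))
  }
  sc$pos <- sc$pos + 1L
  invisible(sc)
}

# quoted string with backslash escapes; scanner positioned at the quote
sc_quoted <- function(sc) {
  start <- sc$pos
  sc_expect_char(sc, '"')
  out <- character(0)
  repeat {
    if (sc_eof(sc)) {
      stop(bel_parse_error("MALFORMED_STATEMENT", "unterminated string", start))
    }
    ch <- sc_peek(sc)
    if (ch == "\\") {
      out <- c(out, substr(sc$s, sc$pos + 1L, sc$pos + 1L))
      sc$pos <- sc$pos + 2L
    } else if (ch == '"') {
      sc$pos <- sc$pos + 1L
      return(paste(out, collapse = ""))
    } else {
      out <- c(out, ch)
      sc$pos <- sc$pos + 1L
    }
  }
}

# --- term parsing ------------------------------------------------------

VARIANT_KEYWORDS <- c("pmod", "var", "sub", "trunc")

# balanced-paren content read verbatim, e.g. pmod(Ph, S, 123)
sc_variant <- function(sc, keyword) {
  start <- sc$pos
  sc_expect_char(sc, "(")
  depth <- 1L
  chars <- character(0)
  while (depth > 0L) {
    if (sc_eof(sc)) {
      stop(bel_parse_error("MALFORMED_STATEMENT", "unterminated variant", start))
    }
    ch <- sc_peek(sc)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth > 0L) chars <- c(chars, ch)
    sc$pos <- sc$pos + 1L
  }
  paste0(keyword, "(", paste(chars, collapse = ""), ")")
}

# namespace:name argument; returns list(namespace, name, ns_pos)
sc_ns_arg <- function(sc) {
  sc_skip_ws(sc)
  ns_pos <- sc$pos
  ident <- sc_take_regex(sc, "[A-Za-z_][A-Za-z0-9_]*")
  if (is.null(ident)) {
    stop(bel_parse_error("MALFORMED_STATEMENT", "expected namespace argument",
                         sc$pos, token = sc_peek(sc)))
  }
  if (sc_peek(sc) != ":") {
    stop(bel_parse_error("NAKED_NAME", "name used without a namespace",
                         ns_pos, token = ident))
  }
  sc$pos <- sc$pos + 1L
  name <- if (sc_peek(sc) == '"') {
    sc_quoted(sc)
  } else {
    nm <- sc_take_regex(sc, "[A-Za-z0-9_.-]+")
    if (is.null(nm)) {
      stop(bel_parse_error("MALFORMED_STATEMENT", "expected a name after ':'",
                           sc$pos, token = sc_peek(sc)))
    }
    nm
  }
  list(namespace = ident, name = name, ns_pos = ns_pos)
}

# One BEL term, optionally wrapped in a single act() modifier.
# Returns list(spec = node_spec, activity = logical, ns_pos = integer).
sc_term <- function(sc, depth = 0L) {
  sc_skip_ws(sc)
  start <- sc$pos
  ident <- sc_take_regex(sc, "[A-Za-z_][A-Za-z0-9_]*")
  if (is.null(ident)) {
    stop(bel_parse_error("MALFORMED_STATEMENT", "expected a term", sc$pos,
                         token = sc_peek(sc)))
  }
  if (sc_peek(sc) != "(") {
    stop(bel_parse_error("NAKED_NAME", "bare name is not a valid term",
                         start, token = ident))
  }
  if (ident %in% c("act", "activity")) {
    if (depth > 0L) {
      stop(bel_parse_error("MALFORMED_STATEMENT",
                           "nesting beyond one modifier level", start,
                           token = ident))
    }
    sc$pos <- sc$pos + 1L
    inner <- sc_term(sc, depth = depth + 1L)
    sc_skip_ws(sc)
    sc_expect_char(sc, ")")
    inner$activity <- TRUE
    return(inner)
  }
  func <- FUNCTION_ALIASES[ident]
  if (is.na(func)) {
    stop(bel_parse_error("MALFORMED_STATEMENT",
                         paste0("unknown function '", ident, "'"), start,
                         token = ident))
  }
  func <- unname(func)
  sc$pos <- sc$pos + 1L
  arg <- sc_ns_arg(sc)
  variants <- character(0)
  repeat {
    sc_skip_ws(sc)
    if (sc_peek(sc) != ",") break
    sc$pos <- sc$pos + 1L
    sc_skip_ws(sc)
    vstart <- sc$pos
    vkw <- sc_take_regex(sc, "[A-Za-z_][A-Za-z0-9_]*")
    if (is.null(vkw) || !vkw %in% VARIANT_KEYWORDS || sc_peek(sc) != "(") {
      stop(bel_parse_error("MALFORMED_STATEMENT", "expected a variant",
                           vstart, token = vkw %||% sc_peek(sc)))
    }
    if (!func %in% VARIANT_FUNCTIONS) {
      stop(bel_parse_error("MALFORMED_STATEMENT",
                           "variants only allowed on gene/rna/mirna/protein",
                           vstart, token = vkw))
    }
    variants <- c(variants, sc_variant(sc, vkw))
  }
  sc_expect_char(sc, ")")
  list(spec = node_spec(func, arg$namespace, arg$name, variants),
       activity = FALSE, ns_pos = arg$ns_pos)
}

sc_relation <- function(sc) {
  sc_skip_ws(sc)
  start <- sc$pos
  two <- sc_peek(sc, 2L)
  if (two %in% names(SHORT_RELATIONS)) {
    sc$pos <- sc$pos + 2L
    return(unname(SHORT_RELATIONS[two]))
  }
  ident <- sc_take_regex(sc, "[A-Za-z]+")
  if (is.null(ident) || !ident %in% RELATIONS) {
    stop(bel_parse_error("MALFORMED_STATEMENT", "expected a relation", start,
                         token = ident %||% sc_peek(sc)))
  }
  ident
}

# full statement: term relation term, nothing trailing
parse_statement_line <- function(line) {
  sc <- new_scanner(line)
  subject <- sc_term(sc)
  relation <- sc_relation(sc)
  object <- sc_term(sc)
  sc_skip_ws(sc)
  if (!sc_eof(sc)) {
    stop(bel_parse_error("MALFORMED_STATEMENT", "trailing content", sc$pos,
                         token = sc_peek(sc)))
  }
  list(subject = subject, relation = relation, object = object)
}

# --- directive value helpers ------------------------------------------

# all quoted strings inside a {...} list
parse_quoted_list <- function(value) {
  m <- gregexpr('"(?:[^"\\\\]|\\\\.)*"', value, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  vapply(regmatches(value, list(m))[[1]], function(q) {
    q <- substr(q, 2L, nchar(q) - 1L)
    gsub('\\\\(.)', "\\1", q)
  }, character(1), USE.NAMES = FALSE)
}

# a SET value: either one quoted string or a {...} list
parse_set_value <- function(value) {
  value <- trimws(value)
  if (startsWith(value, "{")) return(parse_quoted_list(value))
  if (startsWith(value, '"')) {
    v <- parse_quoted_list(paste0("{", value, "}"))
    if (length(v) == 1L) return(v)
  }
  NULL
}

#' Read a namespace term file
#'
#' Plain text, one valid name per line; `#` comment lines and blank lines
#' are ignored.
#'
#' @param path File path.
#' @return Character vector of terms.
#' @export
read_namespace_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

normalize_resource <- function(x) {
  if (is.character(x)) return(x)
  if (is.list(x) && !is.null(x$terms)) return(as.character(x$terms))
  as.character(unlist(x))
}

# --- the document parser ----------------------------------------------

#' Parse a BEL script into a validated document
#'
#' Consumes a BEL 1.0-style script line by line: `SET DOCUMENT` metadata,
#' `DEFINE NAMESPACE`/`DEFINE ANNOTATION` headers, `SET`/`UNSET`
#' citation, evidence and annotation context, and relational statements.
#' Statements inherit the currently-SET citation, evidence and
#' annotations. Every problem becomes a row in the returned issue table
#' (severity error/warning, category syntactic/semantic, a stable code,
#' and the verbatim line with 1-based line number and column); parsing
#' never raises on malformed input.
#'
#' Namespaces defined `AS URL` are resolved through the `resources`
#' argument or a local file path; otherwise they are kept unresolved with
#' a warning and their names pass unvalidated. A `DEFINE NAMESPACE KW AS
#' LIST {"A", "B"}` inline form is also accepted.
#'
#' @param text BEL script as a single string (or character vector of lines).
#' @param resources Optional named list mapping namespace/annotation
#'   keywords to character vectors of valid terms, overriding URL
#'   resolution.
#' @return A `bel_document`: list with `metadata`, `namespaces`,
#'   `annotation_definitions`, `statements` (tibble, one row per valid
#'   relational statement) and `issues` (tibble of parse issues).
#' @export
#' @examples
#' doc <- parse_bel_document(paste(
#'   'SET Citation = {"PubMed", "ref", "1"}',
#'   'SET Evidence = "e"',
#'   "p(HGNC:RB1) increases act(p(HGNC:E2F4))",
#'   sep = "\n"))
#' nrow(doc$statements)
parse_bel_document <- function(text, resources = NULL) {
  if (length(text) == 0) text <- ""
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  lines <- if (identical(text, "")) character(0) else strsplit(text, "\n", fixed = TRUE)[[1]]

  resources <- lapply(resources %||% list(), normalize_resource)

  metadata <- list()
  namespaces <- list()
  anndefs <- list()
  statements <- list()
  issues <- list()

  ctx_citation <- NULL
  ctx_evidence <- NULL
  ctx_annotations <- list()

  add_issue <- function(severity, category, code, ln, position = 1L, token = "") {
    issues[[length(issues) + 1L]] <<- tibble(
      severity = severity, category = category, code = code,
      line_number = ln, position = as.integer(position),
      line_text = lines[[ln]], token = token
    )
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (grepl("^[ \t]*$", line) || grepl("^[ \t]*#", line)) next

    # SET DOCUMENT <key> = <value>
    m <- regmatches(line, regexec("^[ \t]*SET[ \t]+DOCUMENT[ \t]+([A-Za-z_][A-Za-z0-9_]*)[ \t]*=[ \t]*(.*)$", line))[[1]]
    if (length(m) == 3) {
      value <- parse_set_value(m[3])
      if (is.null(value)) {
        add_issue("error", "syntactic", "MALFORMED_DIRECTIVE", ln, token = m[2])
      } else {
        metadata[[m[2]]] <- value
      }
      next
    }

    # DEFINE NAMESPACE / ANNOTATION
    m <- regmatches(line, regexec("^[ \t]*DEFINE[ \t]+(NAMESPACE|ANNOTATION)[ \t]+([A-Za-z_][A-Za-z0-9_]*)[ \t]+AS[ \t]+(URL|LIST)[ \t]+(.*)$", line))[[1]]
    if (length(m) == 5) {
      kind <- m[2]; kw <- m[3]; how <- m[4]; rest <- trimws(m[5])
      exists_already <- if (kind == "NAMESPACE") kw %in% names(namespaces) else kw %in% names(anndefs)
      if (exists_already) {
        add_issue("warning", "semantic", "DUPLICATE_DEFINITION", ln, token = kw)
      }
      if (how == "LIST") {
        terms <- parse_quoted_list(rest)
        if (kind == "NAMESPACE") {
          namespaces[[kw]] <- list(keyword = kw, source = "inline", terms = terms)
        } else {
          anndefs[[kw]] <- list(keyword = kw, allowed_values = terms)
        }
      } else {
        url <- parse_set_value(rest)
        if (is.null(url) || length(url) != 1L) {
          add_issue("error", "syntactic", "MALFORMED_DIRECTIVE", ln, token = kw)
          next
        }
        if (kw %in% names(resources)) {
          terms <- resources[[kw]]
          src <- "resources"
        } else if (file.exists(url)) {
          terms <- read_namespace_file(url)
          src <- url
        } else {
          terms <- NULL
          src <- "unresolved"
        }
        if (kind == "NAMESPACE") {
          namespaces[[kw]] <- list(keyword = kw, source = src, terms = terms)
          if (src == "unresolved") {
            add_issue("warning", "semantic", "UNRESOLVED_NAMESPACE", ln, token = kw)
          }
        } else {
          anndefs[[kw]] <- list(keyword = kw, allowed_values = terms)
          if (src == "unresolved") {
            add_issue("warning", "semantic", "UNRESOLVED_ANNOTATION", ln, token = kw)
          }
        }
      }
      next
    }
    if (grepl("^[ \t]*DEFINE[ \t]", line)) {
      add_issue("error", "syntactic", "MALFORMED_DIRECTIVE", ln)
      next
    }

    # UNSET
    m <- regmatches(line, regexec("^[ \t]*UNSET[ \t]+([A-Za-z_][A-Za-z0-9_]*)[ \t]*$", line))[[1]]
    if (length(m) == 2) {
      key <- m[2]
      if (key == "ALL") {
        ctx_citation <- NULL; ctx_evidence <- NULL; ctx_annotations <- list()
      } else if (key == "Citation") {
        ctx_citation <- NULL
      } else if (key %in% c("Evidence", "SupportingText")) {
        ctx_evidence <- NULL
      } else {
        ctx_annotations[[key]] <- NULL
      }
      next
    }
    if (grepl("^[ \t]*UNSET([ \t]|$)", line)) {
      add_issue("error", "syntactic", "MALFORMED_DIRECTIVE", ln)
      next
    }

    # SET <key> = <value>
    m <- regmatches(line, regexec("^[ \t]*SET[ \t]+([A-Za-z_][A-Za-z0-9_]*)[ \t]*=[ \t]*(.*)$", line))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      value <- parse_set_value(m[3])
      if (is.null(value)) {
        add_issue("error", "syntactic", "MALFORMED_DIRECTIVE", ln, token = key)
      } else if (key == "Citation") {
        if (length(value) < 3L || !nzchar(value[1]) || !nzchar(value[3])) {
          add_issue("error", "semantic", "INVALID_CITATION", ln, token = key)
          ctx_citation <- NULL
        } else {
          authors <- if (length(value) >= 5L && nzchar(value[5])) {
            strsplit(value[5], "|", fixed = TRUE)[[1]]
          } else {
            character(0)
          }
          ctx_citation <- list(
            db = value[1], name = value[2], ref = value[3],
            date = if (length(value) >= 4L) value[4] else "",
            authors = authors
          )
        }
      } else if (key %in% c("Evidence", "SupportingText")) {
        ctx_evidence <- paste(value, collapse = " ")
      } else if (key == "STATEMENT_GROUP") {
        # grouping construct; carries no model content
      } else if (!key %in% names(anndefs)) {
        add_issue("error", "semantic", "UNDEFINED_ANNOTATION", ln, token = key)
      } else {
        allowed <- anndefs[[key]]$allowed_values
        if (!is.null(allowed)) {
          bad <- setdiff(value, allowed)
          for (b in bad) {
            add_issue("error", "semantic", "INVALID_ANNOTATION_VALUE", ln, token = b)
          }
          value <- intersect(value, allowed)
        }
        if (length(value) > 0) {
          ctx_annotations[[key]] <- value
        }
      }
      next
    }
    if (grepl("^[ \t]*SET([ \t]|$)", line)) {
      add_issue("error", "syntactic", "MALFORMED_DIRECTIVE", ln)
      next
    }

    # relational statement
    parsed <- tryCatch(
      parse_statement_line(line),
      bel_parse_error = function(e) e,
      error = function(e) bel_parse_error("MALFORMED_STATEMENT", conditionMessage(e), 1L)
    )
    if (inherits(parsed, "bel_parse_error")) {
      add_issue("error", "syntactic", parsed$code, ln,
                position = parsed$pos, token = parsed$token)
      next
    }

    # semantic validation
    ok <- TRUE
    for (side in list(parsed$subject, parsed$object)) {
      ns <- side$spec$namespace
      if (!ns %in% names(namespaces)) {
        add_issue("error", "semantic", "UNDEFINED_NAMESPACE", ln,
                  position = side$ns_pos, token = ns)
        ok <- FALSE
      } else {
        terms <- namespaces[[ns]]$terms
        if (!is.null(terms) && !side$spec$name %in% terms) {
          add_issue("error", "semantic", "NAME_NOT_IN_NAMESPACE", ln,
                    position = side$ns_pos, token = side$spec$name)
          ok <- FALSE
        }
      }
    }
    if (is.null(ctx_citation)) {
      add_issue("error", "semantic", "MISSING_CITATION", ln)
      ok <- FALSE
    }
    if (!ok) next

    statements[[length(statements) + 1L]] <- tibble(
      line_number = ln,
      subject = list(parsed$subject$spec),
      relation = parsed$relation,
      object = list(parsed$object$spec),
      subject_activity = parsed$subject$activity,
      object_activity = parsed$object$activity,
      citation_db = ctx_citation$db,
      citation_name = ctx_citation$name,
      citation_ref = ctx_citation$ref,
      citation_date = ctx_citation$date,
      citation_authors = list(ctx_citation$authors),
      evidence = ctx_evidence %||% "",
      annotations = list(ctx_annotations)
    )
  }

  structure(
    list(
      metadata = metadata,
      namespaces = namespaces,
      annotation_definitions = anndefs,
      statements = if (length(statements)) bind_rows(statements) else empty_statements(),
      issues = if (length(issues)) bind_rows(issues) else empty_issues()
    ),
    class = "bel_document"
  )
}

#' @export
print.bel_document <- function(x, ...) {
  n_err <- sum(x$issues$severity == "error")
  n_warn <- sum(x$issues$severity == "warning")
  cat("<bel_document> ", x$metadata$Name %||% "(unnamed)", "\n",
      "  statements: ", nrow(x$statements),
      "  namespaces: ", length(x$namespaces),
      "  issues: ", n_err, " errors, ", n_warn, " warnings\n", sep = "")
  invisible(x)
}

#' Group recurring parse issues
#'
#' Recurring errors and warnings are grouped by (code, offending token)
#' so curators can prioritize impactful fixes. Groups are sorted by count
#' descending, ties broken by first line number ascending; the
#' representative message is the verbatim text of the group's first line.
#'
#' @param issues Issue tibble from [parse_bel_document()].
#' @return A tibble with columns `code`, `token`, `representative`,
#'   `count`, `line_numbers` (list column). Counts sum to `nrow(issues)`.
#' @export
group_recurring_issues <- function(issues) {
  if (nrow(issues) == 0) {
    return(tibble(code = character(), token = character(),
                  representative = character(), count = integer(),
                  line_numbers = list()))
  }
  issues |>
    arrange(.data$line_number) |>
    group_by(.data$code, .data$token) |>
    summarise(
      representative = .data$line_text[1],
      count = n(),
      line_numbers = list(.data$line_number),
      first_line = .data$line_number[1],
      .groups = "drop"
    ) |>
    arrange(desc(.data$count), .data$first_line) |>
    select(-"first_line")
}
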