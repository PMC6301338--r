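# Serialization of a bel_document back to BEL script text.

bel_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

serialize_citation <- function(row) {
  fields <- c(row$citation_db, row$citation_name, row$citation_ref)
  authors <- row$citation_authors[[1]]
  if (nzchar(row$citation_date) || length(authors) > 0) {
    fields <- c(fields, row$citation_date)
  }
  if (length(authors) > 0) {
    fields <- c(fields, paste(authors, collapse = "|"))
  }
  paste0("SET Citation = {", paste(bel_quote(fields), collapse = ", "), "}")
}

#' Serialize a document to BEL script text
#'
#' Emits document metadata, namespace and annotation definitions
#' (resolved namespaces as inline `AS LIST` definitions so the output
#' re-parses without external resources), and one `SET` block per
#' statement followed by `UNSET ALL`. Annotation `SET` lines are emitted
#' in lexicographic key order with sorted values, giving a canonical
#' form: re-parsing the output yields the same statement multiset.
#'
#' @param document A `bel_document` without error-severity issues.
#' @return BEL script as a single string.
#' @export
serialize_bel <- function(document) {
  stopifnot(inherits(document, "bel_document"))
  if (any(document$issues$severity == "error")) {
    stop("cannot serialize a document with error-severity issues", call. = FALSE)
  }
  out <- character(0)
  for (key in names(document$metadata)) {
    v <- document$metadata[[key]]
    val <- if (length(v) == 1L) bel_quote(v) else
      paste0("{", paste(bel_quote(v), collapse = ", "), "}")
    out <- c(out, paste0("SET DOCUMENT ", key, " = ", val))
  }
  for (kw in sort(names(document$namespaces))) {
    ns <- document$namespaces[[kw]]
    out <- c(out, if (is.null(ns$terms)) {
      paste0("DEFINE NAMESPACE ", kw, " AS URL ",
             bel_quote(if (ns$source == "unresolved") paste0("unresolved://", kw) else ns$source))
    } else {
      paste0("DEFINE NAMESPACE ", kw, " AS LIST {",
             paste(bel_quote(ns$terms), collapse = ", "), "}")
    })
  }
  for (kw in sort(names(document$annotation_definitions))) {
    ad <- document$annotation_definitions[[kw]]
    out <- c(out, if (is.null(ad$allowed_values)) {
      paste0("DEFINE ANNOTATION ", kw, " AS URL ",
             bel_quote(paste0("unresolved://", kw)))
    } else {
      paste0("DEFINE ANNOTATION ", kw, " AS LIST {",
             paste(bel_quote(ad$allowed_values), collapse = ", "), "}")
    })
  }
  st <- document$statements
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    out <- c(out, "", serialize_citation(row))
    if (nzchar(row$evidence)) {
      out <- c(out, paste0("SET Evidence = ", bel_quote(row$evidence)))
    }
    ann <- row$annotations[[1]]
    for (key in sort(names(ann))) {
      vals <- sort(ann[[key]])
      val <- if (length(vals) == 1L) bel_quote(vals) else
        paste0("{", paste(bel_quote(vals), collapse = ", "), "}")
      out <- c(out, paste0("SET ", key, " = ", val))
    }
    out <- c(out, paste(
      term_to_string(row$subject[[1]], row$subject_activity),
      row$relation,
      term_to_string(row$object[[1]], row$object_activity)
    ), "UNSET ALL")
  }
  paste(out, collapse = "\n")
}

# canonical comparable form of a statement table, for round-trip checks
statement_fingerprints <- function(statements) {
  if (nrow(statements) == 0) return(character(0))
  vapply(seq_len(nrow(statements)), function(i) {
    row <- statements[i, ]
    ann <- row$annotations[[1]]
    ann_s <- if (length(ann) == 0) "" else {
      keys <- sort(names(ann))
      paste(vapply(keys, function(k) paste0(k, "=", paste(sort(ann[[k]]), collapse = ",")), ""),
            collapse = ";")
    }
    paste(
      term_to_string(row$subject[[1]], row$subject_activity),
      row$relation,
      term_to_string(row$object[[1]], row$object_activity),
      row$citation_db, row$citation_name, row$citation_ref, row$citation_date,
      paste(row$citation_authors[[1]], collapse = "|"),
      row$evidence, ann_s,
      sep = ""
    )
  }, character(1))
}
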