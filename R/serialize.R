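escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

term_nt <- function(object, object_kind, datatype) {
  ifelse(object_kind == "iri",
         paste0("<", object, ">"),
         paste0("\"", escape_lit(object), "\"",
                ifelse(is.na(datatype) | datatype == paste0(XSD, "string"),
                       "", paste0("^^<", datatype, ">"))))
}

sorted_triples <- function(kg) {
  kg$triples %>% arrange(.data$subject, .data$predicate, .data$object,
                         .data$object_kind)
}

#' Serialize a knowledge graph
#'
#' `write_ntriples()` emits canonical N-Triples (sorted, one triple per
#' line); `write_turtle()` emits a compact Turtle form with a prefix block
#' and `a` for `rdf:type`. Both are byte-stable for a given graph.
#' `read_ntriples()` and `read_turtle()` parse these serializations back
#' (the subset the writers produce: IRIs, typed literals, prefixed names —
#' no blank nodes or language tags).
#'
#' @param kg an `adl_kg`.
#' @param path output file.
#' @return The writers return `path` invisibly; the readers return an
#'   `adl_kg`.
#' @export
write_ntriples <- function(kg, path) {
  tr <- sorted_triples(kg)
  lines <- paste0("<", tr$subject, "> <", tr$predicate, "> ",
                  term_nt(tr$object, tr$object_kind, tr$datatype), " .")
  writeLines(lines, path)
  invisible(path)
}

parse_term <- function(tok, prefixes) {
  if (startsWith(tok, "<")) {
    list(value = substr(tok, 2, nchar(tok) - 1), kind = "iri",
         datatype = NA_character_)
  } else if (startsWith(tok, "\"")) {
    m <- regmatches(tok, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(.+))?$',
                                 tok))[[1]]
    dt <- m[3]
    if (!is.na(dt) && dt != "") {
      dt <- if (startsWith(dt, "<")) substr(dt, 2, nchar(dt) - 1)
            else expand_pname(dt, prefixes)
    } else {
      dt <- paste0(XSD, "string")
    }
    list(value = unescape_lit(m[2]), kind = "literal", datatype = dt)
  } else if (tok == "a") {
    list(value = iri_rdf_type, kind = "iri", datatype = NA_character_)
  } else {
    list(value = expand_pname(tok, prefixes), kind = "iri",
         datatype = NA_character_)
  }
}

expand_pname <- function(tok, prefixes) {
  parts <- stringr::str_split_fixed(tok, ":", 2)
  base <- prefixes[[parts[1]]]
  if (is.null(base)) abort(paste0("undeclared prefix in term: ", tok))
  paste0(base, parts[2])
}

tokenize_statement <- function(line) {
  # three terms followed by " ."; literals may contain escaped quotes
  pat <- '(<[^>]*>|"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^(?:<[^>]*>|[A-Za-z][\\w.-]*:[\\w.-]+))?|[A-Za-z][\\w.-]*:[\\w.-]*|a)'
  m <- stringr::str_match_all(line, pat)[[1]][, 2]
  if (length(m) != 3) abort(paste0("cannot parse statement: ", line))
  m
}

parse_statements <- function(lines, prefixes) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- purrr::map(lines, function(l) {
    toks <- tokenize_statement(l)
    s <- parse_term(toks[1], prefixes)
    p <- parse_term(toks[2], prefixes)
    o <- parse_term(toks[3], prefixes)
    tibble(subject = s$value, predicate = p$value, object = o$value,
           object_kind = o$kind, datatype = o$datatype)
  })
  kg_new(bind_rows(rows))
}

#' @rdname write_ntriples
#' @export
read_ntriples <- function(path) {
  parse_statements(readLines(path, warn = FALSE), list())
}

term_ttl <- function(object, object_kind, datatype, prefixes) {
  out <- character(length(object))
  for (i in seq_along(object)) {
    if (object_kind[i] == "iri") {
      pn <- NA
      for (p in names(prefixes)) {
        base <- prefixes[[p]]
        if (startsWith(object[i], base)) {
          local <- substr(object[i], nchar(base) + 1, nchar(object[i]))
          if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
            pn <- paste0(p, ":", local); break
          }
        }
      }
      out[i] <- if (is.na(pn)) paste0("<", object[i], ">") else pn
    } else {
      dt <- datatype[i]
      suffix <- if (is.na(dt) || dt == paste0(XSD, "string")) "" else
        paste0("^^xsd:", sub(XSD, "", dt, fixed = TRUE))
      out[i] <- paste0("\"", escape_lit(object[i]), "\"", suffix)
    }
  }
  out
}

#' @rdname write_ntriples
#' @export
write_turtle <- function(kg, path) {
  tr <- sorted_triples(kg)
  pre <- kg$prefixes
  header <- paste0("@prefix ", names(pre), ": <", unname(pre), "> .")
  s <- term_ttl(tr$subject, rep("iri", nrow(tr)), rep(NA, nrow(tr)), pre)
  p <- term_ttl(tr$predicate, rep("iri", nrow(tr)), rep(NA, nrow(tr)), pre)
  p[tr$predicate == iri_rdf_type] <- "a"
  o <- term_ttl(tr$object, tr$object_kind, tr$datatype, pre)
  writeLines(c(header, "", paste0(s, " ", p, " ", o, " .")), path)
  invisible(path)
}

#' @rdname write_ntriples
#' @export
read_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pre_lines <- grep("^@prefix", lines, value = TRUE)
  m <- stringr::str_match(pre_lines, "^@prefix\\s+([A-Za-z][\\w.-]*):\\s+<([^>]*)>")
  prefixes <- as.list(setNames(m[, 3], m[, 2]))
  body <- lines[!grepl("^@prefix", lines)]
  parse_statements(body, prefixes)
}
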