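#' @title RDF triple tables
#' @description
#' Triples are held in a plain tibble with columns `subject`, `predicate`,
#' `object`, `object_kind` (`"iri"`, `"bnode"` or `"literal"`), `lang` and
#' `datatype`. Blank nodes carry `_:`-prefixed identifiers until
#' [skolemize_triples()] rewrites them to stable `urn:skolem:` IRIs; all
#' higher layers of the package only ever see skolemized triple sets, so two
#' triples are equal iff all components (literals: lexical form + datatype +
#' language tag) are equal.
#' @name rdf-triples
NULL

triple_tbl <- function(subject = character(), predicate = character(),
                       object = character(), object_kind = character(),
                       lang = character(), datatype = character()) {
  tibble::tibble(subject = as.character(subject),
                 predicate = as.character(predicate),
                 object = as.character(object),
                 object_kind = as.character(object_kind),
                 lang = as.character(lang),
                 datatype = as.character(datatype))
}

# Plain literals and xsd:string literals are the same RDF 1.1 value; normalize
# the explicit form away so set comparison is syntax-independent.
normalize_triples <- function(tr) {
  tr$datatype[!is.na(tr$datatype) & tr$datatype == XSD_STRING] <- NA_character_
  tr$lang[!is.na(tr$lang) & tr$lang == ""] <- NA_character_
  dplyr::distinct(tr)
}

# canonical N-Triples-style rendering; the package's triple identity key
render_ntriple <- function(tr) {
  if (nrow(tr) == 0) return(character(0))
  obj <- ifelse(tr$object_kind == "literal",
                paste0("\"", escape_literal(tr$object), "\"",
                       ifelse(!is.na(tr$lang), paste0("@", tr$lang),
                              ifelse(!is.na(tr$datatype),
                                     paste0("^^<", tr$datatype, ">"), ""))),
                ifelse(tr$object_kind == "bnode", tr$object,
                       paste0("<", tr$object, ">")))
  subj <- ifelse(startsWith(tr$subject, "_:"), tr$subject,
                 paste0("<", tr$subject, ">"))
  paste0(subj, " <", tr$predicate, "> ", obj, " .")
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  needs <- grepl("\\", x, fixed = TRUE)
  if (!any(needs)) return(x)
  x[needs] <- vapply(x[needs], function(s) {
    parts <- regmatches(s, gregexpr(
      "\\\\u[0-9a-fA-F]{4}|\\\\U[0-9a-fA-F]{8}|\\\\.|[^\\\\]+", s))[[1]]
    out <- vapply(parts, function(p) {
      if (!startsWith(p, "\\")) return(p)
      key <- substr(p, 2, 2)
      switch(key,
             "u" = , "U" = intToUtf8(strtoi(substring(p, 3), 16L)),
             "n" = "\n", "t" = "\t", "r" = "\r", "b" = "\b", "f" = "\f",
             "\\" = "\\", "\"" = "\"", "'" = "'",
             stop("unsupported escape sequence: ", p, call. = FALSE))
    }, character(1))
    paste(out, collapse = "")
  }, character(1))
  x
}

## ---------------------------------------------------------------- Turtle ----

# master token pattern; alternation order matters (strings and IRIs shield
# '#' and punctuation from the comment/punct branches)
.turtle_token_re <- paste(
  "\"\"\"[\\s\\S]*?\"\"\"",                       # long string (no escaped-quote edge)
  "\"(?:[^\"\\\\\\n]|\\\\.)*\"",                  # string
  "<[^>\\s]*>",                                   # IRIREF
  "#[^\\n]*",                                     # comment
  "\\^\\^",                                       # datatype marker
  "@[A-Za-z]+(?:-[A-Za-z0-9]+)*",                 # langtag or @prefix/@base
  "_:[A-Za-z0-9][A-Za-z0-9_.-]*",                 # blank node label
  "(?:[A-Za-z_][A-Za-z0-9_-]*(?:\\.[A-Za-z0-9_-]+)*)?:(?:[A-Za-z0-9_%-]+(?:\\.[A-Za-z0-9_%-]+)*)?", # pname
  "[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",# numeric literal
  "[A-Za-z_][A-Za-z0-9_-]*",                      # bareword (a, true, false, PREFIX)
  "[.;,\\[\\]()]",                                # punctuation
  sep = "|")

tokenize_turtle <- function(text) {
  m <- gregexpr(.turtle_token_re, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(text, list(m))[[1]]
  toks[!startsWith(toks, "#")]
}

#' Parse Turtle or N-Triples text into a triple table
#'
#' Supports the Turtle subset emitted by mainstream ontology tooling:
#' prefix directives (`@prefix` and SPARQL `PREFIX`), `;`/`,` predicate-object
#' lists, `a`, plain/typed/language-tagged literals (short and long quoted),
#' numeric and boolean shorthand, labelled blank nodes and anonymous `[ ... ]`
#' blank nodes. RDF collections `( ... )` are not supported. N-Triples
#' documents are valid input (N-Triples is a Turtle subset).
#'
#' @param text A single string of Turtle source.
#' @param source Name used in error messages.
#' @return A triple tibble (see [rdf-triples]); blank nodes not yet skolemized.
#' @export
parse_turtle <- function(text, source = "<text>") {
  toks <- tokenize_turtle(text)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$toks <- toks
  env$n <- length(toks)
  env$prefixes <- c(NS$rdf, NS$rdfs, NS$owl, NS$xsd)
  names(env$prefixes) <- c("rdf", "rdfs", "owl", "xsd")
  env$base <- ""
  env$bnode_counter <- 0L
  acc <- vector("list", 256L)
  acc_n <- 0L
  emit <- function(s, p, o, kind, lang = NA_character_, dt = NA_character_) {
    acc_n <<- acc_n + 1L
    if (acc_n > length(acc)) length(acc) <<- 2L * acc_n
    acc[[acc_n]] <<- list(s, p, o, kind, lang, dt)
  }
  peek <- function() if (env$i <= env$n) env$toks[[env$i]] else ""
  advance <- function() { t <- peek(); env$i <- env$i + 1L; t }
  fail <- function(msg) {
    stop(sprintf("parse error in %s near token %d ('%s'): %s",
                 source, env$i, peek(), msg), call. = FALSE)
  }
  expect <- function(tok) if (advance() != tok) fail(paste0("expected '", tok, "'"))

  expand_pname <- function(tok) {
    colon <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1, colon - 1)
    loc <- substring(tok, colon + 1)
    if (!pfx %in% names(env$prefixes))
      fail(paste0("undeclared prefix '", pfx, ":'"))
    base <- env$prefixes[[pfx]]
    paste0(base, utils::URLdecode(loc))
  }
  fresh_bnode <- function() {
    env$bnode_counter <- env$bnode_counter + 1L
    paste0("_:genid", env$bnode_counter)
  }

  parse_resource <- function(tok) {
    if (startsWith(tok, "<")) {
      iri <- substr(tok, 2, nchar(tok) - 1)
      if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)) iri <- paste0(env$base, iri)
      iri
    } else if (startsWith(tok, "_:")) {
      tok
    } else if (grepl(":", tok, fixed = TRUE)) {
      expand_pname(tok)
    } else fail("expected IRI, prefixed name or blank node")
  }

  # returns list(value, kind, lang, datatype)
  parse_object <- function() {
    tok <- advance()
    if (tok == "[") {
      b <- fresh_bnode()
      if (peek() != "]") parse_po_list(b)
      expect("]")
      return(list(b, "bnode", NA_character_, NA_character_))
    }
    if (tok == "(") fail("RDF collections are not supported")
    if (startsWith(tok, "\"")) {
      raw <- if (startsWith(tok, "\"\"\"")) substr(tok, 4, nchar(tok) - 3)
             else substr(tok, 2, nchar(tok) - 1)
      val <- unescape_literal(raw)
      lang <- NA_character_; dt <- NA_character_
      if (startsWith(peek(), "@")) {
        lang <- substring(advance(), 2)
      } else if (peek() == "^^") {
        advance()
        dt <- parse_resource(advance())
      }
      return(list(val, "literal", lang, dt))
    }
    if (tok %in% c("true", "false"))
      return(list(tok, "literal", NA_character_, XSD_BOOLEAN))
    if (grepl("^[+-]?[0-9]", tok)) {
      dt <- if (grepl("[eE]", tok)) paste0(NS$xsd, "double")
            else if (grepl(".", tok, fixed = TRUE)) paste0(NS$xsd, "decimal")
            else paste0(NS$xsd, "integer")
      return(list(tok, "literal", NA_character_, dt))
    }
    r <- parse_resource(tok)
    list(r, if (startsWith(r, "_:")) "bnode" else "iri",
         NA_character_, NA_character_)
  }

  parse_po_list <- function(subj) {
    repeat {
      ptok <- advance()
      pred <- if (ptok == "a") RDF_TYPE else parse_resource(ptok)
      repeat {
        o <- parse_object()
        emit(subj, pred, o[[1]], o[[2]], o[[3]], o[[4]])
        if (peek() == ",") advance() else break
      }
      if (peek() == ";") {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (peek() %in% c(".", "]")) break
      } else break
    }
  }

  while (env$i <= env$n) {
    tok <- advance()
    if (tok == "@prefix" || tok == "PREFIX") {
      pn <- advance()
      if (!grepl(":$", pn)) fail("malformed prefix declaration")
      iri_tok <- advance()
      if (!startsWith(iri_tok, "<")) fail("prefix IRI expected")
      env$prefixes[[substr(pn, 1, nchar(pn) - 1)]] <-
        substr(iri_tok, 2, nchar(iri_tok) - 1)
      if (tok == "@prefix") expect(".")
    } else if (tok == "@base" || tok == "BASE") {
      iri_tok <- advance()
      env$base <- substr(iri_tok, 2, nchar(iri_tok) - 1)
      if (tok == "@base") expect(".")
    } else if (tok == "[") {
      b <- fresh_bnode()
      if (peek() != "]") parse_po_list(b)
      expect("]")
      if (peek() != ".") parse_po_list(b)
      expect(".")
    } else {
      subj <- parse_resource(tok)
      parse_po_list(subj)
      expect(".")
    }
  }

  if (acc_n == 0L) return(triple_tbl())
  acc <- acc[seq_len(acc_n)]
  normalize_triples(triple_tbl(
    subject = vapply(acc, `[[`, "", 1L),
    predicate = vapply(acc, `[[`, "", 2L),
    object = vapply(acc, `[[`, "", 3L),
    object_kind = vapply(acc, `[[`, "", 4L),
    lang = vapply(acc, function(x) x[[5L]], NA_character_),
    datatype = vapply(acc, function(x) x[[6L]], NA_character_)))
}

## --------------------------------------------------------------- RDF/XML ----

#' Parse an RDF/XML document into a triple table
#'
#' Handles the striped syntax produced by mainstream serializers: `rdf:RDF`
#' roots, `rdf:Description` and typed node elements, `rdf:about` / `rdf:ID` /
#' `rdf:nodeID`, `rdf:resource` and `rdf:datatype` attributes, inherited
#' `xml:lang`, nested node elements and `rdf:parseType="Resource"`.
#'
#' @param x A file path, URL-free XML string, or `xml2` document.
#' @inheritParams parse_turtle
#' @return A triple tibble; blank nodes not yet skolemized.
#' @export
parse_rdfxml <- function(x, source = "<xml>") {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  rdfns <- NS$rdf
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  acc$k <- 0L
  acc$bn <- 0L
  emit <- function(s, p, o, kind, lang = NA_character_, dt = NA_character_) {
    acc$k <- acc$k + 1L
    acc$rows[[acc$k]] <- list(s, p, o, kind, lang, dt)
  }
  fresh_bnode <- function() { acc$bn <- acc$bn + 1L; paste0("_:xml", acc$bn) }
  nsmap <- xml2::xml_ns(doc)
  nsfull <- c(structure(as.character(nsmap), names = names(nsmap)),
              xml = "http://www.w3.org/XML/1998/namespace")
  qname <- function(node) {
    nm <- xml2::xml_name(node, ns = nsmap)   # "prefix:local" or "local"
    if (grepl(":", nm, fixed = TRUE)) {
      pfx <- sub(":.*", "", nm)
      paste0(nsmap[[pfx]], sub(".*:", "", nm))
    } else nm
  }
  qattr <- function(node, qname) {
    a <- xml2::xml_attrs(node, ns = nsfull)
    if (qname %in% names(a)) unname(a[[qname]]) else NULL
  }
  attr_of <- function(node, local) qattr(node, paste0("rdf:", local))
  lang_attr <- function(node) qattr(node, "xml:lang") %||% NA_character_
  base_iri <- function() qattr(xml2::xml_root(doc), "xml:base") %||% ""

  node_subject <- function(node) {
    about <- attr_of(node, "about")
    if (!is.null(about)) return(about)
    id <- attr_of(node, "ID")
    if (!is.null(id)) return(paste0(base_iri(), "#", id))
    nid <- attr_of(node, "nodeID")
    if (!is.null(nid)) return(paste0("_:", nid))
    fresh_bnode()
  }

  walk_node <- function(node, lang) {
    lng <- lang_attr(node)
    if (!is.na(lng)) lang <- if (nzchar(lng)) lng else NA_character_
    subj <- node_subject(node)
    nm <- qname(node)
    if (nm != paste0(rdfns, "Description"))
      emit(subj, RDF_TYPE, nm, "iri")
    for (prop in xml2::xml_children(node)) walk_property(prop, subj, lang)
    subj
  }

  walk_property <- function(prop, subj, lang) {
    lng <- lang_attr(prop)
    if (!is.na(lng)) lang <- if (nzchar(lng)) lng else NA_character_
    pred <- qname(prop)
    res <- attr_of(prop, "resource")
    if (!is.null(res)) { emit(subj, pred, res, "iri"); return(invisible()) }
    nid <- attr_of(prop, "nodeID")
    if (!is.null(nid)) { emit(subj, pred, paste0("_:", nid), "bnode"); return(invisible()) }
    pt <- attr_of(prop, "parseType")
    if (!is.null(pt) && pt == "Resource") {
      b <- fresh_bnode()
      emit(subj, pred, b, "bnode")
      for (ch in xml2::xml_children(prop)) walk_property(ch, b, lang)
      return(invisible())
    }
    kids <- xml2::xml_children(prop)
    if (length(kids) > 0) {
      obj <- walk_node(kids[[1]], lang)
      emit(subj, pred, obj, if (startsWith(obj, "_:")) "bnode" else "iri")
    } else {
      dt <- attr_of(prop, "datatype")
      txt <- xml2::xml_text(prop)
      emit(subj, pred, txt, "literal",
           if (is.null(dt)) lang else NA_character_,
           dt %||% NA_character_)
    }
  }

  root <- xml2::xml_root(doc)
  root_lang <- lang_attr(root)
  tops <- if (qname(root) == paste0(rdfns, "RDF")) xml2::xml_children(root) else list(root)
  for (nd in tops) walk_node(nd, root_lang)

  rows <- acc$rows[seq_len(acc$k)]
  if (length(rows) == 0) return(triple_tbl())
  normalize_triples(triple_tbl(
    subject = vapply(rows, `[[`, "", 1L),
    predicate = vapply(rows, `[[`, "", 2L),
    object = vapply(rows, `[[`, "", 3L),
    object_kind = vapply(rows, `[[`, "", 4L),
    lang = vapply(rows, function(x) x[[5L]], NA_character_),
    datatype = vapply(rows, function(x) x[[6L]], NA_character_)))
}

## --------------------------------------------------------- skolemization ----

#' Deterministic skolemization of blank nodes
#'
#' Replaces every blank node by a `urn:skolem:` IRI derived from a two-round
#' Weisfeiler–Lehman-style signature of the node's neighbourhood (the triples
#' it occurs in, with blank-node positions abstracted, then refined by
#' neighbour signatures). Nodes whose signatures remain identical are
#' disambiguated by first occurrence in the (deterministically parsed) input,
#' so identical input bytes always yield identical skolem IRIs.
#'
#' @param tr A triple tibble.
#' @return The tibble with all blank nodes rewritten to IRIs.
#' @export
skolemize_triples <- function(tr) {
  is_bsub <- startsWith(tr$subject, "_:")
  is_bobj <- tr$object_kind == "bnode"
  if (!any(is_bsub) && !any(is_bobj)) return(tr)
  bnodes <- unique(c(tr$subject[is_bsub], tr$object[is_bobj]))

  sig_of <- function(prev) {
    # prev: named character of per-bnode signatures (or "" initially)
    vapply(bnodes, function(b) {
      rs <- tr[tr$subject == b | (is_bobj & tr$object == b), , drop = FALSE]
      lines <- paste(
        ifelse(rs$subject == b, "SELF",
               ifelse(startsWith(rs$subject, "_:"),
                      paste0("B[", prev[rs$subject], "]"), rs$subject)),
        rs$predicate,
        ifelse(rs$object_kind == "bnode" & rs$object == b, "SELF",
               ifelse(rs$object_kind == "bnode",
                      paste0("B[", prev[rs$object], "]"), rs$object)),
        rs$object_kind, ifelse(is.na(rs$lang), "", rs$lang),
        ifelse(is.na(rs$datatype), "", rs$datatype))
      content_hash(paste(stable_sort(lines), collapse = "\n"))
    }, character(1))
  }
  sig <- stats::setNames(rep("", length(bnodes)), bnodes)
  for (round in 1:2) sig <- stats::setNames(sig_of(sig), bnodes)
  # disambiguate equal signatures by first-occurrence order
  occurrence <- stats::setNames(seq_along(bnodes), bnodes)
  final <- paste0(sig, "-", stats::ave(occurrence[bnodes], sig[bnodes],
                                       FUN = function(v) rank(v, ties.method = "first")))
  skolem <- stats::setNames(paste0("urn:skolem:", content_hash(final)), bnodes)

  tr$subject[is_bsub] <- unname(skolem[tr$subject[is_bsub]])
  tr$object[is_bobj] <- unname(skolem[tr$object[is_bobj]])
  tr$object_kind[is_bobj] <- "iri"
  dplyr::distinct(tr)
}

## ------------------------------------------------------------ serializers ----

default_prefixes <- function() c(
  rdf = NS$rdf, rdfs = NS$rdfs, owl = NS$owl, xsd = NS$xsd,
  skos = NS$skos, oboInOwl = NS$obo
)

compact_iri <- function(iri, prefixes) {
  nas <- is.na(iri)
  iri[nas] <- ""
  for (p in names(prefixes)) {
    base <- prefixes[[p]]
    hit <- startsWith(iri, base)
    if (any(hit)) {
      loc <- substring(iri, nchar(base) + 1)
      ok <- hit & grepl("^[A-Za-z0-9_][A-Za-z0-9_-]*$", loc)
      iri[ok] <- paste0(p, ":", loc[ok])
    }
  }
  ifelse(grepl("^[A-Za-z0-9_.-]+:[A-Za-z0-9_-]*$", iri) & !grepl("^urn:", iri) &
           !grepl("://", iri),
         iri, paste0("<", iri, ">"))
}

format_object_ttl <- function(tr, prefixes) {
  ifelse(tr$object_kind == "literal",
         paste0("\"", escape_literal(tr$object), "\"",
                ifelse(!is.na(tr$lang), paste0("@", tr$lang),
                       ifelse(!is.na(tr$datatype),
                              paste0("^^", compact_iri(tr$datatype, prefixes)), ""))),
         compact_iri(tr$object, prefixes))
}

#' Serialize a triple table
#'
#' `write_turtle()` writes grouped, prefix-compacted Turtle with a stable
#' (sorted) statement order; `write_ntriples()` writes canonical sorted
#' N-Triples. Both return the serialized text invisibly when `path` is `NULL`.
#'
#' @param tr A triple tibble (skolemized; blank labels are written as-is).
#' @param path Output file, or `NULL` to return the text.
#' @param prefixes Named character vector of prefix -> namespace IRI.
#' @return The serialized document as a single string (invisibly if written).
#' @export
write_turtle <- function(tr, path = NULL, prefixes = default_prefixes()) {
  header <- paste0("@prefix ", names(prefixes), ": <", prefixes, "> .")
  tr <- tr[stable_order(tr$subject, tr$predicate != RDF_TYPE, tr$predicate,
                        tr$object, ifelse(is.na(tr$lang), "", tr$lang)), ,
           drop = FALSE]
  body <- character(0)
  if (nrow(tr) > 0) {
    obj <- format_object_ttl(tr, prefixes)
    pred <- ifelse(tr$predicate == RDF_TYPE, "a",
                   compact_iri(tr$predicate, prefixes))
    lines <- split(paste0("  ", pred, " ", obj),
                   factor(tr$subject, levels = unique(tr$subject)))
    body <- vapply(names(lines), function(s) {
      paste0(compact_iri(s, prefixes), "\n",
             paste(lines[[s]], collapse = " ;\n"), " .")
    }, character(1))
  }
  out <- paste(c(header, "", body, ""), collapse = "\n")
  if (is.null(path)) return(invisible(out))
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' @rdname write_turtle
#' @export
write_ntriples <- function(tr, path = NULL) {
  out <- paste(c(stable_sort(render_ntriple(tr)), ""), collapse = "\n")
  if (is.null(path)) return(invisible(out))
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}
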