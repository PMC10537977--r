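# Internal helpers: stable content hashes, IRI manipulation, namespace constants.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Well-known vocabulary IRIs used by defaults and parsers.
NS <- list(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  obo  = "http://www.geneontology.org/formats/oboInOwl#"
)

RDF_TYPE       <- paste0(NS$rdf, "type")
RDFS_SUBCLASS  <- paste0(NS$rdfs, "subClassOf")
RDFS_SUBPROP   <- paste0(NS$rdfs, "subPropertyOf")
RDFS_LABEL     <- paste0(NS$rdfs, "label")
RDFS_COMMENT   <- paste0(NS$rdfs, "comment")
OWL_DEPRECATED <- paste0(NS$owl, "deprecated")
XSD_BOOLEAN    <- paste0(NS$xsd, "boolean")
XSD_STRING     <- paste0(NS$xsd, "string")

#' @keywords internal
#' @noRd
iri_local_name <- function(iri) {
  # local part after the last '#' or '/'
  sub(".*[#/]", "", iri)
}

# Vectorised double-pass FNV-1a (32-bit x 2) content hash, hex-encoded.
# Deterministic across platforms; used only for stable identifiers, not security.
# Processes all strings position-by-position so the loop length is max(nchar),
# not total bytes.
content_hash <- function(x) {
  if (length(x) == 0L) return(character(0))
  raws <- lapply(enc2utf8(as.character(x)), charToRaw)
  lens <- lengths(raws)
  n <- length(raws)
  maxlen <- max(lens, 1L)
  # 16-bit split multiplication mod 2^32 keeps everything exact in doubles
  mul32 <- function(h, p) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  pass <- function(offset, prime) {
    h <- rep(offset, n)
    for (j in seq_len(maxlen)) {
      act <- lens >= j
      if (!any(act)) break
      b <- vapply(raws[act], function(r) as.integer(r[[j]]), integer(1))
      hb <- h[act]
      hb <- floor(hb / 256) * 256 + bitwXor(as.integer(hb %% 256), b)
      h[act] <- mul32(hb, prime)
    }
    h
  }
  h1 <- pass(2166136261, 16777619)
  h2 <- pass(31, 16777619)  # different basis -> quasi-64-bit
  paste0(to_hex32(h1), to_hex32((h2 + lens) %% 4294967296))
}

# 8-digit lowercase hex of a double holding a value in [0, 2^32)
to_hex32 <- function(h) {
  hexd <- strsplit("0123456789abcdef", "")[[1]]
  out <- rep("", length(h))
  for (i in 1:8) {
    d <- h %% 16
    out <- paste0(hexd[d + 1], out)
    h <- (h - d) / 16
  }
  out
}

# deterministic, locale-independent ordering for IRIs and keys
stable_order <- function(...) order(..., method = "radix")
stable_sort <- function(x) if (length(x)) x[stable_order(x)] else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
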