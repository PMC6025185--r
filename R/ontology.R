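.ASPECT_FROM_NAMESPACE <- c(molecular_function = "MF",
                            biological_process = "BP",
                            cellular_component = "CC")
.ASPECT_FROM_GAF <- c(F = "MF", P = "BP", C = "CC")

#' Parse a GO ontology from OBO-format text
#'
#' Reads an OBO 1.2/1.4 flat file and builds the GO directed acyclic graph.
#' Non-obsolete terms are kept in the DAG; obsolete terms are retained in a
#' separate registry (with no parent edges). `alt_id` accessions are recorded
#' so downstream annotation readers can remap them to primary ids.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @param relations Character vector of relations to treat as parent edges.
#'   Default `c("is_a", "part_of")`, standard GOA propagation practice;
#'   use `"is_a"` to restrict to subsumption only. `regulates` is never
#'   followed.
#' @return An object of class `go_ontology`: a list with elements
#'   `terms` (data.frame: id, name, aspect, obsolete), `parents`
#'   (named list mapping each non-obsolete id to its parent ids),
#'   `alt_id` (named character vector alt -> primary), and `roots`
#'   (named character vector, one root id per aspect present).
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: molecular_function",
#'          "", "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: molecular_function", "is_a: GO:0000001 ! root")
#' onto <- parse_obo(obo)
#' ancestors(onto, "GO:0000002")
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  # split into [Term] stanzas
  is_header <- grepl("^\\[", lines)
  stanza_id <- cumsum(is_header)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("no [Term] stanzas found in OBO input")

  ids <- character(0); names_ <- character(0); aspects <- character(0)
  obsolete <- logical(0)
  parents <- list()
  alt_from <- character(0); alt_to <- character(0)

  for (s in term_starts) {
    sid <- stanza_id[s]
    body <- lines[which(stanza_id == sid)]
    body <- body[-1]                      # drop the [Term] header line
    body <- body[nzchar(body)]
    kv <- regmatches(body, regexec("^([A-Za-z_]+): *(.*)$", body))
    bad <- which(lengths(kv) != 3L & nzchar(body))
    if (length(bad)) {
      stop(sprintf("malformed OBO stanza line: '%s' (line %d of stanza)",
                   body[bad[1]], bad[1]))
    }
    keys <- vapply(kv, `[`, "", 2L)
    vals <- vapply(kv, `[`, "", 3L)
    id <- vals[keys == "id"][1]
    if (is.na(id)) stop("OBO [Term] stanza without an id")
    if (!grepl("^GO:\\d{7}$", id)) {
      stop(sprintf("term id '%s' does not match GO accession pattern", id))
    }
    obs <- any(keys == "is_obsolete" & grepl("^true", vals))
    nm <- vals[keys == "name"][1]
    ns <- vals[keys == "namespace"][1]
    asp <- if (is.na(ns)) NA_character_ else unname(.ASPECT_FROM_NAMESPACE[ns])

    par <- character(0)
    if (!obs) {
      if ("is_a" %in% relations) {
        isa <- vals[keys == "is_a"]
        par <- c(par, sub(" *!.*$", "", isa))
      }
      rel <- vals[keys == "relationship"]
      for (r in rel) {
        m <- regexec("^([a-z_]+) +(GO:\\d{7})", r)[[1]]
        if (m[1] != -1) {
          rr <- regmatches(r, regexec("^([a-z_]+) +(GO:\\d{7})", r))[[1]]
          if (rr[2] %in% setdiff(relations, "is_a")) par <- c(par, rr[3])
        }
      }
    }
    alts <- vals[keys == "alt_id"]
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }
    ids <- c(ids, id); names_ <- c(names_, nm %||% "")
    aspects <- c(aspects, asp); obsolete <- c(obsolete, obs)
    parents[[id]] <- unique(par)
  }

  terms <- data.frame(id = ids, name = names_, aspect = aspects,
                      obsolete = obsolete, stringsAsFactors = FALSE)
  dup <- duplicated(terms$id)
  if (any(dup)) {
    terms <- terms[!dup, , drop = FALSE]
  }
  rownames(terms) <- terms$id

  # drop parent edges that cross aspects (rare part_of cases) or point
  # outside the ontology, keep closure aspect-pure
  live <- terms$id[!terms$obsolete]
  asp_of <- stats::setNames(terms$aspect, terms$id)
  for (id in live) {
    p <- parents[[id]]
    p <- p[p %in% live & asp_of[p] == asp_of[id]]
    parents[[id]] <- unname(p)
  }
  parents <- parents[live]

  onto <- structure(list(terms = terms, parents = parents,
                         alt_id = stats::setNames(alt_to, alt_from),
                         roots = character(0)),
                    class = "go_ontology")
  .validate_acyclic(onto)
  root_ids <- live[lengths(parents[live]) == 0L]
  onto$roots <- stats::setNames(root_ids, asp_of[root_ids])
  onto
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

.validate_acyclic <- function(onto) {
  # Kahn topological sort over the live parent graph
  indeg <- lengths(onto$parents)        # edges child -> parent; count parents
  children <- list()
  for (id in names(onto$parents)) {
    for (p in onto$parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  # process terms whose parents are all processed: reverse Kahn on parents
  remaining <- names(onto$parents)
  done <- character(0)
  queue <- remaining[indeg[remaining] == 0L]
  npar <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    done <- c(done, t)
    for (ch in children[[t]]) {
      npar[ch] <- npar[ch] - 1L
      if (npar[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(done) != length(remaining)) {
    stop("cyclic is_a/part_of graph: ontology is not a DAG")
  }
  invisible(TRUE)
}

#' Ancestor closure of a GO term
#'
#' Transitive closure over the configured parent relations, excluding the
#' term itself and restricted to the term's aspect (parent edges never cross
#' aspects by construction).
#'
#' @param onto A `go_ontology`.
#' @param term A GO accession present and non-obsolete in `onto`.
#' @return Character vector of ancestor accessions (possibly empty).
#' @export
ancestors <- function(onto, term) {
  if (!term %in% names(onto$parents)) {
    stop(sprintf("unknown or obsolete GO accession: %s", term))
  }
  seen <- character(0)
  frontier <- onto$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(onto$parents[new], use.names = FALSE))
  }
  seen
}

# closure including the term itself, memoised across a whole annotation set
.closure_table <- function(onto, terms) {
  terms <- unique(terms)
  memo <- new.env(parent = emptyenv())
  get_cl <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    cl <- c(t, ancestors(onto, t))
    memo[[t]] <- cl
    cl
  }
  stats::setNames(lapply(terms, get_cl), terms)
}

#' Construct an annotation set
#'
#' An annotation set maps entities (proteins or domains) to GO terms with
#' their aspect. Stored as a unique-row data.frame.
#'
#' @param entity,term Character vectors of equal length.
#' @param onto A `go_ontology` used to resolve aspects, remap `alt_id`
#'   accessions to primary ids, and drop obsolete terms.
#' @return Object of class `annotation_set`: a data.frame with columns
#'   `entity`, `term`, `aspect`, plus an attribute `rejects` listing any
#'   accessions that could not be resolved.
#' @export
annotation_set <- function(entity, term, onto) {
  stopifnot(length(entity) == length(term))
  term <- ifelse(term %in% names(onto$alt_id),
                 unname(onto$alt_id[term]), term)
  known <- term %in% onto$terms$id
  rejects <- unique(term[!known])
  entity <- entity[known]; term <- term[known]
  obs <- onto$terms[term, "obsolete"]
  if (any(obs)) {
    warning(sprintf("dropping %d annotation rows to obsolete terms",
                    sum(obs)))
    entity <- entity[!obs]; term <- term[!obs]
  }
  df <- unique(data.frame(entity = entity, term = term,
                          aspect = onto$terms[term, "aspect"],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, class = c("annotation_set", "data.frame"),
            rejects = rejects)
}

#' Read a GAF 2.1/2.2 annotation file
#'
#' Uses columns 2 (object id), 4 (qualifier), 5 (GO id) and 9 (aspect).
#' Rows whose qualifier contains `NOT` are dropped; `alt_id` accessions are
#' remapped and unresolvable terms collected in the `rejects` attribute.
#'
#' @param path Path to a GAF file (comment lines start with `!`).
#' @param onto A `go_ontology`.
#' @return An `annotation_set`.
#' @export
read_gaf <- function(path, onto) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(annotation_set(character(0), character(0), onto))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9L)
  if (length(short)) {
    stop(sprintf("GAF line %d has fewer than 9 columns", short[1]))
  }
  obj <- vapply(fields, `[`, "", 2L)
  qual <- vapply(fields, `[`, "", 4L)
  go <- vapply(fields, `[`, "", 5L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  annotation_set(obj[keep], go[keep], onto)
}

#' True-path propagation of an annotation set
#'
#' Closes every entity's term set under ancestors (is_a/part_of as
#' configured in the ontology). Idempotent and monotone.
#'
#' @param anno An `annotation_set`.
#' @param onto The `go_ontology` the annotations resolve in.
#' @return A propagated `annotation_set`.
#' @export
propagate <- function(anno, onto) {
  if (nrow(anno) == 0L) return(anno)
  unknown <- setdiff(anno$term, names(onto$parents))
  if (length(unknown)) {
    stop(sprintf("unresolvable term(s) in annotation set: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  cl <- .closure_table(onto, anno$term)
  ent <- rep(anno$entity, times = lengths(cl[anno$term]))
  trm <- unlist(cl[anno$term], use.names = FALSE)
  df <- unique(data.frame(entity = ent, term = trm,
                          aspect = onto$terms[trm, "aspect"],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, class = c("annotation_set", "data.frame"),
            rejects = attr(anno, "rejects"))
}

#' @export
print.go_ontology <- function(x, ...) {
  live <- !x$terms$obsolete
  cat(sprintf("GO ontology: %d terms (%d obsolete), aspects: %s\n",
              nrow(x$terms), sum(!live),
              paste(sort(unique(x$terms$aspect[live])), collapse = "/")))
  invisible(x)
}
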