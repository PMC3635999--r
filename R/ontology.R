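# OBO ontology store: parsing, validation, is_a closure, catalogs.
#
# An ontology is held as a light S3 object:
#   id         short label, e.g. "GO"
#   title      human-readable title
#   category   catalog category tag ("Preferred" marks the curated subset)
#   terms      data.frame(accession, name, obsolete)
#   synonyms   data.frame(accession, synonym, scope)
#   parents    data.frame(child, parent)          -- is_a edges only
#   parent_map named list accession -> character vector of parent accessions
#
# Only is_a is retained: other OBO relationships (part_of, regulates, ...)
# are ignored during parsing because annotation propagation follows is_a
# exclusively.

SYNONYM_SCOPES <- c("EXACT", "RELATED", "BROAD", "NARROW")

new_ontology <- function(id, title, category, terms, synonyms, parents) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  terms$obsolete <- as.logical(terms$obsolete)
  if (anyDuplicated(terms$accession)) {
    oe_stop(sprintf("ontology %s: duplicate term accession(s): %s", id,
                    paste(unique(terms$accession[duplicated(terms$accession)]),
                          collapse = ", ")))
  }
  bad_name <- !terms$obsolete & !nzchar(trimws(terms$name))
  if (any(bad_name)) {
    oe_stop(sprintf("ontology %s: non-obsolete term(s) without a name: %s",
                    id, paste(terms$accession[bad_name], collapse = ", ")))
  }
  if (nrow(parents)) {
    unknown <- setdiff(unique(c(parents$child, parents$parent)),
                       terms$accession)
    if (length(unknown)) {
      oe_stop(sprintf("ontology %s: is_a reference(s) to unknown term(s): %s",
                      id, paste(unknown, collapse = ", ")))
    }
    self <- parents$child == parents$parent
    if (any(self)) {
      oe_stop(sprintf("ontology %s: term(s) listed as their own parent: %s",
                      id, paste(unique(parents$child[self]), collapse = ", ")))
    }
    parents <- unique(parents)
  }
  parent_map <- split(parents$parent,
                      factor(parents$child, levels = unique(parents$child)))
  cyc <- find_cycle(terms$accession, parent_map)
  if (!is.null(cyc)) {
    oe_stop(sprintf("ontology %s: cyclic is_a relationship: %s",
                    id, paste(cyc, collapse = " -> ")))
  }
  structure(
    list(id = id, title = title, category = category,
         terms = terms, synonyms = synonyms, parents = parents,
         parent_map = parent_map),
    class = "ontology"
  )
}

# Depth-first search over is_a edges; returns one cycle (as a vector of
# accessions ending where it started) or NULL if the graph is acyclic.
find_cycle <- function(accs, parent_map) {
  color <- new.env(parent = emptyenv())
  for (a in accs) assign(a, 0L, envir = color)
  stack <- character(0)
  cycle <- NULL
  visit <- function(a) {
    if (!is.null(cycle)) return(invisible())
    assign(a, 1L, envir = color)
    stack <<- c(stack, a)
    for (p in parent_map[[a]] %||% character(0)) {
      if (!is.null(cycle)) break
      cp <- get0(p, envir = color, ifnotfound = 2L)
      if (cp == 0L) {
        visit(p)
      } else if (cp == 1L) {
        i <- match(p, stack)
        cycle <<- c(stack[i:length(stack)], p)
      }
    }
    assign(a, 2L, envir = color)
    stack <<- stack[-length(stack)]
    invisible()
  }
  for (a in accs) {
    if (get(a, envir = color) == 0L) visit(a)
    if (!is.null(cycle)) break
  }
  cycle
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (`id`, `name`, `synonym`, `is_a`, `is_obsolete`;
#' unknown tags are ignored without error), retains only `is_a` edges and
#' validates the result: every parent reference must resolve, no term may be
#' its own parent and the is_a graph must be acyclic.  Obsolete terms are
#' loaded and flagged so that downstream steps (lexicon construction,
#' propagation, enrichment) can exclude them.
#'
#' @param path path to an OBO 1.2 flat file.
#' @param id short ontology label; defaults to the header `ontology:` tag
#'   (uppercased) or the file name.
#' @param title ontology title; defaults to `id`.
#' @param category catalog category tag (e.g. `"Preferred"`).
#' @return an object of class `"ontology"`.
#' @seealso [ancestors()], [build_lexicon()], [read_catalog()]
#' @export
parse_obo <- function(path, id = NULL, title = NULL, category = "General") {
  if (!file.exists(path)) oe_stop(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts) || !any(lines[starts] == "[Term]")) {
    oe_stop(sprintf("no [Term] stanza found in %s", path))
  }
  header <- lines[seq_len(starts[1] - 1L)]
  if (is.null(id)) {
    ont_line <- grep("^ontology:", header, value = TRUE)
    id <- if (length(ont_line)) {
      toupper(trimws(sub("^ontology:", "", ont_line[1])))
    } else {
      toupper(tools::file_path_sans_ext(basename(path)))
    }
  }
  bounds <- c(starts, length(lines) + 1L)

  acc <- name <- character(0)
  obsolete <- logical(0)
  syn_acc <- syn_text <- syn_scope <- character(0)
  par_child <- par_parent <- character(0)

  for (si in seq_along(starts)) {
    if (lines[starts[si]] != "[Term]") next
    from <- starts[si] + 1L
    to <- bounds[si + 1L] - 1L
    block_lines <- if (from <= to) seq(from, to) else integer(0)
    t_id <- NA_character_
    t_name <- ""
    t_obs <- FALSE
    t_syn <- list()
    t_par <- character(0)
    for (ln in block_lines) {
      raw <- lines[ln]
      if (!nzchar(trimws(raw)) || startsWith(raw, "!")) next
      m <- regmatches(raw, regexec("^([A-Za-z_]+):[ \t]*(.*)$", raw))[[1]]
      if (length(m) != 3L) {
        oe_stop(sprintf("%s: malformed line %d in [Term] stanza: '%s'",
                        path, ln, raw))
      }
      tag <- m[2]
      val <- trimws(m[3])
      if (tag == "id" && is.na(t_id)) {
        t_id <- val
      } else if (tag == "name" && !nzchar(t_name)) {
        t_name <- val
      } else if (tag == "is_a") {
        t_par <- c(t_par, trimws(sub("\\s*!.*$", "", val)))
      } else if (tag == "synonym") {
        sm <- regmatches(val, regexec("^\"(.*)\"\\s*([A-Z_]*)", val))[[1]]
        if (length(sm) != 3L) {
          oe_stop(sprintf("%s: malformed synonym at line %d: '%s'",
                          path, ln, raw))
        }
        scope <- if (sm[3] %in% SYNONYM_SCOPES) sm[3] else "RELATED"
        t_syn[[length(t_syn) + 1L]] <- c(sm[2], scope)
      } else if (tag == "is_obsolete") {
        t_obs <- identical(tolower(val), "true")
      } # other tags ignored
    }
    if (is.na(t_id) || !nzchar(t_id)) {
      oe_stop(sprintf("%s: [Term] stanza starting at line %d has no id",
                      path, starts[si]))
    }
    acc <- c(acc, t_id)
    name <- c(name, t_name)
    obsolete <- c(obsolete, t_obs)
    if (length(t_syn)) {
      syn_acc <- c(syn_acc, rep.int(t_id, length(t_syn)))
      syn_text <- c(syn_text, vapply(t_syn, `[`, "", 1L))
      syn_scope <- c(syn_scope, vapply(t_syn, `[`, "", 2L))
    }
    if (length(t_par)) {
      par_child <- c(par_child, rep.int(t_id, length(t_par)))
      par_parent <- c(par_parent, t_par)
    }
  }

  new_ontology(
    id = id,
    title = title %||% id,
    category = category,
    terms = data.frame(accession = acc, name = name, obsolete = obsolete,
                       stringsAsFactors = FALSE),
    synonyms = data.frame(accession = syn_acc, synonym = syn_text,
                          scope = syn_scope, stringsAsFactors = FALSE),
    parents = data.frame(child = par_child, parent = par_parent,
                         stringsAsFactors = FALSE)
  )
}

#' Write an ontology back to OBO 1.2
#'
#' Serializes the in-memory data model (terms, synonyms, is_a edges,
#' obsolete flags); parsing the output again yields an identical term and
#' edge set.
#'
#' @param ontology an `"ontology"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "ontology"))
  out <- c("format-version: 1.2",
           paste0("ontology: ", tolower(ontology$id)))
  name_of <- stats::setNames(ontology$terms$name, ontology$terms$accession)
  for (i in seq_len(nrow(ontology$terms))) {
    a <- ontology$terms$accession[i]
    out <- c(out, "", "[Term]", paste0("id: ", a),
             paste0("name: ", ontology$terms$name[i]))
    syn <- ontology$synonyms[ontology$synonyms$accession == a, , drop = FALSE]
    if (nrow(syn)) {
      out <- c(out, sprintf("synonym: \"%s\" %s []", syn$synonym, syn$scope))
    }
    par <- ontology$parents$parent[ontology$parents$child == a]
    if (length(par)) {
      out <- c(out, sprintf("is_a: %s ! %s", par, name_of[par]))
    }
    if (ontology$terms$obsolete[i]) out <- c(out, "is_obsolete: true")
  }
  writeLines(out, path)
  invisible(path)
}

#' Reflexive transitive is_a closure of a term
#'
#' Returns the term itself plus every ancestor reachable along `is_a`
#' edges.  Diamond-shaped paths contribute each ancestor once; annotating a
#' gene to a term therefore implicitly annotates it to exactly this set
#' (the true-path rule).
#'
#' @param ontology an `"ontology"` object.
#' @param accession term accession present in `ontology`.
#' @return sorted character vector of accessions, including `accession`.
#' @export
ancestors <- function(ontology, accession) {
  stopifnot(inherits(ontology, "ontology"))
  if (!accession %in% ontology$terms$accession) {
    oe_stop(sprintf("unknown term '%s' in ontology %s",
                    accession, ontology$id))
  }
  pm <- ontology$parent_map
  seen <- character(0)
  frontier <- accession
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(pm[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

# closure table for a set of accessions:
# data.frame(term_accession, ancestor_accession)
ancestor_table <- function(ontology, accessions) {
  accessions <- unique(accessions)
  closures <- lapply(accessions, function(a) ancestors(ontology, a))
  data.frame(
    term_accession = rep.int(accessions, lengths(closures)),
    ancestor_accession = unlist(closures, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology %s> %s [%s]: %d terms (%d obsolete), %d is_a edges, %d synonyms\n",
              x$id, x$title, x$category, nrow(x$terms),
              sum(x$terms$obsolete), nrow(x$parents), nrow(x$synonyms)))
  invisible(x)
}

#' Bundle ontologies into a catalog
#'
#' @param ontologies list of `"ontology"` objects with distinct ids.
#' @return an `"ontology_catalog"` object (named list of ontologies).
#' @export
ontology_catalog <- function(ontologies) {
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)
  if (!length(ontologies)) oe_stop("catalog needs at least one ontology",
                                   "oe_usage_error")
  ids <- vapply(ontologies, function(o) o$id, "")
  if (anyDuplicated(ids)) {
    oe_stop(sprintf("duplicate ontology id(s) in catalog: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(ontologies = stats::setNames(ontologies, ids)),
            class = "ontology_catalog")
}

#' Read a catalog manifest
#'
#' The manifest is a TSV with columns `id`, `title`, `category`, `path`;
#' `path` is resolved relative to the manifest's directory.  Each listed
#' OBO file is parsed with [parse_obo()].
#'
#' @param path manifest file path.
#' @return an `"ontology_catalog"`.
#' @export
read_catalog <- function(path) {
  man <- read_tsv(path, required = c("id", "title", "category", "path"))
  if (!nrow(man)) oe_stop(sprintf("empty catalog manifest: %s", path))
  base <- dirname(path)
  onts <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    parse_obo(p, id = man$id[i], title = man$title[i],
              category = man$category[i])
  })
  ontology_catalog(onts)
}

#' All terms of a catalog as one table
#'
#' @param catalog an `"ontology_catalog"`.
#' @return data.frame with columns `ontology_id`, `accession`, `name`,
#'   `obsolete`.
#' @export
catalog_terms <- function(catalog) {
  stopifnot(inherits(catalog, "ontology_catalog"))
  do.call(rbind, lapply(catalog$ontologies, function(o) {
    data.frame(ontology_id = o$id, accession = o$terms$accession,
               name = o$terms$name, obsolete = o$terms$obsolete,
               stringsAsFactors = FALSE, row.names = NULL)
  })) -> df
  rownames(df) <- NULL
  df
}

#' @export
print.ontology_catalog <- function(x, ...) {
  cat(sprintf("<ontology catalog: %d ontologies>\n", length(x$ontologies)))
  for (o in x$ontologies) print(o)
  invisible(x)
}
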