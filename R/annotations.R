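#' Ontology container
#'
#' A minimal directed-acyclic-graph representation of an ontology namespace:
#' term identifiers, their `is_a`/`part_of` parents and a namespace label per
#' term.
#'
#' @param terms Character vector of term identifiers.
#' @param parents Named list mapping each term to a character vector of parent
#'   terms (empty for roots). Terms missing from the list are treated as
#'   parentless.
#' @param namespace Named character vector of namespace labels, or a single
#'   label recycled for all terms.
#' @param names Optional named character vector of human-readable term names.
#' @return An object of class `ontology` with elements `terms`, `parents`,
#'   `namespace`, `term_names` and an igraph `graph` (edges child -> parent).
#' @export
ontology <- function(terms, parents = list(), namespace = "biological_process",
                     names = NULL) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(base::names(parents), terms)]
  full <- stats::setNames(vector("list", length(terms)), terms)
  full[base::names(parents)] <- lapply(parents, function(p) {
    p <- intersect(as.character(p), terms)
    p
  })
  full <- lapply(full, function(p) if (is.null(p)) character() else p)
  if (length(namespace) == 1L)
    namespace <- stats::setNames(rep(namespace, length(terms)), terms)
  edges <- data.frame(
    from = rep(terms, lengths(full)),
    to = unlist(full, use.names = FALSE),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g))
    stop("the parent relation contains a cycle; the ontology must be a DAG")
  structure(list(terms = terms, parents = full,
                 namespace = namespace, term_names = names, graph = g),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d parent edges, namespaces: %s\n",
              length(x$terms), sum(lengths(x$parents)),
              paste(unique(x$namespace), collapse = ", ")))
  invisible(x)
}

#' Parse an OBO 1.4 file
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` tags; obsolete terms are dropped. Only the
#' requested namespace is retained, and `part_of` edges leaving the namespace
#' are ignored.
#'
#' @param path Path to the OBO file.
#' @param namespace Namespace to keep; default `"biological_process"`.
#' @param relations Parent relations to follow; default `is_a` and `part_of`.
#' @return An [ontology()].
#' @export
read_obo <- function(path, namespace = "biological_process",
                     relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(); nss <- character(); nms <- character()
  parents <- list()
  for (i in seq_along(stanza_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!startsWith(block, "[")]
    get1 <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ": "))]
      if (length(v) == 0L) return(NA_character_)
      sub(paste0("^", tag, ": "), "", v[1])
    }
    if (!is.na(get1("is_obsolete")) && get1("is_obsolete") == "true") next
    id <- get1("id")
    if (is.na(id)) next
    par <- character()
    if ("is_a" %in% relations) {
      isa <- block[startsWith(block, "is_a: ")]
      par <- c(par, sub("^is_a: ([^ !]+).*$", "\\1", isa))
    }
    if ("part_of" %in% relations) {
      rel <- block[startsWith(block, "relationship: part_of ")]
      par <- c(par, sub("^relationship: part_of ([^ !]+).*$", "\\1", rel))
    }
    ids <- c(ids, id)
    nss <- c(nss, get1("namespace"))
    nms <- c(nms, get1("name"))
    parents[[id]] <- unique(par)
  }
  keep <- is.na(nss) | nss == namespace
  ids <- ids[keep]
  ontology(ids, parents[ids],
           namespace = stats::setNames(rep(namespace, length(ids)), ids),
           names = stats::setNames(nms[keep], ids))
}

#' Annotation set
#'
#' @param gene_terms Named list mapping gene identifiers to character vectors
#'   of annotated term identifiers.
#' @param propagated Logical; whether the set is closed under ancestor
#'   propagation.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(gene_terms, propagated = FALSE) {
  stopifnot(is.list(gene_terms))
  gene_terms <- lapply(gene_terms, function(t) unique(as.character(t)))
  structure(list(gene_terms = gene_terms, propagated = propagated),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d distinct terms (%spropagated)\n",
              length(x$gene_terms),
              length(unique(unlist(x$gene_terms))),
              if (x$propagated) "" else "not "))
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Keeps rows in the requested aspect whose evidence code is not excluded;
#' rows with a `NOT` qualifier and comment lines are dropped. Gene identity is
#' taken from the DB Object ID column.
#'
#' @param path Path to the GAF file.
#' @param exclude_evidence Evidence codes to drop; default `"IEA"`.
#' @param aspect GO aspect to keep: `"P"` (biological process, default),
#'   `"F"` or `"C"`.
#' @return An un-propagated [annotation_set()].
#' @export
read_gaf <- function(path, exclude_evidence = "IEA", aspect = "P") {
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  genes <- character(0); terms <- character(0)
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 15L)
      stop(sprintf("malformed GAF line %d: expected >= 15 tab-separated fields, got %d",
                   i, length(f)))
    if (grepl("(^|\\|)NOT(\\||$)", f[4])) next
    if (f[7] %in% exclude_evidence) next
    if (f[9] != aspect) next
    genes <- c(genes, f[2])
    terms <- c(terms, f[5])
  }
  annotation_set(split(terms, genes), propagated = FALSE)
}

.ancestors <- function(ont, term) {
  # all terms reachable through parent edges, excluding the term itself
  v <- igraph::subcomponent(ont$graph, term, mode = "out")
  setdiff(names(v), term)
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' Closes every gene's term set under the ontology's parent relation, so that
#' a gene annotated with a term is also annotated with all of the term's
#' ancestors. Idempotent.
#'
#' @param ann An [annotation_set()].
#' @param ont An [ontology()].
#' @return A propagated `annotation_set`. Terms not present in the ontology
#'   raise an error naming them.
#' @export
propagate <- function(ann, ont) {
  stopifnot(inherits(ann, "annotation_set"), inherits(ont, "ontology"))
  used <- unique(unlist(ann$gene_terms))
  unknown <- setdiff(used, ont$terms)
  if (length(unknown) > 0L)
    stop("annotated terms missing from the ontology: ",
         paste(unknown, collapse = ", "))
  anc <- lapply(stats::setNames(used, used), function(t) c(t, .ancestors(ont, t)))
  closed <- lapply(ann$gene_terms, function(ts) unique(unlist(anc[ts], use.names = FALSE)))
  annotation_set(closed, propagated = TRUE)
}

#' Binary label vector for one term
#'
#' @param ann A propagated [annotation_set()].
#' @param genes Ordered character vector of gene identifiers.
#' @param term Term identifier.
#' @return A `term_labels` object: list with `term` and the 0/1 integer vector
#'   `y` named by `genes`.
#' @export
term_labels <- function(ann, genes, term) {
  stopifnot(inherits(ann, "annotation_set"))
  y <- vapply(genes, function(g) as.integer(term %in% ann$gene_terms[[g]]), 1L)
  structure(list(term = term, y = stats::setNames(y, genes)),
            class = "term_labels")
}

#' Gene x term binary label matrix
#'
#' @param ann A propagated [annotation_set()].
#' @param genes Ordered gene identifiers (rows).
#' @param terms Term identifiers (columns); defaults to all annotated terms.
#' @param min_pos Keep only terms with at least this many positive genes
#'   (default 0 = keep all).
#' @return An integer 0/1 matrix, genes x terms.
#' @export
term_label_matrix <- function(ann, genes, terms = NULL, min_pos = 0L) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(terms)) terms <- sort(unique(unlist(ann$gene_terms[genes])))
  Y <- matrix(0L, length(genes), length(terms),
              dimnames = list(genes, terms))
  for (g in genes) {
    ts <- intersect(ann$gene_terms[[g]], terms)
    if (length(ts)) Y[g, ts] <- 1L
  }
  Y[, colSums(Y) >= min_pos, drop = FALSE]
}

#' Resnik information content
#'
#' `ic(t) = -log(n_t / n)` where `n_t` is the number of genes annotated with
#' `t` after propagation and `n` the number of annotated genes; natural log.
#' Terms annotated to every gene (in particular the root) have IC 0; terms
#' with no annotations are excluded from the output.
#'
#' @param ann A propagated [annotation_set()].
#' @param ont Optional [ontology()]; when given, only its terms are reported.
#' @return Named numeric vector of IC values.
#' @export
resnik_ic <- function(ann, ont = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!ann$propagated)
    stop("resnik_ic requires propagated annotations")
  counts <- table(unlist(lapply(ann$gene_terms, unique)))
  n <- length(ann$gene_terms)
  ic <- -log(as.numeric(counts) / n)
  names(ic) <- names(counts)
  if (!is.null(ont)) ic <- ic[names(ic) %in% ont$terms]
  ic
}

#' Maximum path length to the ontology root
#'
#' Length of the longest chain of parent edges from a term to a root of its
#' namespace (dynamic programme over a topological order).
#'
#' @param ont An [ontology()].
#' @param term Optional single term; when omitted, depths for all terms are
#'   returned.
#' @return Integer depth(s); roots have depth 0.
#' @export
max_path_to_root <- function(ont, term = NULL) {
  stopifnot(inherits(ont, "ontology"))
  ord <- names(igraph::topo_sort(ont$graph, mode = "in"))  # parents first
  depth <- stats::setNames(rep(NA_integer_, length(ont$terms)), ont$terms)
  for (t in ord) {
    p <- ont$parents[[t]]
    depth[t] <- if (length(p) == 0L) 0L else max(depth[p]) + 1L
  }
  if (is.null(term)) return(depth)
  if (!term %in% ont$terms) stop("term not in ontology: ", term)
  if (is.na(depth[term])) stop("term disconnected from the root: ", term)
  unname(depth[term])
}

#' Term specificity table
#'
#' @param ann A propagated [annotation_set()].
#' @param ont An [ontology()].
#' @return A data.frame with columns `term`, `resnik_ic`, `max_root_path` for
#'   every annotated ontology term.
#' @export
term_specificity <- function(ann, ont) {
  ic <- resnik_ic(ann, ont)
  depth <- max_path_to_root(ont)
  data.frame(term = names(ic), resnik_ic = unname(ic),
             max_root_path = unname(depth[names(ic)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
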