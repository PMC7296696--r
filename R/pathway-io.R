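#' Read a KGML (KEGG pathway XML) file into a pathway graph
#'
#' Nodes are the gene identifiers of KGML `entry` elements of type
#' `"gene"`: an entry whose `name` attribute lists several ids (e.g.
#' `"hsa:1 hsa:2"`) fans out into one node per id. `group` entries expand
#' to the gene ids of their `component` entries. `map` and `compound`
#' entries are skipped, as are `maplink` relations. Each `relation`
#' element contributes the directed edges of the cartesian product of its
#' endpoint entries' gene ids; a relation referencing an unknown or
#' non-gene entry is skipped with a warning. The resulting graph is
#' deduplicated and self-loop-free per [pathway_graph()].
#'
#' @param path KGML file path.
#' @param pathway_id label; defaults to the KGML `name`/`title` attribute,
#'   else the file name.
#' @param relation_types optional character vector restricting relations
#'   by their `type` attribute (e.g. `c("PPrel", "GErel")`); `NULL` keeps
#'   every non-maplink relation.
#' @return a `pathway_graph`.
#' @export
read_kgml <- function(path, pathway_id = NULL, relation_types = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("KGML parse failure for ", path,
                                           ": ", conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document (no <pathway> root): ", path)
  if (is.null(pathway_id)) {
    pathway_id <- xml2::xml_attr(root, "name")
    if (is.na(pathway_id)) pathway_id <- sub("\\.[^.]*$", "", basename(path))
  }
  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")

  # entry id -> character vector of gene ids (empty for skipped entries)
  genes_of <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    genes_of[[i]] <- if (identical(types[i], "gene")) {
      strsplit(trimws(names_attr[i]), "\\s+")[[1]]
    } else character(0)
  }
  # groups expand to their components' gene ids
  for (i in which(types == "group")) {
    comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "component"), "id")
    genes_of[[i]] <- unique(unlist(genes_of[comp], use.names = FALSE))
  }

  all_nodes <- unique(unlist(genes_of, use.names = FALSE))
  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  from <- character(0); to <- character(0)
  for (r in rels) {
    rtype <- xml2::xml_attr(r, "type")
    if (identical(rtype, "maplink")) next
    if (!is.null(relation_types) && !(rtype %in% relation_types)) next
    e1 <- xml2::xml_attr(r, "entry1"); e2 <- xml2::xml_attr(r, "entry2")
    if (!(e1 %in% ids) || !(e2 %in% ids)) {
      warning("relation references unknown entry (", e1, " -> ", e2,
              ") in ", pathway_id, "; skipped")
      next
    }
    g1 <- genes_of[[e1]]; g2 <- genes_of[[e2]]
    if (!length(g1) || !length(g2)) next  # endpoint is map/compound/empty group
    pairs <- expand.grid(g1, g2, stringsAsFactors = FALSE)
    from <- c(from, pairs[[1]]); to <- c(to, pairs[[2]])
  }
  if (!length(all_nodes)) stop("KGML file contains no gene entries: ", path)
  suppressWarnings(  # self-loop removal warning is routine for KGML autoregulation
    pathway_graph(cbind(from, to), nodes = all_nodes, pathway_id = pathway_id)
  )
}

#' Gene set container
#'
#' @param name set label.
#' @param genes character vector of gene identifiers (deduplicated).
#' @return object of class `gene_set` with elements `name`, `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene set: ", name)
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets (GMT or one-gene-per-line list)
#'
#' GMT rows are `name<TAB>description<TAB>gene1<TAB>gene2...`, one
#' [gene_set()] per row. A plain list file yields a single set named after
#' the file. Duplicate identifiers are collapsed.
#'
#' @param path file path.
#' @param format `"gmt"` or `"list"`; default guesses from the extension.
#' @return list of `gene_set` objects.
#' @export
read_gene_set <- function(path, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such gene-set file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  if (format == "list") {
    return(list(gene_set(sub("\\.[^.]*$", "", basename(path)), trimws(lines))))
  }
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT row (need name, description, >=1 gene): ", l)
    gene_set(f[1], f[-(1:2)])
  })
}

#' Write gene sets to GMT
#'
#' @param sets a `gene_set` or list of them.
#' @param path output file.
#' @param description description column (recycled).
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  rows <- vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), "")
  writeLines(rows, path)
  invisible(path)
}

#' Union of gene sets
#' @param sets list of `gene_set`s.
#' @param name label for the union.
#' @return a `gene_set`.
#' @export
gene_set_union <- function(sets, name = "union") {
  gene_set(name, unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
}

#' Pathway quality filters
#'
#' Applies, in this fixed order, the pathway quality criteria used before
#' any validation analysis; the first failing rule is the recorded reason:
#' \enumerate{
#'   \item `too_large`: node count > `max_nodes` AND edge count >
#'     `max_edges` (both must exceed);
#'   \item `too_small`: node count <= `min_nodes` OR edge count <=
#'     `min_edges`;
#'   \item `eigenvalue`: adjacency spectral radius > `eigen_limit`, or the
#'     configured Katz alpha violates its convergence margin
#'     (`katz_alpha >= 0.999 / lambda1`), so every kept pathway is
#'     computable by every configured model;
#'   \item `constant_centrality`: any configured centrality model (at its
#'     default parameters) yields a constant score vector;
#'   \item `too_few_important`: 5 or fewer of the pathway's nodes are in
#'     the important set (`|V intersect R| <= min_important`).
#' }
#'
#' @param graphs list of `pathway_graph`s.
#' @param important a `gene_set` of a-priori important genes.
#' @param katz_alpha Katz dampening factor used in the eigenvalue rule and
#'   the constant-centrality probe.
#' @param models model/variant grid probed by the constant-centrality
#'   rule; defaults to [default_models()].
#' @param max_nodes,max_edges,min_nodes,min_edges,eigen_limit,min_important
#'   rule thresholds (defaults: 1000, 4000, 20, 20, 10, 5).
#' @return list with `kept` (list of graphs) and `report` (data frame with
#'   columns `pathway_id, decision, reason, n_nodes, n_edges, lambda1,
#'   n_important`).
#' @export
filter_pathways <- function(graphs, important, katz_alpha = 0.1,
                            models = default_models(),
                            max_nodes = 1000, max_edges = 4000,
                            min_nodes = 20, min_edges = 20,
                            eigen_limit = 10, min_important = 5) {
  stopifnot(inherits(important, "gene_set"))
  rep_rows <- vector("list", length(graphs))
  keep <- logical(length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    n <- n_nodes(g); m <- n_edges(g)
    lam <- if (m > 0) spectral_radius(g) else 0
    n_imp <- length(intersect(g$nodes, important$genes))
    reason <- "none"
    if (n > max_nodes && m > max_edges) {
      reason <- "too_large"
    } else if (n <= min_nodes || m <= min_edges) {
      reason <- "too_small"
    } else if (lam > eigen_limit || (lam > 0 && katz_alpha >= 0.999 / lam)) {
      reason <- "eigenvalue"
    } else if (any_constant_profile(g, models, katz_alpha)) {
      reason <- "constant_centrality"
    } else if (n_imp <= min_important) {
      reason <- "too_few_important"
    }
    keep[i] <- reason == "none"
    rep_rows[[i]] <- data.frame(
      pathway_id = g$pathway_id,
      decision = if (keep[i]) "kept" else "excluded",
      reason = reason, n_nodes = n, n_edges = m, lambda1 = lam,
      n_important = n_imp, stringsAsFactors = FALSE
    )
  }
  list(kept = graphs[keep], report = do.call(rbind, rep_rows))
}

any_constant_profile <- function(g, models, katz_alpha) {
  for (i in seq_len(nrow(models))) {
    a <- if (models$model[i] == "katz") katz_alpha else NULL
    p <- centrality(g, models$model[i], models$variant[i], alpha = a)
    if (diff(range(p$scores)) == 0) return(TRUE)
  }
  FALSE
}

#' Write a filter report to TSV
#' @param report data frame from [filter_pathways()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
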