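#' Default centrality parameters
#'
#' Per-model defaults for the dampening factor `alpha` and the constant
#' restart/seed value `beta`: PageRank `alpha = 0.85`, `beta = 0.15`;
#' Katz `alpha = 0.1`, `beta = 1`; Laplacian `alpha = 0.85`, `beta = 1`.
#' `beta` is a scalar broadcast to a constant vector of length n -- note in
#' particular that this PageRank is the literal linear-system form
#' `C = (I - alpha * t(A) %*% solve(D_out))^{-1} beta` with out-degrees
#' clamped at 1: there is no dangling-node mass redistribution and no
#' sum-to-one renormalization, which differs from textbook PageRank.
#'
#' @param model one of `"pagerank"`, `"katz"`, `"laplacian"`.
#' @return list with elements `alpha`, `beta`.
#' @export
default_params <- function(model) {
  switch(model,
    pagerank  = list(alpha = 0.85, beta = 0.15),
    katz      = list(alpha = 0.1,  beta = 1),
    laplacian = list(alpha = 0.85, beta = 1),
    degree    = ,
    closeness = list(alpha = NA_real_, beta = NA_real_),
    stop("unknown model: ", model)
  )
}

#' Default model/variant grid
#'
#' The twelve (model, variant) pairs analysed by default: total degree,
#' the four PageRank variants (source, sink, SSC, undirected), the three
#' Katz and three Laplacian variants (source, sink, SSC), and SSC
#' closeness. Katz and Laplacian have no undirected variant here (the
#' undirected Katz needs a globally small alpha; the undirected Laplacian
#' is constant on connected components).
#'
#' @return data frame with columns `model`, `variant`.
#' @export
default_models <- function() {
  data.frame(
    model = c("degree",
              rep("pagerank", 4), rep("katz", 3), rep("laplacian", 3),
              "closeness"),
    variant = c("ssc",
                "source", "sink", "ssc", "undirected",
                "source", "sink", "ssc",
                "source", "sink", "ssc",
                "ssc"),
    stringsAsFactors = FALSE
  )
}

new_profile <- function(g, model, variant, alpha, beta, scores) {
  names(scores) <- g$nodes
  structure(
    list(pathway_id = g$pathway_id, model = model, variant = variant,
         alpha = alpha, beta = beta, scores = scores),
    class = "centrality_profile"
  )
}

#' @export
print.centrality_profile <- function(x, ...) {
  cat("<centrality_profile> ", x$pathway_id, ": ", x$model, "/", x$variant,
      if (!is.na(x$alpha)) paste0(" (alpha=", x$alpha, ", beta=", x$beta, ")"),
      ", ", length(x$scores), " nodes\n", sep = "")
  invisible(x)
}

#' Shared linear solver for the spectral centralities
#'
#' Every spectral centrality here is the fixed point of
#' `C = beta + M %*% C` for a non-negative operator `M` with spectral
#' radius below one. `closed_form` solves `(I - M) C = beta` directly;
#' `iterative` runs the fixed-point recurrence from `C0 = beta` until the
#' max-norm change drops below `tol` (default 1e-12, capped at 10000
#' iterations). The two agree within 1e-9 max-norm whenever the
#' contraction condition holds.
#'
#' @param M square iteration matrix.
#' @param beta numeric seed vector (or scalar, broadcast).
#' @param method `"closed_form"` or `"iterative"`.
#' @param tol max-norm stopping tolerance for the iterative method.
#' @param max_iter iteration cap.
#' @return numeric score vector.
#' @export
solve_spectral <- function(M, beta, method = c("closed_form", "iterative"),
                           tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  n <- nrow(M)
  b <- rep_len(beta, n)
  if (method == "closed_form") {
    x <- tryCatch(solve(diag(n) - M, b),
                  error = function(e) stop("singular centrality system: ",
                                           conditionMessage(e)))
    return(as.vector(x))
  }
  x <- b
  for (k in seq_len(max_iter)) {
    x_new <- b + as.vector(M %*% x)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  stop("fixed-point iteration did not converge in ", max_iter,
       " iterations (last residual ", format(max(abs(as.vector(M %*% x) + b - x))),
       ")")
}

#' Degree centrality
#'
#' Total degree `out + in` (the `ssc` variant, the paper-standard degree
#' centrality, equal to the undirected degree when no node pair has
#' reciprocal edges). `source` is the out-degree, `sink` the in-degree,
#' and `undirected` the degree of the underlying undirected graph. No
#' clamping is applied to these values.
#'
#' @param g a `pathway_graph`.
#' @param variant one of `"ssc"`, `"source"`, `"sink"`, `"undirected"`.
#' @return a `centrality_profile`.
#' @export
degree_centrality <- function(g, variant = "ssc") {
  variant <- match.arg(variant, c("ssc", "source", "sink", "undirected"))
  d <- degrees(g)
  scores <- switch(variant,
    source = d$out,
    sink = d$in_,
    ssc = d$out + d$in_,
    undirected = degrees(underlying_undirected(g))$out
  )
  new_profile(g, "degree", variant, NA_real_, NA_real_, as.numeric(scores))
}

#' PageRank centrality (source / sink / SSC / undirected)
#'
#' The sink variant is the standard PageRank fixed point
#' `C = beta + alpha * t(A) %*% solve(D_out) %*% C`, scoring nodes as
#' receivers of signal (a node with no incoming edges scores exactly
#' `beta`). The source variant applies the same model to the transposed
#' graph, `C = (I - alpha * A %*% solve(D_in))^{-1} beta`, scoring nodes
#' as senders. SSC is the elementwise sum of the two computed at the same
#' `(alpha, beta)`; the undirected variant runs the sink model on the
#' underlying undirected graph (where source and sink coincide).
#'
#' @param g a `pathway_graph`.
#' @param variant `"source"`, `"sink"`, `"ssc"`, or `"undirected"`.
#' @param alpha dampening factor in (0, 1).
#' @param beta positive restart constant (broadcast to all nodes).
#' @param method passed to [solve_spectral()].
#' @param tol iterative tolerance, passed to [solve_spectral()].
#' @return a `centrality_profile`.
#' @export
pagerank_centrality <- function(g, variant = c("ssc", "source", "sink", "undirected"),
                                alpha = 0.85, beta = 0.15,
                                method = "closed_form", tol = 1e-12) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1, beta > 0)
  if (variant == "undirected") {
    u <- underlying_undirected(g)
    b <- adjacency_bundle(u)
    scores <- solve_spectral(alpha * t(b$A / b$d_out), beta, method, tol)
    return(new_profile(g, "pagerank", variant, alpha, beta, scores))
  }
  b <- adjacency_bundle(g)
  sink_M <- function() alpha * t(b$A / b$d_out)            # alpha A^T D_out^-1
  src_M  <- function() alpha * t(t(b$A) / b$d_in)          # alpha A D_in^-1
  scores <- switch(variant,
    sink = solve_spectral(sink_M(), beta, method, tol),
    source = solve_spectral(src_M(), beta, method, tol),
    ssc = solve_spectral(src_M(), beta, method, tol) +
          solve_spectral(sink_M(), beta, method, tol)
  )
  new_profile(g, "pagerank", variant, alpha, beta, scores)
}

#' Katz centrality (source / sink / SSC)
#'
#' The source variant is standard Katz on the directed graph,
#' `C = (I - alpha * A)^{-1} beta`; the sink variant is Katz on the
#' transposed graph, `C = (I - alpha * t(A))^{-1} beta`; SSC is their
#' elementwise sum at the same `(alpha, beta)`. Convergence requires
#' `alpha < 1 / lambda1` (largest adjacency eigenvalue); the computation
#' is refused with a small safety margin when
#' `alpha >= 0.999 / lambda1`. Both components share the same convergence
#' condition. No undirected variant is offered.
#'
#' @inheritParams pagerank_centrality
#' @param variant `"source"`, `"sink"`, or `"ssc"`.
#' @param alpha dampening factor, `alpha > 0`.
#' @param beta positive seed constant.
#' @return a `centrality_profile`.
#' @export
katz_centrality <- function(g, variant = c("ssc", "source", "sink"),
                            alpha = 0.1, beta = 1,
                            method = "closed_form", tol = 1e-12) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, beta > 0)
  lam <- spectral_radius(g)
  if (lam > 0 && alpha >= 0.999 / lam) {
    stop("Katz convergence condition violated for pathway '", g$pathway_id,
         "': lambda1 = ", format(lam), ", need alpha < ",
         format(0.999 / lam), " (got ", alpha, ")")
  }
  A <- adjacency_matrix(g)
  scores <- switch(variant,
    source = solve_spectral(alpha * A, beta, method, tol),
    sink = solve_spectral(alpha * t(A), beta, method, tol),
    ssc = solve_spectral(alpha * A, beta, method, tol) +
          solve_spectral(alpha * t(A), beta, method, tol)
  )
  new_profile(g, "katz", variant, alpha, beta, scores)
}

#' Laplacian influence centrality (source / sink / SSC)
#'
#' A directed influence model in which a node's centrality relates to the
#' average centrality of its out-neighbors:
#' source `C = (I - alpha * solve(D_out) %*% A)^{-1} beta`, sink
#' `C = (I - alpha * solve(D_in) %*% t(A))^{-1} beta`, SSC their sum at
#' the same `(alpha, beta)`. Equivalent to the geometric (influence-
#' matrix) series `sum_k (alpha * D^{-1} A)^k beta`. The undirected form
#' is constant on connected components and is not offered.
#'
#' @inheritParams katz_centrality
#' @param alpha dampening factor in (0, 1).
#' @return a `centrality_profile`.
#' @export
laplacian_centrality <- function(g, variant = c("ssc", "source", "sink"),
                                 alpha = 0.85, beta = 1,
                                 method = "closed_form", tol = 1e-12) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1, beta > 0)
  b <- adjacency_bundle(g)
  src_M  <- function() alpha * (b$A / b$d_out)             # alpha D_out^-1 A
  sink_M <- function() alpha * (t(b$A) / b$d_in)           # alpha D_in^-1 A^T
  scores <- switch(variant,
    source = solve_spectral(src_M(), beta, method, tol),
    sink = solve_spectral(sink_M(), beta, method, tol),
    ssc = solve_spectral(src_M(), beta, method, tol) +
          solve_spectral(sink_M(), beta, method, tol)
  )
  new_profile(g, "laplacian", variant, alpha, beta, scores)
}

igraph_from <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = TRUE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  ig
}

#' Harmonic closeness centrality (source / sink / SSC / undirected)
#'
#' Source closeness of `v` is `sum_u 1/d(v, u)` over nodes reachable from
#' `v` (unit edge lengths; unreachable pairs contribute 0 and `d(v, v)` is
#' excluded). Sink closeness uses distances into `v`, SSC is their sum,
#' and the undirected variant runs the source form on the underlying
#' undirected graph. Shortest-path distances come from igraph.
#'
#' @param g a `pathway_graph`.
#' @param variant `"source"`, `"sink"`, `"ssc"`, or `"undirected"`.
#' @return a `centrality_profile`.
#' @export
closeness_centrality <- function(g, variant = c("ssc", "source", "sink", "undirected")) {
  variant <- match.arg(variant)
  gg <- if (variant == "undirected") underlying_undirected(g) else g
  n <- length(gg$nodes)
  if (nrow(gg$edges) == 0L) {
    return(new_profile(g, "closeness", variant, NA_real_, NA_real_, rep(0, n)))
  }
  ig <- igraph_from(gg)
  d <- igraph::distances(ig, mode = "out")  # d[v, u] = distance v -> u
  d <- d[g$nodes, g$nodes]                  # restore stable node order
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  scores <- switch(variant,
    source = rowSums(inv),
    undirected = rowSums(inv),
    sink = colSums(inv),
    ssc = rowSums(inv) + colSums(inv)
  )
  new_profile(g, "closeness", variant, NA_real_, NA_real_, as.numeric(scores))
}

#' Compute one centrality profile
#'
#' Dispatcher over the five centrality families. `alpha`/`beta` default to
#' [default_params()] for the model and are ignored by degree and
#' closeness.
#'
#' @param g a `pathway_graph`.
#' @param model `"degree"`, `"pagerank"`, `"katz"`, `"laplacian"`, or
#'   `"closeness"`.
#' @param variant model variant (see the model-specific functions).
#' @param alpha,beta spectral parameters; `NULL` means the model default.
#' @param method,tol passed to [solve_spectral()] for spectral models.
#' @return a `centrality_profile`.
#' @export
centrality <- function(g, model, variant = "ssc", alpha = NULL, beta = NULL,
                       method = "closed_form", tol = 1e-12) {
  model <- match.arg(model, c("degree", "pagerank", "katz", "laplacian", "closeness"))
  p <- default_params(model)
  if (is.null(alpha)) alpha <- p$alpha
  if (is.null(beta)) beta <- p$beta
  switch(model,
    degree = degree_centrality(g, variant),
    pagerank = pagerank_centrality(g, variant, alpha, beta, method, tol),
    katz = katz_centrality(g, variant, alpha, beta, method, tol),
    laplacian = laplacian_centrality(g, variant, alpha, beta, method, tol),
    closeness = closeness_centrality(g, variant)
  )
}

#' Compute a set of centrality profiles
#'
#' @param g a `pathway_graph`.
#' @param models data frame with columns `model`, `variant` and optional
#'   `alpha`, `beta` (defaults to [default_models()]).
#' @return list of `centrality_profile`s, named `model.variant`.
#' @export
centrality_profiles <- function(g, models = default_models()) {
  out <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    a <- if ("alpha" %in% names(models)) models$alpha[i] else NULL
    b <- if ("beta" %in% names(models)) models$beta[i] else NULL
    if (!is.null(a) && is.na(a)) a <- NULL
    if (!is.null(b) && is.na(b)) b <- NULL
    out[[i]] <- centrality(g, models$model[i], models$variant[i], a, b)
  }
  names(out) <- paste(models$model, models$variant, sep = ".")
  out
}

#' Serialize centrality profiles to TSV
#'
#' Columns `pathway_id, node_id, model, variant, alpha, beta, score` at
#' full float precision (round-trip exact via 17 significant digits).
#'
#' @param profiles list of `centrality_profile`s.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "centrality_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(pathway_id = p$pathway_id, node_id = names(p$scores),
               model = p$model, variant = p$variant,
               alpha = format(p$alpha, digits = 17),
               beta = format(p$beta, digits = 17),
               score = format(p$scores, digits = 17),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
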