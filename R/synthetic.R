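#' Specification for synthetic pathway cohorts
#'
#' Describes a cohort of layered, pathway-like directed graphs with
#' planted important genes. Graphs emulate the upstream-to-downstream
#' organization of signaling pathways: a narrow first layer (receptors), a
#' wider middle cascade, and a narrow last layer (effectors/transcription
#' factors). The two terminal interfaces are attached more densely than
#' the middle ones (factor 2.5 on `p_forward`, capped at 1), reflecting
#' the broadcast role of receptors and the convergence onto effectors;
#' this is what makes terminal nodes topologically prominent.
#'
#' @param n_pathways number of pathways in the cohort.
#' @param layers number of layers (>= 3 so upstream, middle and downstream
#'   all exist).
#' @param nodes_per_layer length-2 integer range for middle-layer widths;
#'   terminal layers are narrow (2-3 nodes).
#' @param p_forward edge probability between adjacent middle layers.
#' @param p_skip probability of a forward layer-skipping edge.
#' @param p_feedback probability of a backward (feedback) edge; the
#'   default 0 keeps graphs acyclic (adjacency spectral radius 0, so Katz
#'   converges at any alpha).
#' @param hub_fraction fraction of middle-layer nodes designated hubs;
#'   hubs get a 3x connection-probability boost (capped at 1).
#' @param importance_model `"terminal_ends"` (important genes drawn from
#'   the first and last layers at `importance_rate`, from middle layers at
#'   `importance_rate / 4`), `"hubs"` (drawn from designated hubs at
#'   `importance_rate`), or `"uniform"` (i.i.d. over all nodes).
#' @param importance_rate marking probability for designated nodes.
#' @param seed integer; the cohort is fully deterministic given the seed,
#'   and pathway `k` uses derived seed `seed + k` so cohorts are stable
#'   under changes to `n_pathways`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pathways = 150, layers = 5,
                           nodes_per_layer = c(6, 12),
                           p_forward = 0.35, p_skip = 0.05, p_feedback = 0,
                           hub_fraction = 0.1,
                           importance_model = c("terminal_ends", "hubs", "uniform"),
                           importance_rate = 0.6, seed = 1L) {
  importance_model <- match.arg(importance_model)
  if (layers < 3) stop("layers must be >= 3 (upstream, middle, downstream)")
  for (p in c(p_forward, p_skip, p_feedback, hub_fraction, importance_rate)) {
    if (is.na(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (n_pathways < 1) stop("n_pathways must be >= 1")
  if (length(nodes_per_layer) != 2L || nodes_per_layer[1] > nodes_per_layer[2] ||
      nodes_per_layer[1] < 1) {
    stop("nodes_per_layer must be an increasing range of positive counts")
  }
  structure(
    list(n_pathways = as.integer(n_pathways), layers = as.integer(layers),
         nodes_per_layer = as.integer(nodes_per_layer),
         p_forward = p_forward, p_skip = p_skip, p_feedback = p_feedback,
         hub_fraction = hub_fraction, importance_model = importance_model,
         importance_rate = importance_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

generate_pathway <- function(spec, k) {
  with_seed(spec$seed + k, {
    L <- spec$layers
    widths <- integer(L)
    widths[1] <- sample(2:3, 1)
    widths[L] <- sample(2:3, 1)
    if (L > 2) {
      widths[2:(L - 1)] <- sample(seq(spec$nodes_per_layer[1],
                                      spec$nodes_per_layer[2]), L - 2,
                                  replace = TRUE)
    }
    layer_of <- rep(seq_len(L), widths)
    n <- length(layer_of)
    idx_in_layer <- sequence(widths)
    ids <- sprintf("p%d_l%d_n%d", k, layer_of, idx_in_layer)

    mid <- which(layer_of > 1 & layer_of < L)
    n_hubs <- min(length(mid), ceiling(spec$hub_fraction * n))
    hubs <- if (n_hubs > 0) sort(sample(mid, n_hubs)) else integer(0)
    boost <- rep(1, n); boost[hubs] <- 3

    p_terminal <- min(1, 2.5 * spec$p_forward)
    from <- integer(0); to <- integer(0)
    for (j in seq_len(L - 1)) {
      u <- which(layer_of == j); v <- which(layer_of == j + 1)
      base_p <- if (j == 1 || j == L - 1) p_terminal else spec$p_forward
      pm <- outer(boost[u], boost[v]) * base_p
      pm[pm > 1] <- 1
      hit <- which(matrix(stats::runif(length(u) * length(v)),
                          length(u)) < pm, arr.ind = TRUE)
      from <- c(from, u[hit[, 1]]); to <- c(to, v[hit[, 2]])
    }
    if (spec$p_skip > 0 && L > 2) {
      for (j in seq_len(L - 2)) {
        u <- which(layer_of == j); v <- which(layer_of > j + 1)
        hit <- which(matrix(stats::runif(length(u) * length(v)),
                            length(u)) < spec$p_skip, arr.ind = TRUE)
        from <- c(from, u[hit[, 1]]); to <- c(to, v[hit[, 2]])
      }
    }
    if (spec$p_feedback > 0) {
      # feedback follows the canonical signaling motif: downstream
      # effectors feeding back onto upstream receptors (last -> first layer)
      u <- which(layer_of == L); v <- which(layer_of == 1L)
      hit <- which(matrix(stats::runif(length(u) * length(v)),
                          length(u)) < spec$p_feedback, arr.ind = TRUE)
      from <- c(from, u[hit[, 1]]); to <- c(to, v[hit[, 2]])
    }
    # connectivity guarantees: every non-first-layer node receives >= 1
    # edge from the previous layer; every non-last-layer node sends >= 1
    for (v in which(layer_of > 1)) {
      if (!any(to == v)) {
        u <- which(layer_of == layer_of[v] - 1)
        pick <- u[sample.int(length(u), 1)]
        from <- c(from, pick); to <- c(to, v)
      }
    }
    for (u in which(layer_of < L)) {
      if (!any(from == u)) {
        v <- which(layer_of == layer_of[u] + 1)
        pick <- v[sample.int(length(v), 1)]
        from <- c(from, u); to <- c(to, pick)
      }
    }
    keep <- !duplicated(from + to * (n + 1L))
    g <- pathway_graph(cbind(ids[from[keep]], ids[to[keep]]), nodes = ids,
                       pathway_id = sprintf("p%d", k))

    important <- switch(spec$importance_model,
      terminal_ends = {
        rate <- ifelse(layer_of %in% c(1L, L), spec$importance_rate,
                       spec$importance_rate / 4)
        ids[stats::runif(n) < rate]
      },
      hubs = ids[hubs][stats::runif(length(hubs)) < spec$importance_rate],
      uniform = ids[stats::runif(n) < spec$importance_rate]
    )
    list(graph = g, important = important)
  })
}

#' Generate a synthetic pathway cohort
#'
#' Produces `spec$n_pathways` layered directed graphs plus the planted
#' important-gene set, fully deterministic given `spec$seed` (the global
#' RNG state is left untouched). Node ids encode pathway, layer, and
#' position (`p{k}_l{j}_n{i}`) so positional claims can be asserted
#' without auxiliary tables.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_cohort`: list with `graphs` (list of
#'   `pathway_graph`s), `important` (a `gene_set`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- lapply(seq_len(spec$n_pathways), function(k) generate_pathway(spec, k))
  imp <- unlist(lapply(out, `[[`, "important"), use.names = FALSE)
  if (!length(imp)) imp <- out[[1]]$graph$nodes[1]  # degenerate draw: keep the set non-empty
  structure(
    list(graphs = lapply(out, `[[`, "graph"),
         important = gene_set("planted_important", imp),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$graphs), " pathways (",
      x$spec$importance_model, " importance), ",
      length(x$important$genes), " planted important genes\n", sep = "")
  invisible(x)
}

#' Expected direction of the validation regression slope
#'
#' Qualitative contract for what the quantile-regression slope should do
#' on cohorts from a given spec. Under `terminal_ends`, path-counting and
#' random-walk SSC variants (Katz, PageRank, closeness, degree) and
#' undirected PageRank recover a positive slope, pure source and pure sink
#' variants sit near zero (the two planted ends cancel), and Laplacian SSC
#' is negative: its neighbor-averaging recurrence accumulates with depth
#' from each end, a concave quantity whose sum peaks mid-cascade, so on
#' homogeneous layered DAGs the planted terminal nodes rank low. Under
#' `hubs`, degree and the degree-sensitive spectral variants are positive
#' (Laplacian, which averages away degree, stays near zero). Under
#' `uniform` there is no planted structure and every slope is near zero.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with columns `model`, `variant`,
#'   `expected_slope` in `{"positive", "zero", "negative"}`.
#' @export
expected_signal <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- default_models()
  key <- paste(grid$model, grid$variant, sep = ".")
  grid$expected_slope <- switch(spec$importance_model,
    uniform = rep("zero", nrow(grid)),
    terminal_ends = ifelse(
      key == "laplacian.ssc", "negative",
      ifelse(grid$variant %in% c("ssc", "undirected"), "positive", "zero")),
    hubs = ifelse(grid$model == "laplacian", "zero", "positive")
  )
  grid
}

#' Write / read a synthetic cohort on disk
#'
#' Writes one edge-list TSV per pathway, a GMT file of planted important
#' genes, and a JSON sidecar with the generating spec -- exactly the
#' formats the package's readers consume.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort`: the directory, invisibly; `read_cohort`: a
#'   `synthetic_cohort` (with a NULL spec if the sidecar is absent).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in cohort$graphs) {
    write_edge_list(g, file.path(dir, paste0(g$pathway_id, ".tsv")))
  }
  write_gmt(cohort$important, file.path(dir, "important.gmt"))
  jsonlite::write_json(unclass(cohort$spec),
                       file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no edge-list TSV files in ", dir)
  graphs <- lapply(files, read_edge_list)
  # order pathways numerically when ids follow the generator's p{k} scheme
  ids <- vapply(graphs, function(g) g$pathway_id, "")
  num <- suppressWarnings(as.integer(sub("^p", "", ids)))
  if (!anyNA(num)) graphs <- graphs[order(num)]
  gmt <- file.path(dir, "important.gmt")
  important <- if (file.exists(gmt)) read_gene_set(gmt, "gmt")[[1]] else NULL
  spec_file <- file.path(dir, "spec.json")
  spec <- NULL
  if (file.exists(spec_file)) {
    raw <- jsonlite::read_json(spec_file, simplifyVector = TRUE)
    spec <- synthetic_spec(raw$n_pathways, raw$layers, raw$nodes_per_layer,
                           raw$p_forward, raw$p_skip, raw$p_feedback,
                           raw$hub_fraction, raw$importance_model,
                           raw$importance_rate, raw$seed)
  }
  structure(list(graphs = graphs, important = important, spec = spec),
            class = "synthetic_cohort")
}
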