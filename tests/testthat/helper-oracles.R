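# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the code paths they check.

# random directed graph on n nodes (no self-loops, 0/1 edges); uses the
# caller's RNG stream
rand_graph <- function(n = sample(3:50, 1), p = stats::runif(1, 0.05, 0.3),
                       id = "rand") {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  hit <- stats::runif(nrow(pairs)) < p
  ids <- sprintf("g%03d", seq_len(n))
  if (!any(hit)) hit[sample.int(length(hit), 1)] <- TRUE
  pathway_graph(cbind(ids[pairs$from[hit]], ids[pairs$to[hit]]),
                nodes = ids, pathway_id = id)
}

path_graph <- function(ids = c("a", "b", "c"), id = "path") {
  m <- cbind(ids[-length(ids)], ids[-1])
  pathway_graph(m, pathway_id = id)
}

# truncated Neumann/geometric series oracle for C = (I - M)^{-1} beta
neumann_solve <- function(M, beta, terms = 10000, tol = 1e-14) {
  n <- nrow(M)
  b <- rep_len(beta, n)
  x <- b
  term <- b
  for (k in seq_len(terms)) {
    term <- as.vector(M %*% term)
    x <- x + term
    if (max(abs(term)) < tol) break
  }
  x
}

# the iteration matrix of each spectral model/variant, built directly from
# the definitions (independent of the package's internal assembly)
oracle_M <- function(g, model, variant, alpha) {
  A <- adjacency_matrix(g)
  d <- degrees(g)
  dout <- pmax(d$out, 1); din <- pmax(d$in_, 1)
  if (model == "pagerank") {
    if (variant == "sink") return(alpha * t(A) %*% diag(1 / dout, nrow(A)))
    if (variant == "source") return(alpha * A %*% diag(1 / din, nrow(A)))
  }
  if (model == "katz") {
    if (variant == "source") return(alpha * A)
    if (variant == "sink") return(alpha * t(A))
  }
  if (model == "laplacian") {
    if (variant == "source") return(alpha * diag(1 / dout, nrow(A)) %*% A)
    if (variant == "sink") return(alpha * diag(1 / din, nrow(A)) %*% t(A))
  }
  stop("no oracle matrix for ", model, "/", variant)
}

# closed-form OLS of y on x via the normal equations, with the adjusted
# r-squared and coefficient inference computed from first principles
ols_hand <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  se1 <- sqrt(s2 / sxx)
  se0 <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  t1 <- b1 / se1; t0 <- b0 / se0
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(slope = b1, intercept = b0, se_slope = se1, se_intercept = se0,
       t_slope = t1, p_slope = 2 * stats::pt(-abs(t1), n - 2),
       adj_r2 = adj)
}

# BH step-up adjustment written directly from the step-up formula
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact one-sided Mann-Whitney p by full enumeration of rank assignments
# (cached combination matrices keyed by (N, n1))
.enum_cache <- new.env(parent = emptyenv())
wilcox_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  key <- paste(N, n1)
  if (is.null(.enum_cache[[key]])) .enum_cache[[key]] <- utils::combn(N, n1)
  cmb <- .enum_cache[[key]]
  rk <- seq_len(N)  # tie-free fixtures: ranks are a permutation
  U_all <- colSums(matrix(rk[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(U_all >= U_obs)
}

# minimal KGML documents for reader tests
kgml_minimal <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:test01" org="hsa" number="1">\n',
    '  <entry id="1" name="hsa:10" type="gene"/>\n',
    '  <entry id="2" name="hsa:20" type="gene"/>\n',
    '  <relation entry1="1" entry2="2" type="PPrel">\n',
    '    <subtype name="activation" value="--&gt;"/>\n',
    '  </relation>\n',
    '</pathway>\n')
}

kgml_fanout <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:test02" org="hsa" number="2">\n',
    '  <entry id="1" name="hsa:1 hsa:2" type="gene"/>\n',
    '  <entry id="2" name="hsa:3" type="gene"/>\n',
    '  <entry id="3" name="path:hsa00001" type="map"/>\n',
    '  <relation entry1="1" entry2="2" type="PPrel"/>\n',
    '  <relation entry1="1" entry2="3" type="maplink"/>\n',
    '</pathway>\n')
}

kgml_group <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:test03" org="hsa" number="3">\n',
    '  <entry id="1" name="hsa:1" type="gene"/>\n',
    '  <entry id="2" name="hsa:2" type="gene"/>\n',
    '  <entry id="3" name="hsa:3" type="gene"/>\n',
    '  <entry id="10" name="undefined" type="group">\n',
    '    <component id="1"/>\n',
    '    <component id="2"/>\n',
    '  </entry>\n',
    '  <relation entry1="10" entry2="3" type="PPrel"/>\n',
    '</pathway>\n')
}

write_tmp <- function(text, ext) {
  f <- tempfile(fileext = ext)
  writeLines(text, f, sep = "")
  f
}

# directed cycle graph: constant for every centrality model
cycle_graph <- function(n, id = "cycle") {
  ids <- sprintf("c%02d", seq_len(n))
  pathway_graph(cbind(ids, ids[c(2:n, 1)]), pathway_id = id)
}

# complete directed graph (both orientations) on n nodes: lambda1 = n - 1
clique_graph <- function(n, id = "clique") {
  ids <- sprintf("k%02d", seq_len(n))
  pairs <- expand.grid(ids, ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs[[1]] != pairs[[2]], ]
  pathway_graph(as.matrix(pairs), pathway_id = id)
}
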